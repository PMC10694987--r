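ellipseAxes <- function(radius, ecc) {
  # radius is the geometric-mean radius sqrt(a*b); ecc = sqrt(1 - (b/a)^2)
  q <- (1 - ecc^2)^0.25
  list(a = radius / q, b = radius * q)
}

ellipsePixels <- function(cx, cy, a, b, theta, h, w) {
  r0 <- max(1L, floor(cy - a) + 1L); r1 <- min(h, ceiling(cy + a) + 1L)
  c0 <- max(1L, floor(cx - a) + 1L); c1 <- min(w, ceiling(cx + a) + 1L)
  rows <- r0:r1; cols <- c0:c1
  dy <- rep(rows - 1 - cy, times = length(cols))
  dx <- rep(cols - 1 - cx, each = length(rows))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  (cc - 1L) * h + rr  # column-major linear indices
}

#' Simulate a brightfield IHC image with known ground truth
#'
#' Renders `nCells` elliptical nuclei (plus optional low-intensity decoy
#' artifacts) with uniform interior stain concentration: every nucleus
#' carries hematoxylin and a `dabPositiveFraction` of them also carry DAB.
#' The concentration rasters are converted to optical density through the
#' stain matrix and to RGB by the Beer-Lambert law
#' `I = (i0 + eps) * 10^(-OD) - eps` (8-bit quantized). Gaussian OD noise is
#' added after the truth counts are taken.
#'
#' @param config an [ImageSimConfig-class].
#' @param stains 3 x 3 stain matrix; default the H-DAB panel.
#' @param i0,eps Beer-Lambert constants matching [rgbToOD()].
#' @return List with elements:
#'   \describe{
#'     \item{rgb}{H x W x 3 integer intensities in `[0, 255]`.}
#'     \item{labelMask}{integer label matrix of the non-artifact nuclei,
#'       labelled in draw order.}
#'     \item{truth}{list: `cells` (one row per drawn object: `cell_id`, `cx`,
#'       `cy`, `radius`, `eccentricity`, `theta`, `dab_positive`,
#'       `is_artifact`), `trueDabPixelCount`, `trueHematoxylinPixelCount`.}
#'     \item{concentration}{noise-free H x W x 3 rendered concentration
#'       array (hematoxylin, dab, residual).}
#'   }
#' @examples
#' sim <- simulateIHCImage(imageSimConfig(nCells = 10, seed = 7))
#' attr(sim$labelMask, "nObjects")
#' @export
simulateIHCImage <- function(config, stains = stainVectors("HDAB"),
                             i0 = 255, eps = 1) {
  stopifnot(is(config, "ImageSimConfig"))
  validObject(config)
  checkStainMatrix(stains)
  set.seed(config@seed)
  h <- as.integer(config@height); w <- as.integer(config@width)
  nCells <- as.integer(config@nCells)
  nArt <- as.integer(round(config@artifactFraction * nCells))
  nTotal <- nCells + nArt
  pop <- config@populations

  concH <- matrix(0, h, w)
  concD <- matrix(0, h, w)
  lab <- matrix(0L, h, w)
  cells <- data.frame(cell_id = integer(), cx = numeric(), cy = numeric(),
                      radius = numeric(), eccentricity = numeric(),
                      theta = numeric(), population = integer(),
                      dab_positive = logical(), is_artifact = logical())
  if (nTotal > 0) {
    popIdx <- sample.int(nrow(pop), nTotal, replace = TRUE,
                         prob = pop$fraction)
    radius <- pmax(1, stats::rnorm(nTotal, pop$meanRadius[popIdx],
                                   pop$radiusSD[popIdx]))
    ecc <- pop$eccentricity[popIdx]
    theta <- stats::runif(nTotal, -pi / 2, pi / 2)
    isArt <- c(rep(FALSE, nCells), rep(TRUE, nArt))
    dabPos <- stats::runif(nTotal) < config@dabPositiveFraction & !isArt
    ax <- ellipseAxes(radius, ecc)
    if (any(ax$b < 0.5))
      stop("zero-area ellipse parameters: minor semi-axis below 0.5 px")
    cx <- numeric(nTotal); cy <- numeric(nTotal)
    maxAttempts <- 10000L
    for (i in seq_len(nTotal)) {
      a <- ax$a[i]
      if (2 * a + 2 > min(h, w))
        stop("cell larger than image: major axis ", round(2 * a, 1), " px")
      placed <- FALSE
      for (attempt in seq_len(maxAttempts)) {
        px <- stats::runif(1, a, w - 1 - a)
        py <- stats::runif(1, a, h - 1 - a)
        if (config@allowOverlap || i == 1L) {
          ok <- TRUE
        } else {
          prev <- seq_len(i - 1L)
          # 2 px padding keeps non-overlapping nuclei background-separated
          # so connected components match the drawn cell count
          ok <- all((cx[prev] - px)^2 + (cy[prev] - py)^2 >
                      (ax$a[prev] + a + 2)^2)
        }
        if (ok) { cx[i] <- px; cy[i] <- py; placed <- TRUE; break }
      }
      if (!placed)
        stop("failed to place cell ", i, " of ", nTotal,
             " without overlap after ", maxAttempts,
             " attempts (cell area fraction ",
             signif(sum(pi * radius[seq_len(i)]^2) / (h * w), 3), ")")
    }
    for (i in seq_len(nTotal)) {
      idx <- ellipsePixels(cx[i], cy[i], ax$a[i], ax$b[i], theta[i], h, w)
      if (length(idx) == 0)
        stop("zero-area ellipse after rasterization (cell ", i, ")")
      hOD <- if (isArt[i])
        config@artifactODFraction * config@hematoxylinODMean
      else config@hematoxylinODMean
      concH[idx] <- hOD
      if (dabPos[i]) concD[idx] <- config@dabODMean
      if (!isArt[i]) lab[idx] <- i
    }
    cells <- data.frame(cell_id = seq_len(nTotal), cx = cx, cy = cy,
                        radius = radius, eccentricity = ecc, theta = theta,
                        population = popIdx, dab_positive = dabPos,
                        is_artifact = isArt)
  }
  conc <- array(0, c(h, w, 3))
  conc[, , 1] <- concH
  conc[, , 2] <- concD
  od <- array(matrix(conc, ncol = 3) %*% stains, c(h, w, 3))
  if (config@backgroundNoiseSD > 0)
    od <- od + stats::rnorm(length(od), 0, config@backgroundNoiseSD)
  od[od < 0] <- 0
  rgb <- round((i0 + eps) * 10^(-od) - eps)
  rgb[rgb < 0] <- 0
  rgb[rgb > i0] <- i0
  attr(lab, "nObjects") <- if (nTotal > 0) as.integer(max(lab)) else 0L
  list(rgb = rgb, labelMask = lab,
       truth = list(cells = cells,
                    trueDabPixelCount = sum(concD > 0),
                    trueHematoxylinPixelCount = sum(concH > 0)),
       concentration = conc)
}
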