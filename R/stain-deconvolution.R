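#' Standard stain OD vectors
#'
#' Returns a 3 x 3 stain matrix for a named panel: rows are unit-norm optical
#' density vectors over (R, G, B) for the two named stains plus a residual
#' third row completed by the normalized cross product. Values are the
#' published Ruifrok-Johnston vectors for hematoxylin, eosin and DAB.
#'
#' @param panel `"HDAB"` (hematoxylin + DAB) or `"HE"` (hematoxylin + eosin).
#' @return 3 x 3 numeric matrix with row names naming the stains.
#' @examples
#' stainVectors("HDAB")
#' @export
stainVectors <- function(panel = c("HDAB", "HE")) {
  panel <- match.arg(panel)
  hema <- c(0.65, 0.70, 0.29)
  eosin <- c(0.07, 0.99, 0.11)
  dab <- c(0.27, 0.57, 0.78)
  second <- if (panel == "HDAB") dab else eosin
  m <- rbind(hematoxylin = hema / sqrt(sum(hema^2)),
             second = second / sqrt(sum(second^2)))
  rownames(m)[2] <- if (panel == "HDAB") "dab" else "eosin"
  res <- c(m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2],
           m[1, 3] * m[2, 1] - m[1, 1] * m[2, 3],
           m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  m <- rbind(m, residual = res / sqrt(sum(res^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

checkStainMatrix <- function(stains) {
  if (!is.matrix(stains) || any(dim(stains) != c(3, 3)))
    stop("stain matrix must be 3 x 3")
  norms <- sqrt(rowSums(stains^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("stain matrix rows must have unit Euclidean norm (tol 1e-6)")
  if (abs(det(stains)) < 1e-8) {
    rn <- rownames(stains)
    if (is.null(rn)) rn <- paste0("row", 1:3)
    stop("singular stain matrix; check rows: ", paste(rn, collapse = ", "))
  }
  invisible(stains)
}

#' Convert an RGB brightfield image to optical density
#'
#' Beer-Lambert transform: `OD = -log10((I + eps) / (i0 + eps))` per channel,
#' where `i0` is the incident (background) intensity. `eps` guards against
#' `log(0)` on saturated black pixels.
#'
#' @param image H x W x 3 numeric array of intensities in `[0, 255]`.
#' @param i0 incident intensity (default 255).
#' @param eps additive guard (default 1 intensity unit).
#' @return H x W x 3 array of optical densities.
#' @examples
#' od <- rgbToOD(array(255, c(4, 4, 3)), eps = 0)  # all zero
#' @export
rgbToOD <- function(image, i0 = 255, eps = 1) {
  if (i0 <= 0) stop("i0 must be > 0")
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be an H x W x 3 array")
  -log10((image + eps) / (i0 + eps))
}

#' Linear color deconvolution
#'
#' Unmixes an optical-density image into per-stain concentrations: per pixel,
#' the concentration vector solves `c %*% stains = od`. Negative solutions
#' (from noise or stains outside the model) are clamped to zero, and the
#' fraction of clamped entries is recorded in the result's `clampRate`.
#'
#' @param od H x W x 3 optical density array (see [rgbToOD()]).
#' @param stains 3 x 3 unit-row stain matrix (see [stainVectors()]).
#' @return A [ConcentrationImage-class].
#' @examples
#' m <- stainVectors("HDAB")
#' od <- array(rep(0.5 * m[1, ], each = 4), c(2, 2, 3))
#' ci <- deconvolve(od, m)  # 0.5 hematoxylin everywhere
#' @export
deconvolve <- function(od, stains) {
  checkStainMatrix(stains)
  d <- dim(od)
  if (length(d) != 3 || d[3] != 3) stop("od must be an H x W x 3 array")
  odFlat <- matrix(od, ncol = 3)
  conc <- odFlat %*% solve(stains)
  rate <- mean(conc < -1e-12)
  conc[conc < 0] <- 0
  nm <- rownames(stains)
  if (is.null(nm)) nm <- c("stain1", "stain2", "residual")
  new("ConcentrationImage", pixels = array(conc, d), stainNames = nm,
      clampRate = rate)
}

#' Recompose an OD image from stain concentrations
#'
#' Inverse of [deconvolve()]: `od = c %*% stains`. Exact up to numerical
#' tolerance when no concentrations were clamped.
#'
#' @param conc a [ConcentrationImage-class] or H x W x 3 array.
#' @param stains the stain matrix used for deconvolution.
#' @return H x W x 3 optical density array.
#' @export
recompose <- function(conc, stains) {
  checkStainMatrix(stains)
  px <- if (is(conc, "ConcentrationImage")) conc@pixels else conc
  d <- dim(px)
  array(matrix(px, ncol = 3) %*% stains, d)
}

#' Extract one stain channel as a scaled gray image
#'
#' Returns the named stain's concentration plane, min-max scaled to `[0, 1]`
#' per image. The scaling constants are recorded in the `"scaleMin"` /
#' `"scaleMax"` attributes so the transform is invertible. A constant plane
#' (degenerate scaling) returns all zeros with a warning.
#'
#' @param conc a [ConcentrationImage-class].
#' @param stain one of `stainNames(conc)`.
#' @return H x W matrix in `[0, 1]` with scaling attributes.
#' @export
stainChannel <- function(conc, stain) {
  stopifnot(is(conc, "ConcentrationImage"))
  idx <- match(stain, conc@stainNames)
  if (is.na(idx))
    stop("unknown stain '", stain, "'; available: ",
         paste(conc@stainNames, collapse = ", "))
  plane <- conc@pixels[, , idx]
  lo <- min(plane); hi <- max(plane)
  if (hi - lo <= 0) {
    warning("constant '", stain, "' channel; returning all zeros")
    out <- array(0, dim(plane))
  } else {
    out <- (plane - lo) / (hi - lo)
  }
  attr(out, "scaleMin") <- lo
  attr(out, "scaleMax") <- hi
  out
}
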