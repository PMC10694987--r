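#' Otsu threshold of a gray image
#'
#' Builds an `nBins` histogram of the image over the fixed `[0, 1]` domain
#' and returns the bin edge that maximizes the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the induced two-class split (class 0: values
#' `<=` threshold, class 1: values `>` threshold, matching [binarize()]).
#' Ties are broken toward the lowest qualifying threshold.
#'
#' @param img H x W matrix with values in `[0, 1]`.
#' @param nBins number of histogram bins (default 256).
#' @return Scalar threshold (a bin edge `k / nBins`).
#' @examples
#' img <- matrix(rep(c(0.2, 0.8), each = 50), 10, 10)
#' otsuThreshold(img)
#' @export
otsuThreshold <- function(img, nBins = 256) {
  v <- as.numeric(img)
  if (any(!is.finite(v))) stop("image must be finite")
  if (min(v) < 0 || max(v) > 1) stop("image values must lie in [0, 1]")
  bin <- pmin(floor(v * nBins), nBins - 1)  # bins 0..nBins-1
  counts <- tabulate(bin + 1L, nbins = nBins)
  if (sum(counts > 0) < 2)
    stop("degenerate histogram: fewer than two occupied bins")
  n <- length(v)
  mids <- (seq_len(nBins) - 0.5) / nBins
  w0 <- cumsum(counts)[-nBins]
  s0 <- cumsum(counts * mids)[-nBins]
  w1 <- n - w0
  totalMean <- sum(counts * mids) / n
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (totalMean * n - s0) / w1, 0)
  sigmaB <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sigmaB[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(sigmaB)  # first maximum = lowest qualifying edge
  k / nBins
}

#' Binarize a gray image at a threshold
#'
#' Strict comparison: a pixel is foreground iff its value is `> threshold`.
#'
#' @param img H x W numeric matrix.
#' @param threshold finite scalar.
#' @return H x W integer matrix in `{0, 1}`.
#' @export
binarize <- function(img, threshold) {
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be numeric")
  out <- (img > threshold) * 1L
  dim(out) <- dim(img)
  out
}

#' Label connected foreground components
#'
#' Maximal connected components of the foreground (value > 0) under 4- or
#' 8-connectivity, labelled `1..n` in raster-scan order (row-major) of each
#' component's first pixel.
#'
#' @param mask H x W binary matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return H x W integer label matrix with attribute `"nObjects"`.
#' @examples
#' m <- matrix(0L, 5, 5); m[2:3, 2:3] <- 1L; m[5, 5] <- 1L
#' lab <- labelComponents(m)
#' attr(lab, "nObjects")  # 2
#' @export
labelComponents <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask > 0)  # column-major linear indices
  lab <- matrix(0L, h, w)
  n <- length(fg)
  if (n == 0) {
    attr(lab, "nObjects") <- 0L
    return(lab)
  }
  id <- integer(h * w)
  id[fg] <- seq_len(n)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- NULL
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hit <- id[nb] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(id[fg[ok]][hit], id[nb][hit]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel by raster (row-major) order of each component's first pixel
  raster <- (rows - 1L) * w + cols
  firstRaster <- tapply(raster, comp, min)
  newLab <- integer(length(firstRaster))
  newLab[order(firstRaster)] <- seq_along(firstRaster)
  lab[fg] <- newLab[comp]
  attr(lab, "nObjects") <- as.integer(max(newLab))
  lab
}

#' Threshold a body/process probability-map pair
#'
#' Binarizes both externally produced CNN prediction maps at the same global
#' threshold (strict `>`, as in [binarize()]).
#'
#' @param bodyMap,processMap H x W matrices with values in `[0, 1]`.
#' @param threshold global threshold in `[0, 1]`.
#' @return List with `body` and `process` binary masks.
#' @export
thresholdProbabilityMaps <- function(bodyMap, processMap, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (!identical(dim(bodyMap), dim(processMap)))
    stop("body and process maps must have the same shape")
  list(body = binarize(bodyMap, threshold),
       process = binarize(processMap, threshold))
}

#' Merge body and process masks into whole-cell labels
#'
#' Pixel-wise union of the two masks followed by [labelComponents()]. Each
#' resulting object is flagged with whether it contains at least one body
#' pixel (attribute `"containsBody"`, one logical per label).
#'
#' @param body,process H x W binary masks of the same shape.
#' @param connectivity 4 or 8 (default 8).
#' @return Label matrix with attributes `"nObjects"` and `"containsBody"`.
#' @export
mergeMasks <- function(body, process, connectivity = 8) {
  if (!identical(dim(body), dim(process)))
    stop("body and process masks must have the same shape")
  lab <- labelComponents((body > 0 | process > 0) * 1L, connectivity)
  nObj <- attr(lab, "nObjects")
  containsBody <- logical(nObj)
  if (nObj > 0) {
    bodyLabs <- unique(lab[body > 0 & lab > 0])
    containsBody[bodyLabs] <- TRUE
  }
  attr(lab, "containsBody") <- containsBody
  lab
}
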