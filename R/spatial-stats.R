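#' Mean distance to the k-th nearest neighboring cell
#'
#' For every cell centroid, the Euclidean distance to its k-th nearest
#' *other* cell (k = 100 by default, the cellularity statistic used on
#' hematoxylin segmentations), and the arithmetic mean over cells. Distances
#' are computed with an exact kd-tree search. When the image holds `k` or
#' fewer cells the statistic is undefined: the mean is `NA` with attribute
#' `insufficientCells = TRUE` and a warning.
#'
#' @param centroids n x 2 matrix (or data.frame) of `(cx, cy)` positions.
#' @param k neighbor order (default 100).
#' @return List: `perCell` (numeric vector of k-th NN distances), `mean`,
#'   `insufficientCells`.
#' @examples
#' pts <- cbind(c(0, 3), c(0, 4))
#' knnMeanDistance(pts, k = 1)$mean  # 5
#' @export
knnMeanDistance <- function(centroids, k = 100) {
  if (k < 1) stop("k must be >= 1")
  pts <- as.matrix(centroids)
  if (ncol(pts) != 2) stop("centroids must be n x 2")
  if (any(!is.finite(pts))) stop("centroids must be finite")
  n <- nrow(pts)
  if (n <= k) {
    warning("only ", n, " cells for k = ", k,
            "; k-th neighbor distance undefined")
    return(list(perCell = rep(NA_real_, n), mean = NA_real_,
                insufficientCells = TRUE))
  }
  nn <- RANN::nn2(pts, pts, k = k + 1, treetype = "kd", eps = 0)
  perCell <- nn$nn.dists[, k + 1]
  list(perCell = perCell, mean = mean(perCell), insufficientCells = FALSE)
}

#' DAB-positive to hematoxylin-positive pixel ratio
#'
#' `count(dab == 1) / count(hema == 1)` over an image, the staining burden
#' statistic that controls for variable cellularity and image size. A zero
#' denominator yields `NA` with `zeroDenominator = TRUE`.
#'
#' @param dabMask,hemaMask binary masks of the same shape (post-Otsu masks
#'   of the respective deconvolved channels).
#' @return List: `ratio`, `dabPixels`, `hemaPixels`, `zeroDenominator`.
#' @export
stainPixelRatio <- function(dabMask, hemaMask) {
  if (!identical(dim(dabMask), dim(hemaMask)))
    stop("masks must have the same shape")
  dab <- sum(dabMask > 0)
  hema <- sum(hemaMask > 0)
  if (hema == 0)
    return(list(ratio = NA_real_, dabPixels = dab, hemaPixels = 0L,
                zeroDenominator = TRUE))
  list(ratio = dab / hema, dabPixels = dab, hemaPixels = hema,
       zeroDenominator = FALSE)
}

#' Image-level statistics record
#'
#' Combines the two image statistics into the per-image record appended to
#' the study table.
#'
#' @param imageId image identifier.
#' @param featureTable per-cell feature table for the image (uses `cx`,
#'   `cy`).
#' @param dabMask,hemaMask post-Otsu stain masks.
#' @param group,region study labels.
#' @param k neighbor order for the cellularity distance.
#' @return One-row `data.frame`: `image_id`, `group`, `region`, `n_cells`,
#'   `mean_knn_distance`, `knn_k`, `dab_hema_ratio`, `insufficient_cells`,
#'   `zero_denominator`.
#' @export
imageStatRecord <- function(imageId, featureTable, dabMask, hemaMask,
                            group = NA_character_, region = NA_character_,
                            k = 100) {
  n <- nrow(featureTable)
  knn <- if (n > 0)
    suppressWarnings(knnMeanDistance(featureTable[, c("cx", "cy")], k = k))
  else list(mean = NA_real_, insufficientCells = TRUE)
  ratio <- stainPixelRatio(dabMask, hemaMask)
  data.frame(image_id = imageId, group = group, region = region,
             n_cells = n, mean_knn_distance = knn$mean, knn_k = k,
             dab_hema_ratio = ratio$ratio,
             insufficient_cells = knn$insufficientCells,
             zero_denominator = ratio$zeroDenominator)
}
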