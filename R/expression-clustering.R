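#' Subset an expression matrix to a signature gene list
#'
#' @param expr genes x samples matrix with gene row names.
#' @param genes character vector of signature gene ids.
#' @return Row-subset matrix; genes absent from `expr` are reported in a
#'   warning.
#' @export
subsetSignature <- function(expr, genes) {
  if (length(genes) == 0) stop("empty gene list")
  present <- intersect(genes, rownames(expr))
  absent <- setdiff(genes, rownames(expr))
  if (length(present) < 2)
    stop("fewer than 2 signature genes present in the matrix")
  if (length(absent))
    warning("signature genes absent from matrix: ",
            paste(absent, collapse = ", "))
  expr[present, , drop = FALSE]
}

#' t-SNE embedding of samples
#'
#' Embeds samples (columns) of a signature-subset expression matrix in 2-D
#' with Rtsne, deterministically for a given seed. Requires
#' `nSamples - 1 >= 3 * perplexity`.
#'
#' @param expr genes x samples matrix.
#' @param perplexity t-SNE perplexity (default 10).
#' @param seed integer seed.
#' @return samples x 2 coordinate matrix.
#' @export
embedSamples <- function(expr, perplexity = 10, seed = 1L) {
  n <- ncol(expr)
  if (n - 1 < 3 * perplexity)
    stop("perplexity too large for ", n, " samples; maximum valid value is ",
         floor((n - 1) / 3))
  set.seed(seed)
  fit <- Rtsne::Rtsne(t(expr), dims = 2, perplexity = perplexity,
                      pca = TRUE, check_duplicates = FALSE, num_threads = 1)
  out <- fit$Y
  rownames(out) <- colnames(expr)
  colnames(out) <- c("tSNE1", "tSNE2")
  out
}

#' kMeans clustering with silhouette-selected k
#'
#' Runs kMeans on samples for every k in `kRange` (best of `nInit` restarts
#' by within-cluster sum of squares) and selects the k maximizing the mean
#' silhouette width under Euclidean distance.
#'
#' @param data samples x features matrix (e.g. `t(signature matrix)` or a
#'   2-D embedding).
#' @param kRange candidate cluster counts (default 2:10).
#' @param nInit kMeans restarts per k (default 25).
#' @param seed integer seed.
#' @return A [ClusterAssignment-class].
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 6), 20))
#' kmeansSilhouette(x, kRange = 2:4)@k  # 2
#' @export
kmeansSilhouette <- function(data, kRange = 2:10, nInit = 25, seed = 1L) {
  X <- as.matrix(data)
  n <- nrow(X)
  if (n < max(kRange) + 1)
    stop("need at least max(kRange) + 1 samples")
  set.seed(seed)
  d <- stats::dist(X)
  fits <- list()
  silByK <- data.frame(k = kRange, meanSilhouette = NA_real_)
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    fit <- stats::kmeans(X, centers = k, nstart = nInit, iter.max = 100)
    fits[[i]] <- fit
    silByK$meanSilhouette[i] <- if (k == 1) NA_real_ else
      mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
  }
  best <- which.max(silByK$meanSilhouette)
  cl <- as.integer(fits[[best]]$cluster)
  names(cl) <- rownames(X)
  new("ClusterAssignment", cluster = cl, k = kRange[best],
      silhouetteByK = silByK, seed = seed)
}

meanPairDistance <- function(X, pairs, nSampledPairs) {
  # pairs: 2-column matrix of candidate row index pairs
  if (nrow(pairs) > nSampledPairs)
    pairs <- pairs[sample.int(nrow(pairs), nSampledPairs), , drop = FALSE]
  mean(sqrt(rowSums((X[pairs[, 1], , drop = FALSE] -
                       X[pairs[, 2], , drop = FALSE])^2)))
}

allPairs <- function(labels) {
  n <- length(labels)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  same <- labels[idx[, 1]] == labels[idx[, 2]]
  list(within = idx[same, , drop = FALSE],
       between = idx[!same, , drop = FALSE])
}

separationStatistic <- function(X, labels, nSampledPairs) {
  p <- allPairs(labels)
  w <- meanPairDistance(X, p$within, nSampledPairs)
  b <- meanPairDistance(X, p$between, nSampledPairs)
  c(within = w, between = b, separation = b - w)
}

#' Permutation validation of cluster separation
#'
#' Measures the observed cluster separation (mean between-cluster distance
#' minus mean within-cluster distance, estimated from up to
#' `nSampledPairs` uniformly sampled pairs of each kind) and compares it to
#' a null built by scrambling the data: each feature (gene) is permuted
#' independently across samples, destroying covariance while preserving
#' each feature's marginal values, then re-clustered with kMeans at the
#' same k and re-measured. The one-sided empirical p-value is
#' `(1 + #\{null >= observed\}) / (nPerm + 1)`.
#'
#' @param data samples x features matrix used for clustering.
#' @param assignment a [ClusterAssignment-class] for `data`.
#' @param nPerm number of permutations (default 10000).
#' @param nSampledPairs pairs sampled per statistic (default 10000).
#' @param nInit kMeans restarts when re-clustering each null dataset.
#' @param reuseLabels if `TRUE`, apply the observed labels to the scrambled
#'   data instead of re-clustering.
#' @param seed integer seed.
#' @return A [PermutationTestResult-class].
#' @export
permutationClusterTest <- function(data, assignment, nPerm = 10000,
                                   nSampledPairs = 10000, nInit = 5,
                                   reuseLabels = FALSE, seed = 1L) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  X <- as.matrix(data)
  labels <- assignment@cluster
  if (length(labels) != nrow(X))
    stop("assignment does not match data rows")
  if (any(table(labels) < 2)) stop("every cluster must have >= 2 members")
  k <- assignment@k
  set.seed(seed)
  obs <- separationStatistic(X, labels, nSampledPairs)
  null <- numeric(nPerm)
  n <- nrow(X)
  for (b in seq_len(nPerm)) {
    Xp <- apply(X, 2, sample)
    labp <- if (reuseLabels) labels else
      stats::kmeans(Xp, centers = k, nstart = nInit, iter.max = 100)$cluster
    if (any(table(labp) < 1)) next
    null[b] <- separationStatistic(Xp, labp, nSampledPairs)["separation"]
  }
  p <- (1 + sum(null >= obs["separation"])) / (nPerm + 1)
  new("PermutationTestResult",
      observedWithin = unname(obs["within"]),
      observedBetween = unname(obs["between"]),
      observedSeparation = unname(obs["separation"]),
      nullSeparations = null, empiricalP = p, nPerm = nPerm,
      nSampledPairs = nSampledPairs, seed = seed)
}

#' 2x2 chi-square with Yates continuity correction
#'
#' Pearson chi-square of a 2x2 contingency table with the Yates correction
#' `sum((max(|O - E| - 0.5, 0))^2 / E)`, `df = 1` — the cluster-vs-diagnosis
#' test for a two-cluster, two-diagnosis design. The correction is capped at
#' `|O - E|` (the standard convention), so a table exactly at its expected
#' counts gives a statistic of 0.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return List: `chi2`, `df`, `p`.
#' @examples
#' yatesChi2(matrix(c(22, 5, 4, 17), 2))  # chi2 = 16.12
#' @export
yatesChi2 <- function(table) {
  O <- as.matrix(table)
  if (any(dim(O) != c(2, 2))) stop("table must be 2x2")
  if (any(O < 0) || any(O != round(O))) stop("counts must be nonnegative integers")
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("all margins must be positive")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
  list(chi2 = chi2, df = 1,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
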