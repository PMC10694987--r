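#' Balanced subsample of cells per group
#'
#' Draws exactly `nPerGroup` rows per group without replacement (8,000 per
#' group by default, controlling for uneven segmentation counts between
#' groups), deterministically for a given seed.
#'
#' @param table cell feature table.
#' @param groupCol grouping column name (default `"group"`).
#' @param nPerGroup rows to keep per group.
#' @param seed integer seed.
#' @return Subsampled table.
#' @export
balancedSubsample <- function(table, groupCol = "group", nPerGroup = 8000,
                              seed = 1L) {
  g <- table[[groupCol]]
  sizes <- table(g)
  if (any(sizes < nPerGroup)) {
    bad <- names(sizes)[sizes < nPerGroup]
    stop("group(s) too small for nPerGroup = ", nPerGroup, ": ",
         paste(sprintf("%s (%d)", bad, sizes[bad]), collapse = ", "))
  }
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(table)), g), function(ix)
    sort(sample(ix, nPerGroup))))
  table[idx, , drop = FALSE]
}

#' 2-D UMAP embedding of cell morphology
#'
#' Z-scores the shape and moment feature columns (x/y positions excluded)
#' and embeds them with UMAP. Constant feature columns are dropped with a
#' warning. Deterministic for a given seed.
#'
#' @param table cell feature table with no missing morphology values.
#' @param features feature columns; default [featureColumns()]
#'   `"morphology"`.
#' @param nNeighbors,minDist UMAP parameters.
#' @param seed integer seed.
#' @return n x 2 coordinate matrix.
#' @export
embedMorphology <- function(table, features = featureColumns("morphology"),
                            nNeighbors = 15, minDist = 0.1, seed = 1L) {
  missing <- setdiff(features, names(table))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(X)) stop("morphology features must not contain missing values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  X <- scale(X)
  set.seed(seed)
  emb <- uwot::umap(X, n_neighbors = nNeighbors, min_dist = minDist,
                    n_threads = 1, n_sgd_threads = 0)
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}

#' Density-based clustering (DBSCAN) of an embedding
#'
#' Classic DBSCAN over Euclidean distance: a point is a core point if its
#' eps-neighborhood (itself included) holds at least `minSamples` points;
#' clusters grow from core points; non-reachable points are noise (-1).
#' Clusters smaller than `minClusterSize` (160 by default, the minimum
#' cluster size for retained morphology phenotypes) are relabelled to noise
#' and reported in the `"omittedClusters"` attribute. Retained clusters are
#' renumbered 1..n by decreasing size.
#'
#' @param embedding n x d numeric matrix.
#' @param eps neighborhood radius (> 0).
#' @param minSamples core-point density threshold (default 5).
#' @param minClusterSize minimum retained cluster size (default 160).
#' @return Integer label vector (-1 = noise) with attribute
#'   `"omittedClusters"` (sizes of the dropped clusters).
#' @export
clusterEmbedding <- function(embedding, eps, minSamples = 5,
                             minClusterSize = 160) {
  if (eps <= 0) stop("eps must be > 0")
  X <- as.matrix(embedding)
  n <- nrow(X)
  nbr <- dbscanNeighbors(X, eps)
  nNbr <- lengths(nbr)
  core <- nNbr >= minSamples
  labels <- rep(0L, n)  # 0 = unvisited, -1 = noise
  cl <- 0L
  for (p in seq_len(n)) {
    if (labels[p] != 0L || !core[p]) next
    cl <- cl + 1L
    labels[p] <- cl
    queue <- nbr[[p]]
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (labels[q] == -1L) labels[q] <- cl       # border point
      if (labels[q] != 0L) next
      labels[q] <- cl
      if (core[q]) queue <- c(queue, nbr[[q]])
    }
  }
  labels[labels == 0L] <- -1L
  # enforce minimum cluster size, renumber survivors by decreasing size
  sizes <- table(labels[labels > 0])
  omitted <- as.integer(sizes[sizes < minClusterSize])
  small <- as.integer(names(sizes)[sizes < minClusterSize])
  labels[labels %in% small] <- -1L
  keep <- sort(unique(labels[labels > 0]))
  if (length(keep)) {
    ord <- keep[order(-as.integer(table(factor(labels, levels = keep))))]
    remap <- integer(max(ord)); remap[ord] <- seq_along(ord)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  attr(labels, "omittedClusters") <- omitted
  labels
}

dbscanNeighbors <- function(X, eps) {
  n <- nrow(X)
  # exact radius search; widen k until every neighborhood fits
  k <- min(n, 64L)
  repeat {
    nn <- RANN::nn2(X, X, k = k, searchtype = "radius", radius = eps)
    if (k == n || all(nn$nn.idx[, k] == 0L)) break
    full <- nn$nn.idx[, k] != 0L
    if (!any(full)) break
    k <- min(n, k * 2L)
  }
  lapply(seq_len(n), function(i) {
    ix <- nn$nn.idx[i, ]
    ix[ix != 0L]
  })
}

#' Suggest a DBSCAN eps by the k-distance knee
#'
#' Returns the distance at the steepest increase of the sorted k-th
#' nearest-neighbor distance curve, a standard heuristic starting point for
#' `eps` (which remains a user-set parameter).
#'
#' @param embedding n x d matrix.
#' @param k neighbor order (default `minSamples`).
#' @return Suggested eps value.
#' @export
suggestEps <- function(embedding, k = 5) {
  X <- as.matrix(embedding)
  nn <- RANN::nn2(X, X, k = k + 1)
  d <- sort(nn$nn.dists[, k + 1])
  jump <- which.max(diff(d))
  d[jump]
}

#' Pearson chi-square of cluster-by-group distribution
#'
#' Tests the retained clusters x groups contingency table against the
#' balanced-design expectation of an even group distribution, using the
#' uncorrected Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)`. Noise cells (label -1) are excluded.
#'
#' @param labels integer cluster labels (-1 = noise).
#' @param groups group label per cell.
#' @return List: `contingency`, `chi2`, `df`, `p`,
#'   `lowExpected` (TRUE if any expected cell < 1).
#' @export
clusterGroupChi2 <- function(labels, groups) {
  keep <- labels > 0
  if (!any(keep)) stop("no retained clusters")
  tab <- table(cluster = labels[keep], group = as.character(groups[keep]))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need >= 2 retained clusters and >= 2 groups")
  O <- unclass(tab)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  low <- any(E < 1)
  if (low) warning("expected cell count below 1; chi-square unreliable")
  list(contingency = O, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), lowExpected = low)
}

#' Morphology clustering of one stain
#'
#' Full per-stain workflow: balanced subsampling, UMAP embedding of shape
#' and moment features, DBSCAN with a minimum retained cluster size, and
#' the cluster-by-group chi-square.
#'
#' @param table cell feature table for one stain.
#' @param stain stain name (metadata only).
#' @param nPerGroup,eps,minSamples,minClusterSize,nNeighbors,minDist
#'   stage parameters (see the stage functions).
#' @param seed integer seed.
#' @return A [MorphoClusterResult-class].
#' @export
morphologyCluster <- function(table, stain = "stain", nPerGroup = 8000,
                              eps, minSamples = 5, minClusterSize = 160,
                              nNeighbors = 15, minDist = 0.1, seed = 1L) {
  sub <- balancedSubsample(table, nPerGroup = nPerGroup, seed = seed)
  emb <- embedMorphology(sub, nNeighbors = nNeighbors, minDist = minDist,
                         seed = seed)
  labels <- clusterEmbedding(emb, eps = eps, minSamples = minSamples,
                             minClusterSize = minClusterSize)
  chi <- clusterGroupChi2(labels, sub$group)
  new("MorphoClusterResult", stain = stain, embedding = emb,
      labels = as.integer(labels), contingency = chi$contingency,
      chi2Stat = chi$chi2, chi2Df = chi$df, chi2P = chi$p,
      nPerGroup = nPerGroup,
      omittedClusters = attr(labels, "omittedClusters"), seed = seed)
}
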