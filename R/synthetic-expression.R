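#' Simulate a genes x samples expression matrix with known structure
#'
#' Generates log-normal expression with `kClusters` latent sample clusters.
#' Signature genes (assigned round-robin to clusters) are shifted upward by
#' `effectSize` in log space for samples of their cluster; housekeeping
#' genes have log-sd `sqrt(log(1 + cv^2))` so their coefficient of variation
#' is exactly `housekeepingCV` in expectation; remaining genes are
#' uninformative noise. Imputation-target genes are built from their named
#' predictor genes (linear combination or pairwise interaction of log
#' values) with noise scaled so the log-space R-squared equals the
#' requested `r2`.
#'
#' @param config an [ExprSimConfig-class].
#' @param baseMean optional per-gene log-scale baseline of length `nGenes`.
#'   Passing the `baseMean` element returned by a previous call generates a
#'   second cohort with the same gene-level biology (as when a reference and
#'   a target platform measure the same genes), which is what cross-dataset
#'   imputation assumes.
#' @return List with:
#'   \describe{
#'     \item{matrix}{`nGenes` x `nSamples` positive matrix, rows
#'       `gene_001`..., columns `sample_001`...}
#'     \item{clusters}{named integer vector of true sample clusters.}
#'     \item{genes}{`data.frame` with `gene_id`, `role` (signature,
#'       housekeeping, target, noise), `cluster` (signature genes) and
#'       `r2` (targets).}
#'     \item{baseMean}{the per-gene log baseline used.}
#'   }
#' @examples
#' sim <- simulateExpression(exprSimConfig(nSamples = 30, nGenes = 100,
#'                                         kClusters = 2, signatureSize = 10))
#' dim(sim$matrix)
#' @export
simulateExpression <- function(config, baseMean = NULL) {
  stopifnot(is(config, "ExprSimConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- as.integer(config@nSamples)
  g <- as.integer(config@nGenes)
  k <- as.integer(config@kClusters)
  geneIds <- sprintf("gene_%03d", seq_len(g))
  sampleIds <- sprintf("sample_%03d", seq_len(n))
  clusters <- rep(seq_len(k), length.out = n)

  nSig <- as.integer(config@signatureSize)
  nHk <- as.integer(config@nHousekeeping)
  sigIdx <- seq_len(nSig)
  hkIdx <- if (nHk > 0) nSig + seq_len(nHk) else integer()
  role <- rep("noise", g)
  role[sigIdx] <- "signature"
  role[hkIdx] <- "housekeeping"
  sigCluster <- rep(NA_integer_, g)
  if (nSig > 0) sigCluster[sigIdx] <- rep(seq_len(k), length.out = nSig)

  if (is.null(baseMean)) {
    baseMean <- stats::rnorm(g, mean = 4, sd = 1)
    # housekeeping genes sit at the typical baseline so that their raw-scale
    # variance is small both relatively (CV) and absolutely
    baseMean[hkIdx] <- 4
  } else if (length(baseMean) != g) {
    stop("baseMean must have length nGenes")
  }
  logX <- matrix(stats::rnorm(g * n, 0, config@noiseSD), g, n) + baseMean
  for (i in sigIdx)
    logX[i, clusters == sigCluster[i]] <-
      logX[i, clusters == sigCluster[i]] + config@effectSize
  if (nHk > 0) {
    sdHk <- sqrt(log(1 + config@housekeepingCV^2))
    logX[hkIdx, ] <- baseMean[hkIdx] +
      matrix(stats::rnorm(nHk * n, 0, sdHk), nHk, n)
  }

  r2vec <- rep(NA_real_, g)
  for (t in config@imputationTargets) {
    ti <- match(t$target, geneIds)
    pi <- match(t$predictors, geneIds)
    if (anyNA(c(ti, pi)))
      stop("imputation target/predictor gene ids must be among generated ",
           "gene ids (gene_001...)")
    if (role[ti] != "noise")
      stop("imputation target '", t$target,
           "' collides with a signature/housekeeping gene")
    P <- logX[pi, , drop = FALSE]
    signal <- if (t$form == "linear") {
      colSums(P)
    } else {
      if (length(pi) < 2)
        stop("interaction form needs >= 2 predictors")
      sc <- scale(t(P[1:2, , drop = FALSE]))
      sc[, 1] * sc[, 2]
    }
    signal <- as.numeric(scale(signal))
    sdNoise <- sqrt((1 - t$r2) / t$r2)
    logX[ti, ] <- baseMean[ti] + signal + stats::rnorm(n, 0, sdNoise)
    role[ti] <- "target"
    r2vec[ti] <- t$r2
  }

  x <- exp(logX)
  dimnames(x) <- list(geneIds, sampleIds)
  names(clusters) <- sampleIds
  list(matrix = x, clusters = clusters,
       genes = data.frame(gene_id = geneIds, role = role,
                          cluster = sigCluster, r2 = r2vec),
       baseMean = baseMean)
}
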