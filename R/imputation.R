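#' Select a shared housekeeping normalizer across two datasets
#'
#' Candidates are genes present with all-nonzero expression in both
#' datasets whose expression variance falls in the lower `pct` percentile
#' in *both*. The chosen normalizer minimizes the sum of its variance ranks
#' across the two datasets (ties broken by lexicographically smallest gene
#' id).
#'
#' @param ref,target genes x samples matrices with gene row names.
#' @param pct variance percentile cutoff (default 0.20).
#' @return A [HousekeepingSelection-class].
#' @export
selectHousekeeping <- function(ref, target, pct = 0.20) {
  shared <- intersect(rownames(ref), rownames(target))
  nz <- shared[apply(ref[shared, , drop = FALSE] > 0, 1, all) &
                 apply(target[shared, , drop = FALSE] > 0, 1, all)]
  if (length(nz) < 5)
    stop("need >= 5 shared genes with all-nonzero expression; got ",
         length(nz))
  vRef <- apply(ref[nz, , drop = FALSE], 1, stats::var)
  vTar <- apply(target[nz, , drop = FALSE], 1, stats::var)
  lowRef <- vRef <= stats::quantile(vRef, pct)
  lowTar <- vTar <= stats::quantile(vTar, pct)
  candidates <- nz[lowRef & lowTar]
  if (length(candidates) == 0)
    stop("no shared gene in the lower ", pct * 100,
         "th variance percentile of both datasets; try a larger pct")
  rankSum <- (rank(vRef, ties.method = "min") +
                rank(vTar, ties.method = "min"))[nz %in% candidates]
  best <- candidates[rankSum == min(rankSum)]
  chosen <- sort(best)[1]
  new("HousekeepingSelection", candidates = candidates, chosenGene = chosen,
      variances = data.frame(gene_id = nz, var_ref = vRef, var_target = vTar,
                             row.names = NULL),
      pct = pct)
}

#' Normalize an expression matrix by a housekeeping gene
#'
#' Divides every gene value in a sample by that sample's value of the
#' housekeeping gene, making the two platforms comparable on a
#' within-sample ratio scale. The housekeeping row becomes exactly 1, and
#' the operation is idempotent.
#'
#' @param expr genes x samples matrix.
#' @param hk housekeeping gene id (row of `expr`).
#' @return Normalized matrix of the same shape.
#' @export
normalizeByHousekeeping <- function(expr, hk) {
  if (!hk %in% rownames(expr)) stop("housekeeping gene '", hk, "' not found")
  denom <- expr[hk, ]
  zero <- denom == 0
  if (any(zero))
    stop("housekeeping gene is zero in sample(s): ",
         paste(colnames(expr)[zero], collapse = ", "))
  sweep(expr, 2, denom, "/")
}

#' Shadow-feature (Boruta-style) all-relevant predictor selection
#'
#' Each iteration appends a column-permuted shadow copy of every predictor,
#' fits a random-forest regressor, and records which real predictors beat
#' the maximum shadow importance (a "hit"). Undecided predictors are tested
#' each round with a two-sided binomial test of the hit count against
#' chance (p = 0.5) at level `alpha`, Bonferroni-corrected across the
#' predictors still undecided in that round: significantly-above-chance
#' predictors are confirmed, significantly-below rejected. Predictors still
#' undecided after `maxIter` iterations are reported tentative. Shadow
#' features are never candidates, so none can be confirmed.
#'
#' @param X samples x predictors matrix with column names.
#' @param y numeric target vector.
#' @param maxIter maximum iterations (default 100).
#' @param alpha binomial test level (default 0.01).
#' @param nTrees trees per forest (default 100).
#' @param seed integer seed.
#' @return List: `confirmed`, `rejected`, `tentative` (character vectors)
#'   and `hits` (per-predictor hit counts over the rounds run).
#' @export
borutaSelect <- function(X, y, maxIter = 100, alpha = 0.01, nTrees = 100,
                         seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need >= 2 predictors")
  if (nrow(X) < 10) stop("need >= 10 samples")
  if (stats::sd(y) == 0) stop("constant target y")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  status <- rep("undecided", p)
  names(status) <- colnames(X)
  hits <- integer(p); names(hits) <- colnames(X)
  set.seed(seed)
  iter <- 0L
  while (iter < maxIter && any(status == "undecided")) {
    iter <- iter + 1L
    active <- status != "rejected"
    shadows <- apply(X, 2, sample)
    colnames(shadows) <- paste0(".shadow_", colnames(X))
    Z <- cbind(X[, active, drop = FALSE], shadows)
    fit <- ranger::ranger(x = as.data.frame(Z), y = y,
                          num.trees = nTrees, importance = "impurity",
                          seed = seed + iter, num.threads = 1)
    imp <- fit$variable.importance
    shadowMax <- max(imp[grepl("^\\.shadow_", names(imp))])
    real <- imp[!grepl("^\\.shadow_", names(imp))]
    hit <- names(real)[real > shadowMax]
    hits[hit] <- hits[hit] + 1L
    und <- names(status)[status == "undecided"]
    m <- length(und)
    for (v in und) {
      pv <- stats::binom.test(hits[[v]], iter, 0.5)$p.value
      if (pv * m < alpha)
        status[v] <- if (hits[[v]] / iter > 0.5) "confirmed" else "rejected"
    }
  }
  list(confirmed = names(status)[status == "confirmed"],
       rejected = names(status)[status == "rejected"],
       tentative = names(status)[status == "undecided"],
       hits = hits, iterations = iter)
}

#' Train a per-gene random-forest imputation model
#'
#' Fits a random-forest regressor of the target gene on its confirmed
#' predictors over the housekeeping-normalized reference samples. Held-out
#' Pearson r from a 25% split is stored in the model metadata, computed on
#' the log scale (expression noise is multiplicative, so correlation of
#' log values is the scale on which imputation quality is interpretable);
#' models with held-out r below `qualityCutoff` are flagged low-quality.
#' The final model is refit on all reference samples.
#'
#' @param refNorm normalized genes x samples reference matrix.
#' @param targetGene gene to impute.
#' @param predictors confirmed predictor gene ids.
#' @param housekeepingGene normalizer used (metadata).
#' @param nTrees trees (default 300).
#' @param qualityCutoff low-quality flag threshold on held-out r
#'   (default 0.5).
#' @param seed integer seed.
#' @return An [ImputationModel-class].
#' @export
trainImputer <- function(refNorm, targetGene, predictors,
                         housekeepingGene = NA_character_, nTrees = 300,
                         qualityCutoff = 0.5, seed = 1L) {
  missing <- setdiff(c(targetGene, predictors), rownames(refNorm))
  if (length(missing))
    stop("genes absent from reference: ", paste(missing, collapse = ", "))
  n <- ncol(refNorm)
  if (n < 20) stop("need >= 20 training samples; got ", n)
  y <- as.numeric(refNorm[targetGene, ])
  X <- as.data.frame(t(refNorm[predictors, , drop = FALSE]))
  set.seed(seed)
  held <- sample.int(n, max(5, round(0.25 * n)))
  fit <- randomForest::randomForest(x = X[-held, , drop = FALSE],
                                    y = y[-held], ntree = nTrees)
  pred <- stats::predict(fit, X[held, , drop = FALSE])
  lp <- log(pmax(pred, .Machine$double.eps))
  ly <- log(pmax(y[held], .Machine$double.eps))
  r <- if (stats::sd(lp) == 0 || stats::sd(ly) == 0) 0 else
    stats::cor(lp, ly)
  full <- randomForest::randomForest(x = X, y = y, ntree = nTrees)
  new("ImputationModel", targetGene = targetGene,
      predictors = predictors, model = full,
      housekeepingGene = housekeepingGene,
      meta = list(nSamples = n, heldOutR = r,
                  lowQuality = r < qualityCutoff, seed = seed))
}

#' Impute a gene in a target dataset
#'
#' Predicts the target gene's normalized expression for every sample of
#' the (housekeeping-normalized) target matrix using a trained
#' [ImputationModel-class]. The output carries `imputed = TRUE` and the
#' model's stored held-out quality so downstream analyses can label
#' imputed values explicitly.
#'
#' @param model an [ImputationModel-class].
#' @param targetNorm normalized genes x samples target matrix.
#' @return Named numeric vector of predictions with attributes `"imputed"`
#'   (TRUE), `"heldOutR"` and `"lowQuality"`.
#' @export
imputeGene <- function(model, targetNorm) {
  stopifnot(is(model, "ImputationModel"))
  if (ncol(targetNorm) == 0) {
    out <- numeric(0)
    attr(out, "imputed") <- TRUE
    return(out)
  }
  missing <- setdiff(model@predictors, rownames(targetNorm))
  if (length(missing))
    stop("predictor(s) absent from target: ",
         paste(missing, collapse = ", "))
  X <- as.data.frame(t(targetNorm[model@predictors, , drop = FALSE]))
  out <- as.numeric(stats::predict(model@model, X))
  names(out) <- colnames(targetNorm)
  attr(out, "imputed") <- TRUE
  attr(out, "heldOutR") <- model@meta$heldOutR
  attr(out, "lowQuality") <- model@meta$lowQuality
  out
}

#' End-to-end imputation of one gene across platforms
#'
#' Convenience wrapper chaining [selectHousekeeping()],
#' [normalizeByHousekeeping()] on both datasets, [borutaSelect()] over the
#' candidate predictors, [trainImputer()] on the reference and
#' [imputeGene()] on the target.
#'
#' @param ref,target genes x samples matrices.
#' @param targetGene gene failing QC in `target`, present in `ref`.
#' @param candidatePredictors predictor pool; default all shared genes
#'   except the target and the housekeeping normalizer.
#' @param pct housekeeping variance percentile (default 0.20).
#' @param seed integer seed.
#' @param ... passed to [borutaSelect()].
#' @return List: `imputed` (flagged vector), `model`, `housekeeping`,
#'   `selection` (boruta output).
#' @export
imputeAcrossPlatforms <- function(ref, target, targetGene,
                                  candidatePredictors = NULL, pct = 0.20,
                                  seed = 1L, ...) {
  hk <- selectHousekeeping(ref, target, pct = pct)
  refN <- normalizeByHousekeeping(ref, chosenGene(hk))
  tarN <- normalizeByHousekeeping(target, chosenGene(hk))
  if (is.null(candidatePredictors))
    candidatePredictors <- setdiff(intersect(rownames(ref), rownames(target)),
                                   c(targetGene, chosenGene(hk)))
  sel <- borutaSelect(t(refN[candidatePredictors, , drop = FALSE]),
                      as.numeric(refN[targetGene, ]), seed = seed, ...)
  preds <- sel$confirmed
  if (length(preds) == 0)
    stop("no predictor confirmed for '", targetGene, "'")
  model <- trainImputer(refN, targetGene, preds,
                        housekeepingGene = chosenGene(hk), seed = seed)
  list(imputed = imputeGene(model, tarN), model = model,
       housekeeping = hk, selection = sel)
}
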