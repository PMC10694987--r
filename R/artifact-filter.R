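#' Train the positive/negative signal classifier
#'
#' Fits a random forest over the intensity/texture/morphology feature
#' columns of a labelled cell feature table to separate true staining
#' (`positive`) from low-intensity artifacts (`negative`), the filtering
#' step applied before any image statistic. A stratified held-out split
#' reports out-of-sample accuracy in the classifier metadata.
#'
#' @param table cell feature table with a `signal_label` column holding
#'   `"positive"` / `"negative"` training labels.
#' @param features feature columns to use; default [featureColumns()]
#'   `"signal"` set.
#' @param nTrees number of trees (default 200).
#' @param holdOut fraction held out for the accuracy estimate (default 0.25).
#' @param seed integer seed.
#' @return A [SignalClassifier-class].
#' @export
trainSignalClassifier <- function(table, features = featureColumns("signal"),
                                  nTrees = 200, holdOut = 0.25, seed = 1L) {
  if (!"signal_label" %in% names(table)) stop("missing signal_label column")
  y <- factor(table$signal_label, levels = c("negative", "positive"))
  if (anyNA(y)) stop("signal_label must be 'positive' or 'negative'")
  if (any(table(y) < 2))
    stop("need at least 2 examples per class; got ",
         paste(table(y), collapse = "/"))
  missing <- setdiff(features, names(table))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  X <- as.data.frame(table[, features, drop = FALSE])
  set.seed(seed)
  heldIdx <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(1, round(holdOut * length(ix))))))
  trainIdx <- setdiff(seq_along(y), heldIdx)
  if (any(table(y[trainIdx]) < 1))
    stop("held-out split left a class empty; add training examples")
  fit <- randomForest::randomForest(x = X[trainIdx, , drop = FALSE],
                                    y = y[trainIdx], ntree = nTrees)
  pred <- stats::predict(fit, X[heldIdx, , drop = FALSE])
  acc <- mean(pred == y[heldIdx])
  new("SignalClassifier", model = fit, features = features,
      meta = list(nTrain = length(trainIdx),
                  classBalance = as.list(table(y[trainIdx])),
                  heldOutAccuracy = acc, seed = seed))
}

#' Classify and filter segmented objects
#'
#' Removes rows the classifier labels `negative` and rows with
#' `area < minArea` (degenerate small objects). Idempotent; feature values
#' are never modified. Removal counts per image are attached as the
#' `"removalLog"` attribute.
#'
#' @param table cell feature table.
#' @param classifier a [SignalClassifier-class].
#' @param minArea minimum object area in px^2 (default 1).
#' @return Filtered table (subset of input rows) with updated
#'   `signal_label`.
#' @export
filterObjects <- function(table, classifier, minArea = 1) {
  stopifnot(is(classifier, "SignalClassifier"))
  missing <- setdiff(classifier@features, names(table))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  if (nrow(table) == 0) return(table)
  pred <- stats::predict(classifier@model,
                         as.data.frame(table[, classifier@features,
                                             drop = FALSE]))
  keep <- pred == "positive" & table$area >= minArea
  out <- table[keep, , drop = FALSE]
  out$signal_label <- "positive"
  log <- stats::aggregate(list(removed = !keep),
                          by = list(image_id = table$image_id), FUN = sum)
  attr(out, "removalLog") <- log
  out
}
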