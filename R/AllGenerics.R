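#' Accessors for gliopath result objects
#'
#' Small accessor family so downstream code never reaches into slots:
#' `clusterLabels()` returns cluster assignments, `empiricalP()` the
#' permutation p-value, `chosenGene()` the housekeeping normalizer,
#' `clampRate()` the deconvolution clamp rate and `stainNames()` the
#' stain order of a [ConcentrationImage-class].
#'
#' @param x a gliopath result object.
#' @return The accessed component (vector, scalar or character).
#' @examples
#' ci <- deconvolve(array(0, c(2, 2, 3)), stainVectors("HDAB"))
#' clampRate(ci)
#' stainNames(ci)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' @rdname accessors
#' @export
setGeneric("chosenGene", function(x) standardGeneric("chosenGene"))

#' @rdname accessors
#' @export
setGeneric("clampRate", function(x) standardGeneric("clampRate"))

#' @rdname accessors
#' @export
setGeneric("stainNames", function(x) standardGeneric("stainNames"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@cluster)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "MorphoClusterResult", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("empiricalP", "PermutationTestResult", function(x) x@empiricalP)

#' @rdname accessors
#' @export
setMethod("chosenGene", "HousekeepingSelection", function(x) x@chosenGene)

#' @rdname accessors
#' @export
setMethod("clampRate", "ConcentrationImage", function(x) x@clampRate)

#' @rdname accessors
#' @export
setMethod("stainNames", "ConcentrationImage", function(x) x@stainNames)

setMethod("show", "ConcentrationImage", function(object) {
  d <- dim(object@pixels)
  cat("ConcentrationImage", d[1], "x", d[2], "\n")
  cat("  stains:", paste(object@stainNames, collapse = ", "), "\n")
  cat("  clamp rate:", format(object@clampRate, digits = 4), "\n")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@cluster), "samples in k =",
      object@k, "clusters\n")
  print(table(object@cluster))
})

setMethod("show", "PermutationTestResult", function(object) {
  cat("PermutationTestResult\n")
  cat("  separation (between - within):",
      format(object@observedSeparation, digits = 4), "\n")
  cat("  empirical p:", format(object@empiricalP, digits = 4),
      "(", object@nPerm, "permutations )\n")
})

setMethod("show", "MorphoClusterResult", function(object) {
  cat("MorphoClusterResult [", object@stain, "]\n")
  nRet <- nrow(object@contingency)
  cat("  cells:", length(object@labels), "; retained clusters:", nRet,
      "; noise:", sum(object@labels == -1L), "\n")
  cat("  chi2 =", format(object@chi2Stat, digits = 5), ", df =",
      object@chi2Df, ", p =", format(object@chi2P, digits = 3), "\n")
})

setMethod("show", "HousekeepingSelection", function(object) {
  cat("HousekeepingSelection:", length(object@candidates),
      "candidates; chosen:", object@chosenGene, "\n")
})

setMethod("show", "ImputationModel", function(object) {
  cat("ImputationModel for", object@targetGene, "\n")
  cat("  predictors:", length(object@predictors),
      "; held-out r:", format(object@meta$heldOutR, digits = 3), "\n")
})

setMethod("show", "SignalClassifier", function(object) {
  cat("SignalClassifier over", length(object@features), "features\n")
  cat("  held-out accuracy:",
      format(object@meta$heldOutAccuracy, digits = 3), "\n")
})
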