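#' @import methods
NULL

#' Configuration for the synthetic IHC image generator
#'
#' Describes a simulated brightfield field of view: image geometry, how many
#' nuclei to draw, the morphology subpopulations they are sampled from, the
#' fraction of DAB-positive nuclei, stain optical densities and background
#' noise. Nuclei are rendered as filled ellipses with uniform interior stain
#' concentration under a Beer-Lambert imaging model, so every downstream
#' measurement has an analytic ground truth.
#'
#' @slot width,height image size in pixels.
#' @slot nCells number of true nuclei to draw.
#' @slot populations `data.frame` with columns `fraction`, `meanRadius`,
#'   `radiusSD`, `eccentricity`; fractions must sum to 1.
#' @slot dabPositiveFraction probability that a nucleus also carries DAB.
#' @slot hematoxylinODMean,dabODMean interior stain concentration, in optical
#'   density units along the respective unit stain vector.
#' @slot backgroundNoiseSD additive Gaussian noise on the OD image.
#' @slot allowOverlap if `FALSE`, nuclei are placed by rejection sampling so
#'   that no two overlap.
#' @slot artifactFraction extra low-intensity decoy objects, as a fraction of
#'   `nCells`; rendered at `artifactODFraction` of the hematoxylin OD and
#'   flagged `is_artifact` in the truth table (never in the label mask).
#' @slot artifactODFraction relative OD of artifact objects (default 0.2).
#' @slot seed integer seed; identical seeds give bit-identical output.
#' @export
setClass("ImageSimConfig",
  representation(
    width = "numeric", height = "numeric", nCells = "numeric",
    populations = "data.frame", dabPositiveFraction = "numeric",
    hematoxylinODMean = "numeric", dabODMean = "numeric",
    backgroundNoiseSD = "numeric", allowOverlap = "logical",
    artifactFraction = "numeric", artifactODFraction = "numeric",
    seed = "numeric"
  )
)

setValidity("ImageSimConfig", function(object) {
  msg <- character()
  if (object@width < 1 || object@height < 1)
    msg <- c(msg, "width and height must be >= 1")
  if (object@nCells < 0) msg <- c(msg, "nCells must be >= 0")
  pop <- object@populations
  need <- c("fraction", "meanRadius", "radiusSD", "eccentricity")
  if (!all(need %in% names(pop)))
    msg <- c(msg, paste("populations must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (abs(sum(pop$fraction) - 1) > 1e-9)
      msg <- c(msg, "population fractions must sum to 1 (tol 1e-9)")
    if (any(pop$eccentricity < 0 | pop$eccentricity >= 1))
      msg <- c(msg, "eccentricity must be in [0, 1)")
    if (any(pop$meanRadius <= 0))
      msg <- c(msg, "meanRadius must be > 0")
  }
  if (object@dabPositiveFraction < 0 || object@dabPositiveFraction > 1)
    msg <- c(msg, "dabPositiveFraction must be in [0, 1]")
  if (object@hematoxylinODMean < 0 || object@dabODMean < 0)
    msg <- c(msg, "stain OD means must be >= 0")
  if (object@backgroundNoiseSD < 0)
    msg <- c(msg, "backgroundNoiseSD must be >= 0")
  if (object@artifactFraction < 0 || object@artifactFraction > 1)
    msg <- c(msg, "artifactFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an [ImageSimConfig-class]
#'
#' @param width,height image size in pixels.
#' @param nCells number of nuclei.
#' @param populations morphology subpopulations; `data.frame` with columns
#'   `fraction`, `meanRadius` (px), `radiusSD` (px), `eccentricity`.
#' @param dabPositiveFraction fraction of DAB-positive nuclei.
#' @param hematoxylinODMean,dabODMean interior stain concentrations (OD units).
#' @param backgroundNoiseSD Gaussian OD noise standard deviation.
#' @param allowOverlap allow nuclei to overlap?
#' @param artifactFraction decoy objects as a fraction of `nCells`.
#' @param artifactODFraction relative hematoxylin OD of decoys.
#' @param seed integer seed.
#' @return An `ImageSimConfig` object.
#' @examples
#' cfg <- imageSimConfig(nCells = 20, seed = 1)
#' @export
imageSimConfig <- function(width = 256, height = 256, nCells = 100,
                           populations = data.frame(
                             fraction = 1, meanRadius = 8,
                             radiusSD = 1.5, eccentricity = 0.4),
                           dabPositiveFraction = 0.3,
                           hematoxylinODMean = 0.7, dabODMean = 0.6,
                           backgroundNoiseSD = 0.01, allowOverlap = FALSE,
                           artifactFraction = 0, artifactODFraction = 0.2,
                           seed = 1L) {
  new("ImageSimConfig", width = width, height = height, nCells = nCells,
      populations = populations, dabPositiveFraction = dabPositiveFraction,
      hematoxylinODMean = hematoxylinODMean, dabODMean = dabODMean,
      backgroundNoiseSD = backgroundNoiseSD, allowOverlap = allowOverlap,
      artifactFraction = artifactFraction,
      artifactODFraction = artifactODFraction, seed = seed)
}

#' Configuration for the synthetic expression generator
#'
#' Describes a genes-by-samples matrix with `kClusters` latent sample groups:
#' signature genes carry a log-scale shift in their assigned cluster,
#' housekeeping genes have a small fixed coefficient of variation, and
#' optional imputation-target genes are generated as functions of named
#' predictor genes at a specified true R-squared (in log space). Values are
#' log-normal, hence strictly positive.
#'
#' @slot nSamples,nGenes matrix dimensions.
#' @slot kClusters number of latent sample clusters (>= 1).
#' @slot signatureSize number of signature genes.
#' @slot effectSize log-scale shift added to a signature gene in its cluster.
#' @slot noiseSD log-scale residual noise.
#' @slot nHousekeeping number of low-variance housekeeping genes.
#' @slot housekeepingCV target coefficient of variation of housekeeping genes.
#' @slot imputationTargets list of lists with elements `target`, `predictors`
#'   (gene ids), `form` ("linear" or "interaction"), `r2` in (0, 1).
#' @slot seed integer seed.
#' @export
setClass("ExprSimConfig",
  representation(
    nSamples = "numeric", nGenes = "numeric", kClusters = "numeric",
    signatureSize = "numeric", effectSize = "numeric", noiseSD = "numeric",
    nHousekeeping = "numeric", housekeepingCV = "numeric",
    imputationTargets = "list", seed = "numeric"
  )
)

setValidity("ExprSimConfig", function(object) {
  msg <- character()
  if (object@kClusters < 1) msg <- c(msg, "kClusters must be >= 1")
  if (object@kClusters > object@nSamples)
    msg <- c(msg, "kClusters must not exceed nSamples")
  nTarget <- length(object@imputationTargets)
  if (object@signatureSize + object@nHousekeeping + nTarget > object@nGenes)
    msg <- c(msg, "signatureSize + nHousekeeping + targets must be <= nGenes")
  for (t in object@imputationTargets) {
    if (!all(c("target", "predictors", "form", "r2") %in% names(t)))
      msg <- c(msg, "each imputation target needs target/predictors/form/r2")
    else {
      if (!t$form %in% c("linear", "interaction"))
        msg <- c(msg, "imputation form must be 'linear' or 'interaction'")
      if (t$r2 <= 0 || t$r2 >= 1)
        msg <- c(msg, "imputation r2 must be in (0, 1)")
    }
  }
  if (object@noiseSD < 0 || object@housekeepingCV < 0)
    msg <- c(msg, "noiseSD and housekeepingCV must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an [ExprSimConfig-class]
#'
#' @param nSamples,nGenes matrix dimensions.
#' @param kClusters number of latent sample clusters.
#' @param signatureSize number of cluster-informative signature genes.
#' @param effectSize log-scale cluster shift of signature genes.
#' @param noiseSD log-scale residual standard deviation.
#' @param nHousekeeping number of housekeeping genes.
#' @param housekeepingCV coefficient of variation of housekeeping genes;
#'   should be well below `noiseSD`.
#' @param imputationTargets list of target specifications (see
#'   [ExprSimConfig-class]); predictor gene ids refer to generated noise
#'   genes, e.g. `"gene_020"`.
#' @param seed integer seed.
#' @return An `ExprSimConfig` object.
#' @examples
#' cfg <- exprSimConfig(nSamples = 60, nGenes = 200, kClusters = 3)
#' @export
exprSimConfig <- function(nSamples = 109, nGenes = 500, kClusters = 3,
                          signatureSize = 83, effectSize = 1.5,
                          noiseSD = 0.5, nHousekeeping = 10,
                          housekeepingCV = 0.02,
                          imputationTargets = list(), seed = 1L) {
  new("ExprSimConfig", nSamples = nSamples, nGenes = nGenes,
      kClusters = kClusters, signatureSize = signatureSize,
      effectSize = effectSize, noiseSD = noiseSD,
      nHousekeeping = nHousekeeping, housekeepingCV = housekeepingCV,
      imputationTargets = imputationTargets, seed = seed)
}

#' Per-stain concentration image
#'
#' Result of linear color deconvolution: an H x W x 3 array of per-stain
#' concentrations (OD units along each unit stain vector), together with the
#' stain names and the fraction of entries that were negative before being
#' clamped to zero.
#'
#' @slot pixels H x W x 3 numeric array, clamped at 0.
#' @slot stainNames ordered character triple.
#' @slot clampRate fraction of pixel-channel entries clamped to 0.
#' @export
setClass("ConcentrationImage",
  representation(pixels = "array", stainNames = "character",
                 clampRate = "numeric")
)

setValidity("ConcentrationImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3) return("pixels must be an H x W x 3 array")
  if (length(object@stainNames) != 3) return("stainNames must have length 3")
  if (any(object@pixels < 0)) return("concentrations must be >= 0 (clamped)")
  TRUE
})

#' Trained positive/negative signal classifier
#'
#' A random-forest classifier over cell feature columns that labels segmented
#' objects as `positive` (true staining) or `negative` (low-intensity
#' artifact), used by [filterObjects()].
#'
#' @slot model the fitted `randomForest` object.
#' @slot features feature column names used at training time.
#' @slot meta list with `nTrain`, `classBalance`, `heldOutAccuracy`, `seed`.
#' @export
setClass("SignalClassifier",
  representation(model = "ANY", features = "character", meta = "list")
)

#' Sample cluster assignment with silhouette-based k selection
#'
#' @slot cluster named integer vector, sample id -> cluster in 1..k.
#' @slot k selected number of clusters.
#' @slot silhouetteByK `data.frame` with columns `k`, `meanSilhouette`.
#' @slot seed seed used.
#' @export
setClass("ClusterAssignment",
  representation(cluster = "integer", k = "numeric",
                 silhouetteByK = "data.frame", seed = "numeric")
)

setValidity("ClusterAssignment", function(object) {
  if (length(object@cluster) == 0) return("empty assignment")
  if (!all(object@cluster %in% seq_len(object@k)))
    return("cluster labels must lie in 1..k")
  TRUE
})

#' Permutation test of cluster separation
#'
#' Observed mean within- and between-cluster distances, the permutation null
#' of the separation statistic (between minus within), and the one-sided
#' empirical p-value.
#'
#' @slot observedWithin,observedBetween,observedSeparation observed statistics.
#' @slot nullSeparations numeric vector of length `nPerm`.
#' @slot empiricalP `(1 + #\{null >= observed\}) / (nPerm + 1)`.
#' @slot nPerm,nSampledPairs,seed test parameters.
#' @export
setClass("PermutationTestResult",
  representation(observedWithin = "numeric", observedBetween = "numeric",
                 observedSeparation = "numeric", nullSeparations = "numeric",
                 empiricalP = "numeric", nPerm = "numeric",
                 nSampledPairs = "numeric", seed = "numeric")
)

setValidity("PermutationTestResult", function(object) {
  if (length(object@nullSeparations) != object@nPerm)
    return("nullSeparations must have length nPerm")
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    return("empiricalP must be in (0, 1]")
  TRUE
})

#' Morphology clustering result for one stain
#'
#' @slot stain stain name.
#' @slot embedding per-cell 2-D coordinates.
#' @slot labels integer cluster labels; -1 denotes noise.
#' @slot contingency retained clusters x groups count table.
#' @slot chi2Stat,chi2Df,chi2P Pearson chi-square of the contingency table.
#' @slot nPerGroup balanced subsample size per group.
#' @slot omittedClusters clusters relabelled to noise for being smaller than
#'   the minimum cluster size.
#' @slot seed seed used.
#' @export
setClass("MorphoClusterResult",
  representation(stain = "character", embedding = "matrix",
                 labels = "integer", contingency = "matrix",
                 chi2Stat = "numeric", chi2Df = "numeric", chi2P = "numeric",
                 nPerGroup = "numeric", omittedClusters = "integer",
                 seed = "numeric")
)

#' Housekeeping-gene selection across two expression datasets
#'
#' @slot candidates genes in the lower variance percentile in both datasets.
#' @slot chosenGene the normalizer: minimal summed variance rank.
#' @slot variances `data.frame` of per-dataset variances of shared genes.
#' @slot pct variance percentile cutoff used.
#' @export
setClass("HousekeepingSelection",
  representation(candidates = "character", chosenGene = "character",
                 variances = "data.frame", pct = "numeric")
)

#' Per-gene random-forest imputation model
#'
#' @slot targetGene imputed gene id.
#' @slot predictors confirmed predictor genes.
#' @slot model fitted `randomForest` regressor.
#' @slot housekeepingGene normalizer used on both datasets.
#' @slot meta list with `nSamples`, `heldOutR`, `lowQuality`, `seed`.
#' @export
setClass("ImputationModel",
  representation(targetGene = "character", predictors = "character",
                 model = "ANY", housekeepingGene = "character",
                 meta = "list")
)
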