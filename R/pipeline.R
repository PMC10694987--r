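pipelineDefaults <- function() {
  list(stainPanel = "HDAB", i0 = 255, eps = 1, nBins = 256,
       connectivity = 8, minArea = 1, knnK = 100, nPerGroup = 8000,
       minClusterSize = 160, minSamples = 5, umapNeighbors = 15,
       umapMinDist = 0.1, kRange = 2:10, nInit = 25, perplexity = 10,
       nPerm = 10000, nSampledPairs = 10000, housekeepingPct = 0.20,
       logTransform = TRUE, seed = 1L)
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML file of pipeline parameters, rejects unknown keys and fills
#' unset parameters with the documented defaults (k = 100 neighbors, 8,000
#' cells per group, 160-cell minimum cluster, 10,000 permutations, 20th
#' variance percentile, ...).
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return Named list of parameters.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- pipelineDefaults()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

configFingerprint <- function(cfg) {
  # stable fingerprint of the effective configuration for output manifests
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), ""), sep = "=",
    collapse = ";")
  raw <- utils::head(serialize(s, NULL, ascii = TRUE), 10000)
  sum(as.integer(raw) * seq_along(raw)) %% 2147483647
}

stageSeed <- function(seed, stage) as.integer(seed) + stage

#' Run the image analysis arm
#'
#' Executes the full image chain on a batch of images: color deconvolution,
#' Otsu thresholding of the hematoxylin and DAB channels, connected-component
#' labelling of the hematoxylin mask, per-cell feature extraction, optional
#' artifact filtering, image-level spatial statistics, and (when requested)
#' morphology clustering across the batch. Deterministic for a given
#' config + seed.
#'
#' @param inputs list of image inputs; each element is either a list with an
#'   `config` ([ImageSimConfig-class], simulated on the fly) or an `rgb`
#'   array, plus `imageId`, `group`, `region`.
#' @param config parameter list from [readPipelineConfig()].
#' @param classifier optional [SignalClassifier-class] for artifact
#'   filtering.
#' @param morphology `NULL` or a list with at least `eps` to run morphology
#'   clustering over the batch (optional overrides: `nPerGroup`,
#'   `minClusterSize`, `minSamples`, `stain`).
#' @param outDir optional directory; writes `image_stats.csv`,
#'   `cell_features.csv`, `morphology.json` and `manifest.json`.
#' @return List: `stats` (one [imageStatRecord()] row per image),
#'   `features` (pooled cell feature table), `morphology`
#'   ([MorphoClusterResult-class] or `NULL`), `manifest`.
#' @export
runImageArm <- function(inputs, config = readPipelineConfig(),
                        classifier = NULL, morphology = NULL,
                        outDir = NULL) {
  if (length(inputs) == 0) stop("no input images")
  stains <- stainVectors(config$stainPanel)
  secondStain <- rownames(stains)[2]
  statsList <- list(); featList <- list()
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    imageId <- if (!is.null(inp$imageId)) inp$imageId else paste0("image_", i)
    if (is.null(inp$group)) inp$group <- NA_character_
    if (is.null(inp$region)) inp$region <- NA_character_
    rgb <- if (!is.null(inp$config)) {
      simulateIHCImage(inp$config, stains, i0 = config$i0,
                       eps = config$eps)$rgb
    } else inp$rgb
    if (is.null(rgb)) stop("input ", i, " has neither 'config' nor 'rgb'")
    od <- rgbToOD(rgb, i0 = config$i0, eps = config$eps)
    conc <- deconvolve(od, stains)
    hemaCh <- suppressWarnings(stainChannel(conc, "hematoxylin"))
    dabCh <- suppressWarnings(stainChannel(conc, secondStain))
    hemaMask <- binarize(hemaCh, otsuThreshold(hemaCh, config$nBins))
    dabMask <- tryCatch(
      binarize(dabCh, otsuThreshold(dabCh, config$nBins)),
      error = function(e) matrix(0L, nrow(dabCh), ncol(dabCh)))
    lab <- labelComponents(hemaMask, config$connectivity)
    feats <- extractCellFeatures(lab, hemaCh, imageId = imageId,
                                 group = inp$group, region = inp$region)
    if (!is.null(classifier))
      feats <- filterObjects(feats, classifier, minArea = config$minArea)
    else
      feats <- feats[feats$area >= config$minArea, , drop = FALSE]
    statsList[[i]] <- imageStatRecord(imageId, feats, dabMask, hemaMask,
                                      group = inp$group,
                                      region = inp$region, k = config$knnK)
    featList[[i]] <- feats
  }
  stats <- do.call(rbind, statsList)
  features <- do.call(rbind, featList)
  morpho <- NULL
  if (!is.null(morphology)) {
    morpho <- morphologyCluster(
      features,
      stain = if (is.null(morphology$stain)) "hematoxylin" else
        morphology$stain,
      nPerGroup = if (is.null(morphology$nPerGroup)) config$nPerGroup else
        morphology$nPerGroup,
      eps = morphology$eps,
      minSamples = if (is.null(morphology$minSamples)) config$minSamples
      else morphology$minSamples,
      minClusterSize = if (is.null(morphology$minClusterSize))
        config$minClusterSize else morphology$minClusterSize,
      nNeighbors = config$umapNeighbors, minDist = config$umapMinDist,
      seed = stageSeed(config$seed, 6))
  }
  manifest <- list(configFingerprint = configFingerprint(config),
                   seed = config$seed, nImages = length(inputs),
                   imageIds = stats$image_id,
                   stages = c("deconvolve", "otsu", "label", "features",
                              if (!is.null(classifier)) "filter",
                              "spatial",
                              if (!is.null(morpho)) "morphology"))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(stats, file.path(outDir, "image_stats.csv"),
                     row.names = FALSE)
    writeFeatureTable(features, file.path(outDir, "cell_features.csv"))
    if (!is.null(morpho))
      jsonlite::write_json(
        list(stain = morpho@stain, chi2 = morpho@chi2Stat,
             df = morpho@chi2Df, p = morpho@chi2P,
             contingency = morpho@contingency, seed = morpho@seed,
             configFingerprint = manifest$configFingerprint),
        file.path(outDir, "morphology.json"), auto_unbox = TRUE,
        digits = NA)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(stats = stats, features = features, morphology = morpho,
       manifest = manifest)
}

#' Run the expression analysis arm
#'
#' Signature-gene stratification of samples: subset to the signature,
#' (optionally) log-transform, t-SNE embedding, kMeans with
#' silhouette-selected k, permutation validation of the clustering, and —
#' when two clusters and a binary diagnosis are available — the 2x2
#' cluster-vs-diagnosis chi-square with Yates continuity correction.
#'
#' @param expr genes x samples matrix.
#' @param signature character vector of signature genes, or `NULL` to use
#'   all genes.
#' @param diagnosis optional named factor/character of per-sample diagnosis
#'   (e.g. PD / psPD).
#' @param config parameter list from [readPipelineConfig()].
#' @param outDir optional output directory for `expression_arm.json`.
#' @return List: `assignment` ([ClusterAssignment-class]), `permutation`
#'   ([PermutationTestResult-class]), `embedding`, `chi2` (list or `NULL`),
#'   `manifest`.
#' @export
runExpressionArm <- function(expr, signature = NULL, diagnosis = NULL,
                             config = readPipelineConfig(), outDir = NULL) {
  if (!is.null(signature)) expr <- subsetSignature(expr, signature)
  X <- if (isTRUE(config$logTransform)) log1p(expr) else expr
  emb <- embedSamples(X, perplexity = config$perplexity,
                      seed = stageSeed(config$seed, 1))
  assignment <- kmeansSilhouette(t(X), kRange = config$kRange,
                                 nInit = config$nInit,
                                 seed = stageSeed(config$seed, 2))
  perm <- permutationClusterTest(t(X), assignment, nPerm = config$nPerm,
                                 nSampledPairs = config$nSampledPairs,
                                 seed = stageSeed(config$seed, 3))
  chi2 <- NULL
  if (!is.null(diagnosis)) {
    diag <- diagnosis[names(clusterLabels(assignment))]
    if (assignment@k == 2 && length(unique(diag)) == 2) {
      tab <- table(cluster = clusterLabels(assignment), diagnosis = diag)
      chi2 <- yatesChi2(unclass(tab))
      chi2$contingency <- unclass(tab)
    } else {
      message("cluster-vs-diagnosis chi-square skipped: needs k = 2 ",
              "clusters and 2 diagnosis levels")
    }
  }
  manifest <- list(configFingerprint = configFingerprint(config),
                   seed = config$seed, k = assignment@k,
                   empiricalP = empiricalP(perm))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(manifest = manifest,
           silhouetteByK = assignment@silhouetteByK,
           cluster = as.list(clusterLabels(assignment)),
           permutation = list(separation = perm@observedSeparation,
                              p = empiricalP(perm), nPerm = perm@nPerm),
           chi2 = chi2),
      file.path(outDir, "expression_arm.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(assignment = assignment, permutation = perm, embedding = emb,
       chi2 = chi2, manifest = manifest)
}
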