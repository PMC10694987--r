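# shared fixtures, all generated in code

hdab <- gliopath::stainVectors("HDAB")

# independent brute-force oracles ------------------------------------------

# Otsu oracle: exhaustive search over every candidate bin edge
otsuOracle <- function(img, nBins = 256) {
  v <- as.numeric(img)
  bin <- pmin(floor(v * nBins), nBins - 1)
  best <- -Inf
  bestK <- NA
  for (k in 1:(nBins - 1)) {
    lo <- v[bin < k]
    hi <- v[bin >= k]
    if (length(lo) == 0 || length(hi) == 0) next
    # class means computed from bin midpoints, as the histogram method does
    mids <- (bin + 0.5) / nBins
    m0 <- mean(mids[bin < k]); m1 <- mean(mids[bin >= k])
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (m0 - m1)^2
    if (s > best + 1e-15) { best <- s; bestK <- k }
  }
  bestK / nBins
}

# k-th nearest neighbor by full distance matrix and sort
knnOracle <- function(pts, k) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  vapply(seq_len(n), function(i) sort(d[i, -i])[k], numeric(1))
}

# Pearson chi-square by the definitional sum
chi2Oracle <- function(O, yates = FALSE) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  s <- 0
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    dev <- abs(O[i, j] - E[i, j])
    if (yates) dev <- max(dev - 0.5, 0)
    s <- s + dev^2 / E[i, j]
  }
  s
}

# small synthetic scene reused by feature/filter tests ----------------------

makeScene <- function(seed = 11, nCells = 60, artifactFraction = 0,
                      width = 420, height = 420, noise = 0.01) {
  cfg <- imageSimConfig(width = width, height = height, nCells = nCells,
                        artifactFraction = artifactFraction,
                        backgroundNoiseSD = noise, seed = seed)
  sim <- simulateIHCImage(cfg)
  conc <- deconvolve(rgbToOD(sim$rgb), hdab)
  ch <- suppressWarnings(stainChannel(conc, "hematoxylin"))
  list(sim = sim, channel = ch, conc = conc)
}

# feature table for objects in the generator's own label mask, so rows map
# 1:1 onto truth records
sceneFeatures <- function(scene, imageId = "img", group = "PD") {
  extractCellFeatures(scene$sim$labelMask, scene$channel,
                      imageId = imageId, group = group)
}

# gaussian blob data for clustering tests
makeBlobs <- function(k, nPer, sep, d = 2, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(nPer * d, sd = sd), nPer) +
      matrix(centers[i, ], nPer, d, byrow = TRUE)))
  list(x = X, labels = rep(seq_len(k), each = nPer))
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
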