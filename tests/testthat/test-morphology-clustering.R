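morphoTable <- function(n, group, radius = 8, seed = 1) {
  set.seed(seed)
  tab <- data.frame(matrix(rnorm(n * length(featureColumns("morphology"))),
                           n))
  names(tab) <- featureColumns("morphology")
  tab$group <- group
  tab$row_id <- paste0(group, "_", seq_len(n))
  tab
}

test_that("balanced subsampling is exact, deterministic and strict", {
  tab <- rbind(morphoTable(2000, "PD", seed = 1),
               morphoTable(900, "psPD", seed = 2))
  sub <- balancedSubsample(tab, nPerGroup = 800, seed = 5)
  expect_equal(unname(table(sub$group)), c(800, 800), ignore_attr = TRUE)
  sub2 <- balancedSubsample(tab, nPerGroup = 800, seed = 5)
  expect_identical(sub$row_id, sub2$row_id)
  sub3 <- balancedSubsample(tab, nPerGroup = 800, seed = 6)
  expect_false(identical(sub$row_id, sub3$row_id))
  # equal-size groups at nPerGroup = size: identity as a set
  eq <- rbind(morphoTable(500, "PD"), morphoTable(500, "psPD"))
  expect_setequal(balancedSubsample(eq, nPerGroup = 500, seed = 1)$row_id,
                  eq$row_id)
  expect_error(balancedSubsample(tab, nPerGroup = 1000, seed = 1),
               "psPD")
})

test_that("morphology embedding separates designed subpopulations", {
  pops <- data.frame(fraction = c(0.5, 0.5), meanRadius = c(6, 15),
                     radiusSD = c(0.8, 1.5), eccentricity = c(0.2, 0.7))
  cfg <- imageSimConfig(width = 900, height = 900, nCells = 150,
                        populations = pops, seed = 11)
  sim <- simulateIHCImage(cfg)
  ch <- suppressWarnings(
    stainChannel(deconvolve(rgbToOD(sim$rgb), hdab), "hematoxylin"))
  f <- extractCellFeatures(sim$labelMask, ch, "m1", "PD")
  emb <- embedMorphology(f, seed = 4)
  truePop <- sim$truth$cells$population
  sil <- mean(cluster::silhouette(truePop, dist(emb))[, "sil_width"])
  expect_gte(sil, 0.5)
  # determinism
  expect_identical(emb, embedMorphology(f, seed = 4))
  # constant column dropped with a warning, still runs
  f2 <- f; f2$theta <- 0
  expect_warning(emb2 <- embedMorphology(f2, seed = 4), "constant")
  expect_equal(nrow(emb2), nrow(f2))
})

test_that("density clustering finds blobs and enforces minimum size", {
  blobs <- makeBlobs(2, 1000, sep = 30, sd = 1, seed = 3)
  lab <- clusterEmbedding(blobs$x, eps = 1, minSamples = 5,
                          minClusterSize = 160)
  expect_equal(max(lab), 2)
  expect_gte(adjustedRand(lab[lab > 0], blobs$labels[lab > 0]), 0.99)
  # all points identical: one cluster holding everything
  same <- matrix(1, 50, 2)
  labSame <- clusterEmbedding(same, eps = 0.5, minSamples = 5,
                              minClusterSize = 10)
  expect_true(all(labSame == 1))
  # a 150-point blob dies at minClusterSize = 160
  mix <- rbind(makeBlobs(1, 1000, 0, sd = 1, seed = 4)$x,
               makeBlobs(1, 150, 0, sd = 1, seed = 5)$x +
                 matrix(c(50, 50), 1150 - 1000, 2, byrow = TRUE))
  labMix <- clusterEmbedding(mix, eps = 1, minSamples = 5,
                             minClusterSize = 160)
  expect_equal(max(labMix), 1)
  expect_true(all(labMix[1001:1150] == -1))
  # the small blob may shed a few non-core points to noise before the
  # size filter sees it
  expect_length(attr(labMix, "omittedClusters"), 1)
  expect_gte(attr(labMix, "omittedClusters"), 140L)
})

test_that("cluster-by-group chi-square matches the definitional sum", {
  even <- clusterGroupChi2(rep(1:2, each = 20), rep(c("a", "b"), 20))
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  split <- clusterGroupChi2(rep(1:2, each = 20),
                            rep(c("a", "b"), each = 20))
  expect_equal(split$chi2, 40)
  expect_equal(split$df, 1)
  # random r x c tables against the brute-force sum and stats::chisq.test
  set.seed(30)
  for (i in 1:25) {
    r <- sample(2:5, 1); c <- sample(2:3, 1)
    O <- matrix(rpois(r * c, 30) + 1, r, c)
    labs <- rep(seq_len(r), times = rowSums(O))
    grps <- unlist(lapply(seq_len(r), function(ri)
      rep(letters[seq_len(c)], times = O[ri, ])))
    got <- clusterGroupChi2(labs, grps)
    expect_equal(got$chi2, chi2Oracle(O), tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(O, correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(sum(got$contingency), length(labs))
  }
  # noise excluded from the contingency
  withNoise <- clusterGroupChi2(c(rep(1:2, each = 20), rep(-1L, 7)),
                                rep(c("a", "b"), length.out = 47))
  expect_equal(sum(withNoise$contingency), 40)
})

test_that("the per-stain morphology workflow runs end to end", {
  pops <- data.frame(fraction = c(0.5, 0.5), meanRadius = c(6, 14),
                     radiusSD = c(0.8, 1.5), eccentricity = c(0.2, 0.7))
  mkTab <- function(group, seed) {
    cfg <- imageSimConfig(width = 800, height = 800, nCells = 120,
                          populations = pops, seed = seed)
    sim <- simulateIHCImage(cfg)
    ch <- suppressWarnings(
      stainChannel(deconvolve(rgbToOD(sim$rgb), hdab), "hematoxylin"))
    extractCellFeatures(sim$labelMask, ch, paste0("img", seed), group)
  }
  tab <- rbind(mkTab("PD", 21), mkTab("psPD", 22))
  res <- morphologyCluster(tab, stain = "hematoxylin", nPerGroup = 100,
                           eps = 1.2, minSamples = 5, minClusterSize = 20,
                           seed = 9)
  expect_s4_class(res, "MorphoClusterResult")
  expect_gte(nrow(res@contingency), 2)
  expect_equal(sum(res@contingency), sum(res@labels > 0))
  expect_equal(unname(colSums(res@contingency))[1] +
                 unname(colSums(res@contingency))[2] +
                 sum(res@labels == -1), 200)
})
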