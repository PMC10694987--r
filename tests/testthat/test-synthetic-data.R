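test_that("image generator handles the empty scene", {
  sim <- simulateIHCImage(imageSimConfig(nCells = 0, backgroundNoiseSD = 0,
                                         seed = 1))
  expect_true(all(sim$rgb == 255))
  expect_equal(attr(sim$labelMask, "nObjects"), 0L)
  expect_equal(nrow(sim$truth$cells), 0)
  expect_equal(sim$truth$trueDabPixelCount, 0)
})

test_that("non-overlapping placement conserves the cell count", {
  sim <- simulateIHCImage(imageSimConfig(nCells = 50, seed = 4))
  lab <- sim$labelMask
  expect_equal(attr(lab, "nObjects"), 50L)
  expect_equal(max(lab), 50)
  expect_setequal(unique(lab[lab > 0]), 1:50)
  # centroids inside bounds, ids unique
  tr <- sim$truth$cells
  expect_false(any(duplicated(tr$cell_id)))
  expect_true(all(tr$cx >= 0 & tr$cx <= 255 & tr$cy >= 0 & tr$cy <= 255))
})

test_that("DAB-positive fraction is binomially consistent with the config", {
  sim <- simulateIHCImage(imageSimConfig(width = 760, height = 760,
                                         nCells = 400,
                                         dabPositiveFraction = 0.25,
                                         seed = 21))
  nPos <- sum(sim$truth$cells$dab_positive)  # independent recount
  bounds <- qbinom(c(0.0005, 0.9995), 400, 0.25)
  expect_gte(nPos, bounds[1])
  expect_lte(nPos, bounds[2])
})

test_that("truth pixel counts equal a recount of the rendered rasters", {
  sim <- simulateIHCImage(imageSimConfig(nCells = 40, seed = 8,
                                         dabPositiveFraction = 0.5))
  expect_identical(sim$truth$trueDabPixelCount,
                   sum(sim$concentration[, , 2] > 0))
  expect_identical(sim$truth$trueHematoxylinPixelCount,
                   sum(sim$concentration[, , 1] > 0))
})

test_that("identical seeds give bit-identical images", {
  cfg <- imageSimConfig(nCells = 30, artifactFraction = 0.2, seed = 99)
  a <- simulateIHCImage(cfg)
  b <- simulateIHCImage(cfg)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$labelMask, b$labelMask)
  expect_identical(a$truth, b$truth)
})

test_that("infeasible placement and degenerate ellipses error clearly", {
  dense <- imageSimConfig(width = 64, height = 64, nCells = 200, seed = 1)
  expect_error(simulateIHCImage(dense), "without overlap")
  thin <- imageSimConfig(nCells = 5, seed = 1,
                         populations = data.frame(fraction = 1,
                                                  meanRadius = 1,
                                                  radiusSD = 0.01,
                                                  eccentricity = 0.99))
  expect_error(simulateIHCImage(thin), "zero-area")
  expect_error(imageSimConfig(populations = data.frame(
    fraction = c(0.6, 0.6), meanRadius = c(5, 5), radiusSD = c(1, 1),
    eccentricity = c(0.2, 0.2))), "sum to 1")
})

test_that("artifacts are in the truth table but not the label mask", {
  sim <- simulateIHCImage(imageSimConfig(nCells = 30, artifactFraction = 0.3,
                                         seed = 5))
  tr <- sim$truth$cells
  expect_equal(sum(tr$is_artifact), 9)
  expect_equal(nrow(tr), 39)
  expect_true(all(sim$labelMask <= 30))
  expect_false(any(tr$dab_positive & tr$is_artifact))
})

test_that("expression generator honours the latent cluster design", {
  # k = 1: all labels identical
  one <- simulateExpression(exprSimConfig(nSamples = 20, nGenes = 50,
                                          kClusters = 1, signatureSize = 5,
                                          seed = 3))
  expect_true(all(one$clusters == 1))
  expect_true(all(one$matrix > 0))
  # k > n errors
  expect_error(exprSimConfig(nSamples = 4, nGenes = 50, kClusters = 5),
               "exceed")
  # null case: with effectSize = 0 signature genes are not informative
  null <- simulateExpression(exprSimConfig(nSamples = 100, nGenes = 80,
                                           kClusters = 2,
                                           signatureSize = 30,
                                           effectSize = 0, seed = 17))
  lx <- log(null$matrix)
  p <- vapply(1:30, function(i)
    t.test(lx[i, null$clusters == 1], lx[i, null$clusters == 2])$p.value,
    numeric(1))
  expect_lte(mean(p < 0.05), 0.2)           # near-nominal rejection
  expect_gt(mean(p), 0.3); expect_lt(mean(p), 0.7)
})

test_that("housekeeping genes meet their coefficient-of-variation budget", {
  sim <- simulateExpression(exprSimConfig(nSamples = 80, nGenes = 100,
                                          kClusters = 2, signatureSize = 10,
                                          nHousekeeping = 8,
                                          housekeepingCV = 0.02, seed = 6))
  hk <- sim$matrix[sim$genes$role == "housekeeping", ]
  cv <- apply(hk, 1, sd) / rowMeans(hk)
  expect_true(all(cv <= 0.02 * 1.5))
})

test_that("imputation targets reach their designed R-squared under OLS", {
  tg <- list(list(target = "gene_090", predictors = c("gene_050", "gene_051"),
                  form = "linear", r2 = 0.9))
  sim <- simulateExpression(exprSimConfig(nSamples = 200, nGenes = 100,
                                          kClusters = 1, signatureSize = 0,
                                          imputationTargets = tg, seed = 12))
  lx <- log(sim$matrix)
  fit <- summary(lm(lx["gene_090", ] ~ t(lx[c("gene_050", "gene_051"), ])))
  expect_lt(abs(fit$r.squared - 0.9), 0.05)
  # interaction form runs and is positive
  tg2 <- list(list(target = "gene_090",
                   predictors = c("gene_050", "gene_051"),
                   form = "interaction", r2 = 0.8))
  sim2 <- simulateExpression(exprSimConfig(nSamples = 100, nGenes = 100,
                                           kClusters = 1, signatureSize = 0,
                                           imputationTargets = tg2,
                                           seed = 12))
  expect_true(all(sim2$matrix > 0))
  expect_equal(sim2$genes$role[90], "target")
})

test_that("expression generation is seed-deterministic", {
  cfg <- exprSimConfig(nSamples = 30, nGenes = 60, kClusters = 3,
                       signatureSize = 9, seed = 42)
  expect_identical(simulateExpression(cfg), simulateExpression(cfg))
})
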