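imputationPair <- function(r2 = 0.9, nRef = 200, nTar = 80, seedR = 9,
                           seedT = 10, form = "linear") {
  tg <- list(list(target = "gene_050",
                  predictors = c("gene_020", "gene_021"),
                  form = form, r2 = r2))
  cfgR <- exprSimConfig(nSamples = nRef, nGenes = 60, kClusters = 1,
                        signatureSize = 0, nHousekeeping = 6,
                        housekeepingCV = 0.02, imputationTargets = tg,
                        seed = seedR)
  ref <- simulateExpression(cfgR)
  cfgT <- exprSimConfig(nSamples = nTar, nGenes = 60, kClusters = 1,
                        signatureSize = 0, nHousekeeping = 6,
                        housekeepingCV = 0.02, imputationTargets = tg,
                        seed = seedT)
  tar <- simulateExpression(cfgT, baseMean = ref$baseMean)
  list(ref = ref, tar = tar)
}

test_that("housekeeping selection finds the designed low-variance genes", {
  sim <- simulateExpression(exprSimConfig(nSamples = 100, nGenes = 500,
                                          kClusters = 1, signatureSize = 0,
                                          nHousekeeping = 10,
                                          housekeepingCV = 0.02, seed = 2))
  sim2 <- simulateExpression(exprSimConfig(nSamples = 60, nGenes = 500,
                                           kClusters = 1, signatureSize = 0,
                                           nHousekeeping = 10,
                                           housekeepingCV = 0.02, seed = 3),
                             baseMean = sim$baseMean)
  sel <- selectHousekeeping(sim$matrix, sim2$matrix, pct = 0.20)
  designed <- sim$genes$gene_id[sim$genes$role == "housekeeping"]
  expect_true(all(designed %in% sel@candidates))
  expect_true(chosenGene(sel) %in% designed)
})

test_that("housekeeping selection edge cases", {
  m1 <- matrix(c(rep(5, 8), runif(32, 1, 100)), 5, 8, byrow = TRUE,
               dimnames = list(paste0("g", 1:5), paste0("a", 1:8)))
  m2 <- matrix(c(rep(7, 8), runif(32, 1, 100)), 5, 8, byrow = TRUE,
               dimnames = list(paste0("g", 1:5), paste0("b", 1:8)))
  sel <- selectHousekeeping(m1, m2, pct = 0.20)
  expect_equal(chosenGene(sel), "g1")         # the shared constant gene
  m3 <- m2; rownames(m3) <- paste0("x", 1:5)
  expect_error(selectHousekeeping(m1, m3), "shared genes")
  m4 <- m1; m4[2, 1] <- 0
  expect_error(selectHousekeeping(m1[1:4, ], m2[1:4, ]), "shared genes")
})

test_that("housekeeping normalization is exact and idempotent", {
  m <- matrix(c(2, 4, 6, 8, 3, 9), 3, 2,
              dimnames = list(c("hk", "g2", "g3"), c("s1", "s2")))
  n1 <- normalizeByHousekeeping(m, "hk")
  expect_equal(unname(n1["hk", ]), c(1, 1))
  expect_equal(n1["g2", "s1"], 2)             # 4 / 2
  expect_equal(normalizeByHousekeeping(n1, "hk"), n1)
  mz <- m; mz["hk", 2] <- 0
  expect_error(normalizeByHousekeeping(mz, "hk"), "s2")
  expect_error(normalizeByHousekeeping(m, "nope"), "not found")
})

test_that("shadow-feature selection confirms signal, rejects noise", {
  set.seed(6)
  n <- 200
  X <- matrix(rnorm(n * 21), n)
  colnames(X) <- c("x1", paste0("noise", 1:20))
  y <- 3 * X[, "x1"]
  y <- y + rnorm(n, 0, 0.1 * sd(y))
  sel <- borutaSelect(X, y, maxIter = 50, seed = 4)
  expect_true("x1" %in% sel$confirmed)
  expect_gte(length(sel$rejected), 18)
  expect_false(any(grepl("shadow", c(sel$confirmed, sel$tentative))))
  # perfect predictor confirms quickly
  sel2 <- borutaSelect(X[, 1:5], X[, 1], maxIter = 50, seed = 2)
  expect_true("x1" %in% sel2$confirmed)
  expect_error(borutaSelect(X, rep(1, n)), "constant")
  expect_error(borutaSelect(X[, 1, drop = FALSE], y), "2 predictors")
})

test_that("imputer training reports honest held-out quality", {
  pair <- imputationPair(r2 = 0.9)
  refN <- normalizeByHousekeeping(pair$ref$matrix, "gene_001")
  model <- trainImputer(refN, "gene_050", c("gene_020", "gene_021"),
                        housekeepingGene = "gene_001", seed = 5)
  expect_gte(model@meta$heldOutR, 0.8)
  expect_false(model@meta$lowQuality)
  # target equal to a predictor: near-perfect
  refCopy <- refN
  refCopy["gene_050", ] <- refCopy["gene_020", ]
  mCopy <- trainImputer(refCopy, "gene_050", c("gene_020", "gene_021"),
                        seed = 5)
  # leaf averaging bounds a forest's fit of even an exact copy
  expect_gte(mCopy@meta$heldOutR, 0.95)
  # pure-noise target: r near zero and flagged
  refNoise <- refN
  set.seed(31)
  refNoise["gene_050", ] <- exp(rnorm(ncol(refN), 4, 0.5))
  mNoise <- trainImputer(refNoise, "gene_050", c("gene_020", "gene_021"),
                         seed = 5)
  expect_lte(abs(mNoise@meta$heldOutR), 0.2)
  expect_true(mNoise@meta$lowQuality)
  expect_error(trainImputer(refN[, 1:10], "gene_050", "gene_020"),
               ">= 20")
})

test_that("cross-platform imputation recovers withheld truth", {
  pair <- imputationPair(r2 = 0.9)
  res <- imputeAcrossPlatforms(pair$ref$matrix, pair$tar$matrix, "gene_050",
                               seed = 3, maxIter = 50)
  expect_setequal(res$model@predictors, c("gene_020", "gene_021"))
  truthN <- normalizeByHousekeeping(pair$tar$matrix,
                                    chosenGene(res$housekeeping))["gene_050", ]
  expect_gte(cor(log(res$imputed), log(truthN)), 0.8)
  expect_true(attr(res$imputed, "imputed"))
  # empty target matrix gives empty flagged output
  empty <- imputeGene(res$model, pair$tar$matrix[, 0])
  expect_length(empty, 0)
  expect_true(attr(empty, "imputed"))
  # missing predictor errors by name
  noPred <- pair$tar$matrix[setdiff(rownames(pair$tar$matrix), "gene_020"), ]
  expect_error(imputeGene(res$model, noPred), "gene_020")
})

test_that("constant predictors regress to the training mean", {
  pair <- imputationPair(r2 = 0.9)
  refN <- normalizeByHousekeeping(pair$ref$matrix, "gene_001")
  model <- trainImputer(refN, "gene_050", c("gene_020", "gene_021"),
                        seed = 5)
  flat <- refN[, 1:4]
  flat["gene_020", ] <- mean(refN["gene_020", ])
  flat["gene_021", ] <- mean(refN["gene_021", ])
  pred <- imputeGene(model, flat)
  expect_lt(max(abs(pred - mean(pred))), 1e-9)  # identical inputs
  expect_lt(abs(pred[1] - mean(refN["gene_050", ])),
            stats::sd(refN["gene_050", ]))
})

test_that("imputation is invariant to a common per-sample rescale", {
  pair <- imputationPair(r2 = 0.9)
  hk <- "gene_001"
  run <- function(ref, tar) {
    refN <- normalizeByHousekeeping(ref, hk)
    tarN <- normalizeByHousekeeping(tar, hk)
    model <- trainImputer(refN, "gene_050", c("gene_020", "gene_021"),
                          seed = 8)
    imputeGene(model, tarN)
  }
  base <- run(pair$ref$matrix, pair$tar$matrix)
  set.seed(12)
  fRef <- runif(ncol(pair$ref$matrix), 0.5, 2)
  fTar <- runif(ncol(pair$tar$matrix), 0.5, 2)
  scaled <- run(sweep(pair$ref$matrix, 2, fRef, "*"),
                sweep(pair$tar$matrix, 2, fTar, "*"))
  expect_equal(unname(base), unname(scaled), tolerance = 1e-9)
})

test_that("held-out r tracks the designed signal strength across seeds", {
  rFor <- function(r2, seeds) {
    vapply(seeds, function(s) {
      pair <- imputationPair(r2 = r2, seedR = 100 + s, seedT = 200 + s)
      refN <- normalizeByHousekeeping(pair$ref$matrix, "gene_001")
      trainImputer(refN, "gene_050", c("gene_020", "gene_021"),
                   seed = s)@meta$heldOutR
    }, numeric(1))
  }
  seeds <- 1:10
  expect_lt(abs(mean(rFor(0.9, seeds)) - sqrt(0.9)), 0.15)
  expect_lt(abs(mean(rFor(0.5, seeds)) - sqrt(0.5)), 0.15)
})
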