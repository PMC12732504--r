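test_that("configuration and head constructors validate inputs", {
  expect_error(nbvaeConfig(latentDim = 0), "latentDim")
  expect_error(nbvaeConfig(betaFinal = -1))
  expect_error(auxHead("", "binary"))
  expect_equal(auxHead("ctx", "binary")$alpha, 10)
  expect_equal(auxHead("t", "continuous")$alpha, 1)
})

test_that("KL term is the closed-form Gaussian divergence", {
  # standard-normal posterior: zero divergence
  expect_equal(gaussianKL(matrix(0, 4, 3), matrix(0, 4, 3)), 0)
  # mu = 1, sigma = 1: 1/2 per latent dimension
  expect_equal(gaussianKL(matrix(1, 2, 5), matrix(0, 2, 5)), 2.5)
  # non-negative for arbitrary posteriors
  set.seed(2)
  for (i in 1:20) {
    expect_gte(gaussianKL(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), 0)
  }
})

test_that("beta = 0 reduces the objective to the reconstruction term", {
  fix <- tinyFixture()
  xRaw <- t(SummarizedExperiment::assay(fix$pre, "counts"))[1:20, ]
  l0 <- elboLoss(fix$model, xRaw, beta = 0)
  l1 <- elboLoss(fix$model, xRaw, beta = 0.7)
  expect_equal(l0$total, l0$recon)
  expect_equal(l1$total, l1$recon + 0.7 * l1$kl)
  expect_gt(l1$kl, 0)
})

test_that("auxiliary losses mask missing labels and hit exact zeros", {
  hB <- auxHead("ctx", "binary", alpha = 2)
  expect_lt(auxLoss(hB, c(1 - 1e-13, 1e-13), c(1, 0)), 1e-9)
  hC <- auxHead("time", "continuous")
  expect_equal(auxLoss(hC, c(0.3, -2), c(0.3, -2)), 0)
  # all labels missing contribute exactly zero
  expect_identical(auxLoss(hB, c(0.2, 0.9), c(NA, NA)), 0)
  expect_error(auxLoss(hB, c(0.2, 0.9), c(0, 2)), "non-binary")
})

test_that("analytic parameter gradients match finite differences", {
  # the full training gradient (reconstruction + KL + aux) against
  # central finite differences on a tiny model
  set.seed(4)
  G <- 6; B <- 5; d <- 3
  model <- newNBVAE(sprintf("g%d", 1:G),
                    nbvaeConfig(latentDim = d, encoderHidden = c(7, 5),
                                seed = 2),
                    auxHeads = list(auxHead("ctx", "binary", alpha = 3),
                                    auxHead("tm", "continuous")))
  xRaw <- matrix(rnbinom(B * G, size = 2, mu = 6), B, G)
  xRaw[, 1] <- xRaw[, 1] + 1
  scale <- rowMeans(xRaw)
  xIn <- log1p(xRaw / scale)
  eps <- matrix(rnorm(B * d), B, d)
  labels <- list(ctx = c(1, 0, NA, 1, 0), tm = c(0.5, NA, NA, -1, 2))
  beta <- 0.3
  res <- perturbflow:::nbvaeGradients(model, xIn, xRaw, scale, eps, beta,
                                      labels)
  lossAt <- function(params) {
    m2 <- model; m2@params <- params
    r <- perturbflow:::nbvaeGradients(m2, xIn, xRaw, scale, eps, beta,
                                      labels)
    r$total
  }
  h <- 1e-5
  for (nm in c("encW1", "encWmu", "encWlv", "decW1", "decWout", "logR",
               "auxW_ctx", "auxB_tm")) {
    g <- res$grads[[nm]]
    idx <- seq_len(min(4, length(g)))
    for (i in idx) {
      pp <- model@params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- model@params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (lossAt(pp) - lossAt(pm)) / (2 * h)
      expect_equal(unname(g[i]), fd, tolerance = 1e-5)
    }
  }
})

test_that("training reduces validation reconstruction below the naive NB baseline", {
  fix <- tinyFixture()
  hist <- fix$model@history
  expect_gt(hist$valRecon[1], tail(hist$valRecon, 1))
  valIdx <- SummarizedExperiment::colData(fix$pre)$partition == "val"
  xVal <- t(SummarizedExperiment::assay(fix$pre, "counts"))[valIdx, ]
  expect_lt(tail(hist$valRecon, 1), naiveNBBaseline(xVal))
})

test_that("beta schedule anneals linearly and never decreases", {
  hist <- tinyFixture()$model@history
  expect_true(all(diff(hist$beta) >= 0))
  expect_equal(tail(hist$beta, 1),
               tinyFixture()$model@config$betaFinal)
})

test_that("patience 0 stops at the first non-improving epoch", {
  fix <- tinyFixture()
  cfg <- nbvaeConfig(latentDim = 4, encoderHidden = c(16, 8),
                     batchSize = 128, maxEpochs = 30, patience = 0,
                     seed = 5)
  m <- trainNBVAE(newNBVAE(rownames(fix$pre), cfg), fix$pre)
  v <- m@history$valLoss
  n <- length(v)
  if (n < 30) {
    # stopped early: the last epoch did not improve on the best before it
    expect_gte(v[n], min(v[seq_len(n - 1)]) - 1e-9)
    # and every earlier epoch improved strictly
    expect_true(all(diff(v[seq_len(n - 1)]) < 0))
  }
  expect_equal(m@history$bestValLoss, min(v))
})

test_that("training is bit-for-bit reproducible under a fixed seed", {
  fix <- tinyFixture()
  cfg <- nbvaeConfig(latentDim = 3, encoderHidden = c(12, 6),
                     batchSize = 128, maxEpochs = 4, patience = 2,
                     seed = 17)
  m1 <- trainNBVAE(newNBVAE(rownames(fix$pre), cfg), fix$pre)
  m2 <- trainNBVAE(newNBVAE(rownames(fix$pre), cfg), fix$pre)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history$valLoss, m2@history$valLoss)
})

test_that("encoding is deterministic with positive posterior variance", {
  fix <- tinyFixture()
  x <- t(SummarizedExperiment::assay(fix$pre, "lognorm"))[1:10, ]
  e1 <- encodeCells(fix$model, x)
  e2 <- encodeCells(fix$model, x)
  expect_identical(e1$mu, e2$mu)
  expect_true(all(exp(e1$logVar) > 0))
  expect_error(encodeCells(fix$model, x[, 1:5]), "expects")
  # encode/decode reconstruction beats the naive baseline
  xRaw <- t(SummarizedExperiment::assay(fix$pre, "counts"))[1:200, ]
  expect_lt(elboLoss(fix$model, xRaw, beta = 0)$recon,
            naiveNBBaseline(xRaw))
})

test_that("aux binary head reaches high held-out accuracy from 10% labels", {
  fix <- txFixture()
  test <- SummarizedExperiment::colData(fix$pre)$partition == "test"
  pred <- predictAux(fix$model, fix$lat[test, ], "condition") > 0.5
  acc <- mean(pred == (fix$cond[test] == 1))
  expect_gte(acc, 0.95)
  # only ~10% of cells had observed labels
  expect_equal(sum(!is.na(fix$sim$labels$condition$label)),
               round(0.1 * ncol(fix$sim$counts)))
})

test_that("checkpoints round-trip the full model state", {
  fix <- tinyFixture()
  path <- tempfile(fileext = ".ckpt")
  saveNBVAE(fix$model, path)
  back <- loadNBVAE(path)
  expect_identical(back@params, fix$model@params)
  expect_identical(back@config, fix$model@config)
  expect_identical(back@geneIds, fix$model@geneIds)
  z <- matrix(rnorm(8), 2, 4)
  expect_identical(decodeMean(back, z), decodeMean(fix$model, z))
})

test_that("decoder output is strictly positive and scales linearly", {
  fix <- tinyFixture()
  z <- matrix(rnorm(20), 5, 4)
  m1 <- decodeMean(fix$model, z, cellScale = 1)
  expect_true(all(m1 > 0))
  expect_equal(decodeMean(fix$model, z, cellScale = 2), 2 * m1)
  expect_error(decodeMean(fix$model, z, cellScale = 0), "positive")
  expect_error(decodeMean(fix$model, z * NA), "non-finite")
})

test_that("trained decoder Jacobians recover the generative loadings", {
  # dedicated clean recovery setting: moderate latent dim, strong
  # loadings, mild overdispersion; compare Jacobian columns with the true
  # loadings after a linear alignment of the two latent spaces
  cfgS <- syntheticConfig(nCells = 2000, nGenes = 150, latentDim = 4,
                          nClusters = 2, clusterSeparation = 3,
                          loadingScale = 0.6, effectLoadingScale = 0.6,
                          effectMeanBoost = 1, dispersionR = 8,
                          conditionAxisNorm = 2, nEffectGenes = 15,
                          seed = 11)
  sim <- suppressWarnings(generateSyntheticData(cfgS))
  pre <- preprocessCounts(sim$counts, minNonzeroGenes = 50, seed = 11)
  cfg <- nbvaeConfig(latentDim = 4, encoderHidden = c(128, 64),
                     betaFinal = 1e-3, betaAnnealSteps = 500,
                     batchSize = 256, maxEpochs = 60, patience = 10,
                     seed = 11)
  model <- trainNBVAE(newNBVAE(rownames(pre), cfg), pre)
  lat <- latentEmbedding(model, pre)
  zTrue <- sim$truth$latents[rownames(lat), ]
  B <- qr.solve(cbind(1, lat), zTrue)[-1, ]
  W <- sim$truth$W[rownames(pre), ]
  set.seed(1)
  zs <- lat[sample(nrow(lat), 50), ]
  acc <- 0
  for (i in seq_len(nrow(zs))) {
    J <- t(B) %*% decoderJacobian(model, zs[i, ])
    acc <- acc + abs(colSums(J * t(W)) /
                     (sqrt(colSums(J^2)) * sqrt(rowSums(W^2))))
  }
  expect_gte(mean(acc / nrow(zs)), 0.7)
})
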