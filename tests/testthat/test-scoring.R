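axisFromVectors <- function(a) {
  lat <- rbind(a, 0 * a)
  rownames(lat) <- c("p", "u")
  perturbationAxis(lat, c(1, 0))
}

test_that("perturbation axis is the exact difference of group means", {
  lat <- rbind(c(1, 0), c(0, 0))
  ax <- perturbationAxis(lat, c(1, 0))
  expect_equal(ax@axis, c(1, 0))
  set.seed(2)
  lat2 <- matrix(rnorm(40), 20, 2)
  lab <- rep(c(0, 1), 10)
  ax2 <- perturbationAxis(lat2, lab)
  expect_equal(ax2@axis, colMeans(lat2[lab == 1, ]) -
                 colMeans(lat2[lab == 0, ]))
  expect_equal(ax2@groupSizes, c(10L, 10L))
  expect_error(perturbationAxis(lat2, rep(1, 20)), "non-empty")
})

test_that("identical groups give a zero axis that scoring refuses", {
  lat <- rbind(c(1, 2), c(1, 2), c(1, 2), c(1, 2))
  expect_warning(ax <- perturbationAxis(lat, c(0, 0, 1, 1)), "zero-norm")
  model <- linearDecoderModel(matrix(c(1, 0), 1))
  expect_error(alignmentScore(model, 1, lat, ax), "zero-norm")
  expect_error(scoreGenes(model, lat, ax), "zero-norm")
})

test_that("alignment score hits the exact worked values", {
  a <- c(2, 1)
  ax <- axisFromVectors(a)
  Z <- matrix(rnorm(10), 5, 2)
  # gradient identically equal to the axis: s = 1
  expect_equal(as.numeric(alignmentScore(linearDecoderModel(matrix(a, 1)),
                                         1, Z, ax)), 1)
  # gradient identically equal to -a: s = -1
  expect_equal(as.numeric(alignmentScore(linearDecoderModel(-matrix(a, 1)),
                                         1, Z, ax)), -1)
  # half of Z with gradient a, half orthogonal: s = mean(1, 0) = 0.5
  aPerp <- c(-a[2], a[1])
  model <- regionGradientModel(gradPos = a, gradNeg = aPerp)
  Zhalf <- rbind(c(1, 1), c(2, 1), c(-1, -1), c(-2, -1))
  s <- alignmentScore(model, 1, Zhalf, axisFromVectors(a))
  expect_equal(as.numeric(s), 0.5)
  expect_equal(attr(s, "nSkipped"), 0)
})

test_that("magnitude-weighted score projects onto the unit axis", {
  a <- c(0.5, -1.5)
  ax <- axisFromVectors(a)
  Z <- matrix(rnorm(8), 4, 2)
  # gradient == a everywhere: sTilde = |a|
  expect_equal(magnitudeWeightedScore(linearDecoderModel(matrix(a, 1)),
                                      1, Z, ax), sqrt(sum(a^2)))
  # zero gradient: sTilde = 0
  expect_equal(magnitudeWeightedScore(linearDecoderModel(matrix(0, 1, 2)),
                                      1, Z, ax), 0)
  # gradients {2a, -a}: mean projection = |a| / 2
  model <- regionGradientModel(gradPos = 2 * a, gradNeg = -a)
  Zhalf <- rbind(c(1, 1), c(-1, -1))
  expect_equal(magnitudeWeightedScore(model, 1, Zhalf, ax),
               sqrt(sum(a^2)) / 2)
})

test_that("cosine score is invariant to positive rescaling", {
  a <- c(1, 2)
  W <- matrix(c(0.3, -0.7), 1)
  Z <- matrix(rnorm(12), 6, 2)
  s1 <- as.numeric(alignmentScore(linearDecoderModel(W), 1, Z,
                                  axisFromVectors(a)))
  s2 <- as.numeric(alignmentScore(linearDecoderModel(5 * W), 1, Z,
                                  axisFromVectors(3 * a)))
  expect_equal(s1, s2, tolerance = 1e-12)
  # sTilde scales with gradient magnitude, invariant to axis rescaling
  m1 <- magnitudeWeightedScore(linearDecoderModel(W), 1, Z,
                               axisFromVectors(a))
  expect_equal(magnitudeWeightedScore(linearDecoderModel(5 * W), 1, Z,
                                      axisFromVectors(3 * a)),
               5 * m1, tolerance = 1e-12)
})

test_that("swapping condition labels negates axis, scores and baseline", {
  fix <- tinyFixture()
  lat <- latentEmbedding(fix$model, fix$pre)
  cond <- fix$sim$truth$condition[match(rownames(lat),
                                        rownames(fix$sim$truth$latents))]
  ax <- perturbationAxis(lat, cond)
  axSwap <- perturbationAxis(lat, 1 - cond)
  expect_equal(axSwap@axis, -ax@axis)
  Z <- lat[1:50, ]
  s <- scoreGenes(fix$model, Z, ax)
  sSwap <- scoreGenes(fix$model, Z, axSwap)
  expect_equal(sSwap$s, -s$s, tolerance = 1e-12)
  expect_equal(sSwap$sTilde, -s$sTilde, tolerance = 1e-12)
  b <- baselineSymmetricChange(fix$model, lat, cond)
  bSwap <- baselineSymmetricChange(fix$model, lat, 1 - cond)
  expect_equal(bSwap, -b, tolerance = 1e-12)
  expect_true(all(s$s >= -1 & s$s <= 1))
  expect_true(all(b >= -2 & b <= 2))
})

test_that("symmetric-change baseline hits its worked values and bounds", {
  # 1-D latent, identity-link decoder: m(z) = z, three genes via loadings
  model <- linearDecoderModel(matrix(c(1, 1), 2, 1), b = c(0, 0))
  # condition medians at z = 2 and z = 2: equal means -> b = 0
  lat <- matrix(c(2, 2, 2, 2), 4, 1)
  rownames(lat) <- sprintf("c%d", 1:4)
  expect_equal(unname(baselineSymmetricChange(model, lat, c(0, 0, 1, 1))),
               c(0, 0))
  # m(1) = 3, m(0) = 1 -> b = (3-1)/2 = 1
  lat2 <- matrix(c(1, 1, 3, 3), 4, 1)
  rownames(lat2) <- sprintf("c%d", 1:4)
  expect_equal(unname(baselineSymmetricChange(model, lat2,
                                              c(0, 0, 1, 1))),
               c(1, 1))
  # m(0) = 0 with m(1) > 0 -> upper bound 2 exactly
  lat3 <- matrix(c(0, 0, 5, 5), 4, 1)
  rownames(lat3) <- sprintf("c%d", 1:4)
  expect_equal(unname(baselineSymmetricChange(model, lat3,
                                              c(0, 0, 1, 1))),
               c(2, 2))
  # m(1) = m(0) = 0 is defined as 0
  lat4 <- matrix(c(0, 0, 0, 0), 4, 1)
  rownames(lat4) <- sprintf("c%d", 1:4)
  expect_equal(unname(baselineSymmetricChange(model, lat4,
                                              c(0, 0, 1, 1))),
               c(0, 0))
})

test_that("top-K selection orders by absolute score with stable ties", {
  sc <- c(g1 = 0.9, g2 = -0.95, g3 = 0.1)
  expect_identical(topKGenes(sc, 2), c("g2", "g1"))
  expect_identical(topKGenes(sc, 3), c("g2", "g1", "g3"))
  tied <- c(b = 0.5, a = -0.5, c = 0.5)
  expect_identical(topKGenes(tied, 2), c("a", "b"))
  expect_error(topKGenes(sc, 4), "exceeds")
})

test_that("scores computed from the analytic truth gradients are exact", {
  sim <- tinyFixture()$sim
  truth <- sim$truth
  aU <- truth$axisUnit
  set.seed(4)
  Z <- matrix(rnorm(10 * ncol(truth$W)), 10)
  for (g in c(1, 5, 20, 40)) {
    grd <- truthGradient(truth, g, Z)
    cosv <- drop(grd %*% truth$aTrue) /
      (sqrt(rowSums(grd^2)) * sqrt(sum(truth$aTrue^2)))
    expect_equal(mean(cosv), trueAlignmentScore(truth, g),
                 tolerance = 1e-12)
  }
})

test_that("restricting the evaluation set changes region-specific scores", {
  a <- c(1, 0)
  model <- regionGradientModel(gradPos = a, gradNeg = c(0, 1))
  ax <- axisFromVectors(a)
  Zglobal <- rbind(c(1, 1), c(2, 2), c(-1, -1), c(-2, -2))
  Zregion <- Zglobal[1:2, , drop = FALSE]
  sGlobal <- as.numeric(alignmentScore(model, 1, Zglobal, ax))
  sRegion <- as.numeric(alignmentScore(model, 1, Zregion, ax))
  expect_equal(sGlobal, 0.5)
  expect_equal(sRegion, 1)
  expect_gt(abs(sRegion - sGlobal), 0.1)
})

test_that("ranking against ground truth separates effect genes", {
  fix <- kdFixture()
  eff <- fix$scores$gene_id %in% fix$sim$truth$effectGenes
  expect_gte(aurocScore(abs(fix$scores$s), eff), 0.9)
  top <- topKGenes(fix$scores, 30)
  expect_gt(mean(top %in% fix$sim$truth$effectGenes), 0.5)
})
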