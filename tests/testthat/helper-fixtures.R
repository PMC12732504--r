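## Shared fixtures. The two trained models (knockdown and treatment
## presets) are expensive, so they are built lazily once per test run and
## cached for every file that needs them.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

fixtureTrainConfig <- function(latentDim = 8, seed = 1) {
  nbvaeConfig(latentDim = latentDim, encoderHidden = c(128, 64),
              betaFinal = 1e-3, betaAnnealSteps = 500, batchSize = 256,
              maxEpochs = 40, patience = 8, seed = seed)
}

# Knockdown preset (3000 cells x 300 genes), trained model, embeddings,
# condition axis and gene scores.
kdFixture <- function() {
  cachedFixture("kd", function() {
    sim <- generateSyntheticData(syntheticPreset("knockdown", seed = 1))
    pre <- preprocessCounts(sim$counts, seed = 1)
    model <- trainNBVAE(newNBVAE(rownames(pre), fixtureTrainConfig()), pre)
    lat <- latentEmbedding(model, pre)
    cond <- sim$truth$condition[match(rownames(lat),
                                      rownames(sim$truth$latents))]
    axis <- perturbationAxis(lat, cond)
    scores <- scoreGenes(model, lat, axis)
    list(sim = sim, pre = pre, model = model, lat = lat, cond = cond,
         axis = axis, scores = scores)
  })
}

# Treatment preset with a binary auxiliary head trained on 10% labels.
txFixture <- function() {
  cachedFixture("tx", function() {
    sim <- generateSyntheticData(syntheticPreset("treatment", seed = 1))
    pre <- preprocessCounts(sim$counts, seed = 1)
    model <- trainNBVAE(
      newNBVAE(rownames(pre), fixtureTrainConfig(),
               auxHeads = list(auxHead("condition", "binary"))),
      pre, labels = list(condition = sim$labels$condition))
    lat <- latentEmbedding(model, pre)
    cond <- sim$truth$condition[match(rownames(lat),
                                      rownames(sim$truth$latents))]
    list(sim = sim, pre = pre, model = model, lat = lat, cond = cond)
  })
}

# Small preprocessed dataset + quickly trained model for cheap checks.
tinyFixture <- function() {
  cachedFixture("tiny", function() {
    cfg <- syntheticConfig(nCells = 400, nGenes = 60, latentDim = 4,
                           nClusters = 2, clusterSeparation = 3,
                           nEffectGenes = 8, seed = 5)
    sim <- suppressWarnings(generateSyntheticData(cfg))
    pre <- preprocessCounts(sim$counts, minNonzeroGenes = 20,
                            minTotalCounts = 100, seed = 5)
    model <- trainNBVAE(
      newNBVAE(rownames(pre),
               nbvaeConfig(latentDim = 4, encoderHidden = c(32, 16),
                           betaFinal = 1e-3, betaAnnealSteps = 60,
                           learningRate = 5e-3, batchSize = 64,
                           maxEpochs = 60, patience = 10,
                           seed = 5)), pre)
    list(sim = sim, pre = pre, model = model)
  })
}

# NB negative log likelihood of the naive per-gene predictor: empirical
# mean and moment-matched dispersion, no cell-level information.
naiveNBBaseline <- function(xRaw) {
  mu <- colMeans(xRaw)
  v <- apply(xRaw, 2, var)
  r <- ifelse(v > mu, mu^2 / (v - mu), 1e6)
  M <- matrix(mu, nrow(xRaw), ncol(xRaw), byrow = TRUE)
  R <- matrix(r, nrow(xRaw), ncol(xRaw), byrow = TRUE)
  mean(-rowSums(nbLogPMF(xRaw, M, R)))
}

# Analytic test double: decoder is exactly y = W z + b (identity link, no
# hidden layers), so the gradient of gene g is row g of W at any z.
linearDecoderModel <- function(W, b = NULL, encoderInputGenes = NULL) {
  W <- as.matrix(W)
  G <- nrow(W); d <- ncol(W)
  if (is.null(b)) b <- numeric(G)
  model <- newNBVAE(sprintf("g%03d", seq_len(G)),
                    nbvaeConfig(latentDim = d, encoderHidden = c(4),
                                decoderHidden = integer(0),
                                decoderLink = "identity", seed = 1))
  model@params$decWout <- t(W)
  model@params$decBout <- b
  model
}

# Piecewise test double (ReLU hidden layer, identity link, 2-D latent,
# one gene): the gene's gradient equals `gradPos` anywhere in the open
# positive quadrant and `gradNeg` anywhere in the open negative quadrant.
# Four ReLU units gate the two coordinate signs:
#   y = p1*relu(z1) + p2*relu(z2) - n1*relu(-z1) - n2*relu(-z2)
regionGradientModel <- function(gradPos, gradNeg) {
  model <- newNBVAE("g001",
                    nbvaeConfig(latentDim = 2, encoderHidden = c(4),
                                decoderHidden = c(4),
                                activation = "relu",
                                decoderLink = "identity", seed = 1))
  model@params$decW1 <- cbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  model@params$decB1 <- numeric(4)
  model@params$decWout <- matrix(
    c(gradPos[1], gradPos[2], -gradNeg[1], -gradNeg[2]), 4, 1)
  model@params$decBout <- 0
  model
}
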