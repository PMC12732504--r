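#' Model configuration for the NB beta-VAE
#'
#' @param latentDim Latent dimensionality (the paper's settings are 2 and
#'   32; any positive integer works).
#' @param encoderHidden Hidden layer sizes of the encoder MLP.
#' @param decoderHidden Hidden layer sizes of the decoder (mirrored encoder
#'   by default).
#' @param activation Rectifier used in the hidden layers: `"softplus"`
#'   (default; smooth, so decoder gradients are exact everywhere) or
#'   `"relu"`.
#' @param decoderLink Positive-mean link on the decoder output:
#'   `"softplus"` (softplus plus 1e-8, the default) or `"identity"`
#'   (linear output; intended for analytic test doubles only — positivity
#'   is then not guaranteed).
#' @param betaFinal Final value of the KL weight beta; annealed linearly
#'   from 0. Small values make the model almost an autoencoder.
#' @param betaAnnealSteps Number of optimizer steps over which beta rises
#'   to `betaFinal`.
#' @param learningRate Adam learning rate.
#' @param batchSize Minibatch size.
#' @param maxEpochs Upper bound on training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); best-validation weights are restored.
#' @param seed Integer seed controlling initialization, shuffling and the
#'   reparameterization noise.
#' @return Named list of validated hyperparameters.
#' @export
nbvaeConfig <- function(latentDim = 32,
                        encoderHidden = c(512, 256),
                        decoderHidden = rev(encoderHidden),
                        activation = c("softplus", "relu"),
                        decoderLink = c("softplus", "identity"),
                        betaFinal = 1e-3,
                        betaAnnealSteps = 2000,
                        learningRate = 1e-3,
                        batchSize = 128,
                        maxEpochs = 200,
                        patience = 20,
                        seed = 1) {
  activation <- match.arg(activation)
  decoderLink <- match.arg(decoderLink)
  stopifnot(latentDim >= 1, all(encoderHidden >= 1),
            all(decoderHidden >= 1) || length(decoderHidden) == 0,
            betaFinal >= 0, learningRate > 0, batchSize >= 1,
            maxEpochs >= 1, patience >= 0)
  list(latentDim = as.integer(latentDim),
       encoderHidden = as.integer(encoderHidden),
       decoderHidden = as.integer(decoderHidden),
       activation = activation, decoderLink = decoderLink,
       betaFinal = betaFinal,
       betaAnnealSteps = as.integer(betaAnnealSteps),
       learningRate = learningRate, batchSize = as.integer(batchSize),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       seed = as.integer(seed))
}

#' Auxiliary output head specification
#'
#' A lightweight linear head on the latent space: binary heads output a
#' probability through a sigmoid and are trained with binary cross-entropy;
#' continuous heads output a real value and are trained with an L1 loss.
#' The head loss is weighted by `alpha` and averaged over the cells whose
#' label is observed, so partially labeled data (e.g., 10% label fraction)
#' contribute a gradient of label-count-invariant scale.
#'
#' @param name Head name (used to reference the head when probing).
#' @param kind `"binary"` or `"continuous"`.
#' @param alpha Positive loss weight; defaults to 10 for binary heads and
#'   1 for continuous heads.
#' @return Named list describing the head.
#' @export
auxHead <- function(name, kind = c("binary", "continuous"), alpha = NULL) {
  kind <- match.arg(kind)
  if (is.null(alpha)) alpha <- if (kind == "binary") 10 else 1
  stopifnot(nzchar(name), alpha > 0)
  list(name = name, kind = kind, alpha = alpha)
}

initLinear <- function(nin, nout) {
  list(W = matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

#' Construct an untrained NB beta-VAE
#'
#' Initializes all weights (He-scaled Gaussian, seeded by
#' `config$seed`), unit dispersions (`log r = 0`) and the requested
#' auxiliary heads.
#'
#' @param geneIds Character vector of output gene identifiers.
#' @param config Configuration from [nbvaeConfig()].
#' @param auxHeads List of [auxHead()] specifications.
#' @return An [NBVAE-class] object.
#' @export
newNBVAE <- function(geneIds, config = nbvaeConfig(), auxHeads = list()) {
  stopifnot(is.character(geneIds), length(geneIds) >= 1,
            !anyDuplicated(geneIds))
  if (length(auxHeads)) names(auxHeads) <- vapply(auxHeads, `[[`,
                                                  character(1), "name")
  set.seed(config$seed)
  G <- length(geneIds)
  d <- config$latentDim
  params <- list()
  sizes <- c(G, config$encoderHidden)
  for (i in seq_along(config$encoderHidden)) {
    l <- initLinear(sizes[i], sizes[i + 1])
    params[[paste0("encW", i)]] <- l$W
    params[[paste0("encB", i)]] <- l$b
  }
  top <- sizes[length(sizes)]
  l <- initLinear(top, d); params$encWmu <- l$W; params$encBmu <- l$b
  l <- initLinear(top, d); params$encWlv <- l$W; params$encBlv <- l$b
  dsizes <- c(d, config$decoderHidden)
  for (i in seq_along(config$decoderHidden)) {
    l <- initLinear(dsizes[i], dsizes[i + 1])
    params[[paste0("decW", i)]] <- l$W
    params[[paste0("decB", i)]] <- l$b
  }
  l <- initLinear(dsizes[length(dsizes)], G)
  params$decWout <- l$W
  params$decBout <- l$b
  params$logR <- numeric(G)
  for (h in auxHeads) {
    l <- initLinear(d, 1)
    params[[paste0("auxW_", h$name)]] <- l$W
    params[[paste0("auxB_", h$name)]] <- l$b
  }
  new("NBVAE", config = config, params = params, geneIds = geneIds,
      auxHeads = auxHeads, history = list())
}

#' @describeIn NBVAE-class compact description of architecture and
#'   training state
#' @param object An `NBVAE`.
#' @export
setMethod("show", "NBVAE", function(object) {
  cfg <- object@config
  cat("NBVAE:", length(object@geneIds), "genes, latent dim",
      cfg$latentDim, "\n")
  cat("  encoder hidden:", paste(cfg$encoderHidden, collapse = "-"),
      "| decoder hidden:", paste(cfg$decoderHidden, collapse = "-"),
      "| activation:", cfg$activation, "\n")
  if (length(object@auxHeads)) {
    cat("  aux heads:", paste(vapply(object@auxHeads, function(h)
      paste0(h$name, " (", h$kind, ", alpha=", h$alpha, ")"),
      character(1)), collapse = ", "), "\n")
  }
  if (length(object@history)) {
    cat("  trained:", object@history$stoppedEpoch, "epochs, best val loss",
        format(object@history$bestValLoss, digits = 6), "\n")
  } else cat("  untrained\n")
})

#' Gene-wise dispersions of the NB observation model
#' @param model An [NBVAE-class] model.
#' @return Named positive numeric vector, one `r` per gene.
#' @export
dispersions <- function(model) {
  r <- exp(model@params$logR)
  names(r) <- model@geneIds
  r
}

# ---- forward passes (internal) ---------------------------------------

asRowMatrix <- function(z, d) {
  if (is.null(dim(z))) z <- matrix(z, ncol = d, byrow = FALSE)
  stopifnot(ncol(z) == d)
  z
}

encoderForward <- function(model, x) {
  p <- model@params
  act <- model@config$activation
  nH <- length(model@config$encoderHidden)
  pre <- vector("list", nH)
  hid <- vector("list", nH)
  h <- x
  for (i in seq_len(nH)) {
    pre[[i]] <- sweep(h %*% p[[paste0("encW", i)]], 2,
                      p[[paste0("encB", i)]], "+")
    hid[[i]] <- applyActivation(pre[[i]], act)
    h <- hid[[i]]
  }
  mu <- sweep(h %*% p$encWmu, 2, p$encBmu, "+")
  lv <- sweep(h %*% p$encWlv, 2, p$encBlv, "+")
  lv <- pmin(pmax(lv, -10), 10)  # clamp for numerical stability
  list(pre = pre, hid = hid, mu = mu, logVar = lv, input = x)
}

decoderForward <- function(model, z) {
  p <- model@params
  act <- model@config$activation
  z <- asRowMatrix(z, model@config$latentDim)
  nH <- length(model@config$decoderHidden)
  pre <- vector("list", nH)
  hid <- vector("list", nH)
  h <- z
  for (i in seq_len(nH)) {
    pre[[i]] <- sweep(h %*% p[[paste0("decW", i)]], 2,
                      p[[paste0("decB", i)]], "+")
    hid[[i]] <- applyActivation(pre[[i]], act)
    h <- hid[[i]]
  }
  A <- sweep(h %*% p$decWout, 2, p$decBout, "+")
  rho <- if (model@config$decoderLink == "softplus") {
    softplus(A) + 1e-8
  } else A
  list(pre = pre, hid = hid, z = z, A = A, rho = rho)
}

#' Decode latent points to per-gene NB means
#'
#' Runs the decoder at latent points `z` and scales the normalized output
#' by `cellScale` (the per-cell mean count). With the default softplus
#' link the result is strictly positive and differentiable in `z`.
#'
#' @param model An [NBVAE-class] model.
#' @param z Latent point (vector) or matrix of points (one per row).
#' @param cellScale Positive scalar or per-row vector multiplying the
#'   normalized decoder output.
#' @return Matrix of NB means (points x genes), gene identifiers as
#'   column names.
#' @export
decodeMean <- function(model, z, cellScale = 1) {
  if (any(!is.finite(z))) stop("non-finite latent point")
  if (any(cellScale <= 0)) stop("cellScale must be positive")
  fw <- decoderForward(model, z)
  m <- fw$rho * cellScale
  colnames(m) <- model@geneIds
  m
}

#' Encode expression profiles to the latent space
#'
#' Maps normalized (mean-scaled, log1p) expression through the encoder and
#' returns the posterior means; optionally a reparameterized posterior
#' sample as well.
#'
#' @param model An [NBVAE-class] model.
#' @param x Matrix of normalized expression, cells in rows, columns in the
#'   model's gene order (or a genes x cells matrix with matching
#'   rownames, which is transposed automatically).
#' @param sample If TRUE, also return one posterior sample per cell drawn
#'   with the model seed.
#' @return List with `mu` (posterior means), `logVar`, and `z` (the sample
#'   when requested, otherwise `mu`).
#' @export
encodeCells <- function(model, x, sample = FALSE) {
  G <- length(model@geneIds)
  if (is.null(dim(x))) x <- matrix(x, ncol = G)
  if (ncol(x) != G && nrow(x) == G) x <- t(x)
  if (ncol(x) != G) {
    stop("input has ", ncol(x), " genes; model expects ", G)
  }
  fw <- encoderForward(model, x)
  z <- fw$mu
  if (sample) {
    set.seed(model@config$seed)
    z <- fw$mu + exp(0.5 * fw$logVar) *
      matrix(rnorm(length(fw$mu)), nrow(fw$mu), ncol(fw$mu))
  }
  list(mu = fw$mu, logVar = fw$logVar, z = z)
}

# Latent embeddings of a (preprocessed) counts container: posterior means
# of the lognorm assay, cells in rows.
#' Posterior-mean latent embedding of all cells
#' @param model An [NBVAE-class] model.
#' @param sce Preprocessed container with a `lognorm` assay restricted to
#'   the model's genes.
#' @return Cells x latentDim matrix with cell identifiers as rownames.
#' @export
latentEmbedding <- function(model, sce) {
  x <- t(assay(sce, "lognorm")[model@geneIds, , drop = FALSE])
  z <- encodeCells(model, x)$mu
  rownames(z) <- colnames(sce)
  z
}

auxForward <- function(model, z, name) {
  h <- model@auxHeads[[name]]
  if (is.null(h)) stop("unknown aux head: ", name)
  p <- model@params
  z <- asRowMatrix(z, model@config$latentDim)
  lin <- drop(z %*% p[[paste0("auxW_", name)]]) + p[[paste0("auxB_", name)]]
  if (h$kind == "binary") sigmoid(lin) else lin
}

#' Predict auxiliary head outputs
#'
#' @param model An [NBVAE-class] model with at least one auxiliary head.
#' @param z Latent point(s), one per row.
#' @param name Head name.
#' @return Numeric vector: probabilities for binary heads, real values for
#'   continuous heads.
#' @export
predictAux <- function(model, z, name) auxForward(model, z, name)

# ---- checkpointing ----------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file archive holding a schema version, the configuration, all
#' parameters, gene list, aux head specs and training history.
#'
#' @param model An [NBVAE-class] model.
#' @param path Checkpoint file path.
#' @return `saveNBVAE` returns `path` invisibly; `loadNBVAE` returns the
#'   restored model.
#' @export
saveNBVAE <- function(model, path) {
  obj <- list(schema = 1L, config = model@config, params = model@params,
              geneIds = model@geneIds, auxHeads = model@auxHeads,
              history = model@history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveNBVAE
#' @export
loadNBVAE <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema != 1L) {
    stop("unsupported checkpoint schema")
  }
  new("NBVAE", config = obj$config, params = obj$params,
      geneIds = obj$geneIds, auxHeads = obj$auxHeads,
      history = obj$history)
}
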