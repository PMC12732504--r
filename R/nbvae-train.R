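## Training of the NB beta-VAE. Gradients are hand-written reverse-mode
## passes over the MLP forward computations in nbvae-model.R; the model is
## small enough that base-R matrix products (BLAS) carry the load.

#' Closed-form KL divergence of the diagonal Gaussian posterior
#'
#' `KL(N(mu, sigma^2) || N(0, I)) = 1/2 * sum(mu^2 + sigma^2 - 1 -
#' log sigma^2)`, averaged over the rows (cells) of the inputs. Always
#' non-negative, zero exactly at the standard normal posterior.
#'
#' @param mu Posterior means (cells x latent dims).
#' @param logVar Posterior log-variances, same shape.
#' @return Scalar mean KL divergence.
#' @export
gaussianKL <- function(mu, logVar) {
  mu <- as.matrix(mu); logVar <- as.matrix(logVar)
  mean(rowSums(0.5 * (mu^2 + exp(logVar) - 1 - logVar)))
}

#' Auxiliary head loss on partially observed labels
#'
#' Binary heads: mean binary cross-entropy over the observed labels;
#' continuous heads: mean absolute error. Missing labels are excluded from
#' the average (not zero-filled), so the gradient scale does not depend on
#' the label fraction; if no label is observed the loss is exactly 0.
#' The result is multiplied by the head's weight `alpha`.
#'
#' @param head An [auxHead()] specification.
#' @param predictions Head outputs per cell (probabilities for binary).
#' @param labels Numeric labels with `NA` marking missing entries.
#' @return Scalar weighted loss.
#' @export
auxLoss <- function(head, predictions, labels) {
  obs <- which(!is.na(labels))
  if (!length(obs)) return(0)
  y <- labels[obs]; p <- predictions[obs]
  if (head$kind == "binary") {
    if (!all(y %in% c(0, 1))) stop("binary head received non-binary labels")
    eps <- 1e-12
    head$alpha * mean(-(y * log(p + eps) + (1 - y) * log(1 - p + eps)))
  } else {
    head$alpha * mean(abs(p - y))
  }
}

#' Evaluate the beta-VAE objective on a batch of raw counts
#'
#' Deterministic evaluation: cells are encoded to their posterior means,
#' decoded, and the negative binomial reconstruction loss plus
#' `beta`-weighted KL term are returned. The per-cell scale (mean count)
#' and the normalized encoder input are derived from the raw counts, so
#' the function needs nothing but the count matrix.
#'
#' @param model An [NBVAE-class] model.
#' @param xRaw Count matrix, cells in rows, genes in the model's order.
#' @param beta KL weight.
#' @return List with `total`, `recon` (mean NB negative log likelihood per
#'   cell) and `kl`.
#' @export
elboLoss <- function(model, xRaw, beta) {
  xRaw <- asRowMatrix(xRaw, length(model@geneIds))
  if (!nrow(xRaw)) stop("empty batch")
  scale <- rowMeans(xRaw)
  if (any(scale <= 0)) stop("all-zero cell in batch")
  xIn <- log1p(xRaw / scale)
  enc <- encoderForward(model, xIn)
  dec <- decoderForward(model, enc$mu)
  m <- dec$rho * scale
  R <- matrix(exp(model@params$logR), nrow(xRaw), ncol(xRaw), byrow = TRUE)
  recon <- mean(-rowSums(nbLogPMF(xRaw, m, R)))
  kl <- gaussianKL(enc$mu, enc$logVar)
  total <- recon + beta * kl
  if (!is.finite(total)) stop("non-finite loss")
  list(total = total, recon = recon, kl = kl)
}

# One forward+backward pass; returns losses and gradients for all params.
# xIn/xRaw: B x G, scale: B, eps: B x d reparameterization noise,
# labels: named list of per-cell numeric vectors (NA = unobserved).
nbvaeGradients <- function(model, xIn, xRaw, scale, eps, beta, labels) {
  p <- model@params
  cfg <- model@config
  act <- cfg$activation
  B <- nrow(xIn); G <- ncol(xIn)
  grads <- list()

  enc <- encoderForward(model, xIn)
  sigma <- exp(0.5 * enc$logVar)
  z <- enc$mu + sigma * eps
  dec <- decoderForward(model, z)
  m <- dec$rho * scale
  R <- matrix(exp(p$logR), B, G, byrow = TRUE)

  recon <- mean(-rowSums(nbLogPMF(xRaw, m, R)))
  kl <- gaussianKL(enc$mu, enc$logVar)

  # reconstruction backward
  dM <- nbNLLGradMean(xRaw, m, R) / B
  grads$logR <- colSums(nbNLLGradLogR(xRaw, m, R)) / B
  dRho <- dM * scale
  dA <- if (cfg$decoderLink == "softplus") dRho * sigmoid(dec$A) else dRho
  nDec <- length(cfg$decoderHidden)
  hLast <- if (nDec) dec$hid[[nDec]] else dec$z
  grads$decWout <- crossprod(hLast, dA)
  grads$decBout <- colSums(dA)
  dH <- dA %*% t(p$decWout)
  if (nDec) {
    for (i in rev(seq_len(nDec))) {
      dPre <- dH * activationGrad(dec$pre[[i]], act)
      inp <- if (i > 1) dec$hid[[i - 1]] else dec$z
      grads[[paste0("decW", i)]] <- crossprod(inp, dPre)
      grads[[paste0("decB", i)]] <- colSums(dPre)
      dH <- dPre %*% t(p[[paste0("decW", i)]])
    }
  }
  dZ <- dH

  # auxiliary heads
  auxLosses <- numeric(0)
  for (h in model@auxHeads) {
    y <- labels[[h$name]]
    wn <- paste0("auxW_", h$name); bn <- paste0("auxB_", h$name)
    if (is.null(y)) y <- rep(NA_real_, B)
    obs <- which(!is.na(y))
    lin <- drop(z %*% p[[wn]]) + p[[bn]]
    if (!length(obs)) {
      auxLosses[h$name] <- 0
      grads[[wn]] <- matrix(0, cfg$latentDim, 1)
      grads[[bn]] <- 0
      next
    }
    dLin <- numeric(B)
    if (h$kind == "binary") {
      pr <- sigmoid(lin)
      eps2 <- 1e-12
      auxLosses[h$name] <- h$alpha *
        mean(-(y[obs] * log(pr[obs] + eps2) +
               (1 - y[obs]) * log(1 - pr[obs] + eps2)))
      dLin[obs] <- h$alpha * (pr[obs] - y[obs]) / length(obs)
    } else {
      auxLosses[h$name] <- h$alpha * mean(abs(lin[obs] - y[obs]))
      dLin[obs] <- h$alpha * sign(lin[obs] - y[obs]) / length(obs)
    }
    grads[[wn]] <- crossprod(z, matrix(dLin, B, 1))
    grads[[bn]] <- sum(dLin)
    dZ <- dZ + outer(dLin, drop(p[[wn]]))
  }

  # KL backward and reparameterization
  dMu <- dZ + beta * enc$mu / B
  dLv <- dZ * (0.5 * sigma * eps) + beta * 0.5 * (exp(enc$logVar) - 1) / B

  nEnc <- length(cfg$encoderHidden)
  hTop <- if (nEnc) enc$hid[[nEnc]] else enc$input
  grads$encWmu <- crossprod(hTop, dMu); grads$encBmu <- colSums(dMu)
  grads$encWlv <- crossprod(hTop, dLv); grads$encBlv <- colSums(dLv)
  dH <- dMu %*% t(p$encWmu) + dLv %*% t(p$encWlv)
  if (nEnc) {
    for (i in rev(seq_len(nEnc))) {
      dPre <- dH * activationGrad(enc$pre[[i]], act)
      inp <- if (i > 1) enc$hid[[i - 1]] else enc$input
      grads[[paste0("encW", i)]] <- crossprod(inp, dPre)
      grads[[paste0("encB", i)]] <- colSums(dPre)
      dH <- dPre %*% t(p[[paste0("encW", i)]])
    }
  }

  total <- recon + beta * kl + sum(auxLosses)
  list(grads = grads, total = total, recon = recon, kl = kl,
       aux = auxLosses)
}

#' Train the NB beta-VAE
#'
#' Minibatch Adam training of the beta-VAE objective (NB reconstruction +
#' beta * KL + weighted auxiliary losses) with linear KL annealing and
#' early stopping on the validation loss. Fully deterministic given the
#' configuration seed and single-threaded numerics.
#'
#' @param model An untrained model from [newNBVAE()] (its config drives
#'   all optimization settings).
#' @param sce Preprocessed counts container restricted to the model's
#'   genes, with `lognorm`, `scaleFactor` and `partition` columns (see
#'   [preprocessCounts()]).
#' @param labels Named list of label tables (one per auxiliary head,
#'   names matching head names); see [readLabels()]. Cells absent from a
#'   table, or with empty labels, simply do not contribute to that head.
#' @param verbose Print per-epoch losses.
#' @return The trained model, with `history` holding per-epoch train and
#'   validation losses, the beta schedule, the stopping epoch and the best
#'   validation loss. Best-validation weights are restored.
#' @export
trainNBVAE <- function(model, sce, labels = list(), verbose = FALSE) {
  cfg <- model@config
  part <- colData(sce)$partition
  if (is.null(part)) stop("no partition column; run splitCells first")
  if (!"lognorm" %in% assayNames(sce)) stop("no lognorm assay present")
  geneOrder <- model@geneIds
  if (!all(geneOrder %in% rownames(sce))) {
    stop("container lacks model genes")
  }
  xAll <- t(assay(sce, "lognorm")[geneOrder, , drop = FALSE])
  rawAll <- t(counts(sce)[geneOrder, , drop = FALSE])
  scAll <- colData(sce)$scaleFactor
  trainIdx <- which(part == "train")
  valIdx <- which(part == "val")
  if (!length(trainIdx) || !length(valIdx)) {
    stop("train and validation partitions must be non-empty")
  }

  labVec <- list()
  for (h in model@auxHeads) {
    tab <- labels[[h$name]]
    v <- rep(NA_real_, ncol(sce))
    if (!is.null(tab)) {
      idx <- match(tab$cell_id, colnames(sce))
      ok <- !is.na(idx)
      v[idx[ok]] <- tab$label[ok]
      if ((h$kind == "binary") != (attr(tab, "kind") %in% "binary")) {
        stop("label kind does not match head kind for '", h$name, "'")
      }
    }
    labVec[[h$name]] <- v
  }

  params <- model@params
  mAdam <- lapply(params, function(x) x * 0)
  vAdam <- lapply(params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8
  step <- 0L
  bestVal <- Inf; bestParams <- params; sinceBest <- 0L
  hist <- list(epoch = integer(), trainLoss = numeric(),
               valLoss = numeric(), valRecon = numeric(),
               valKL = numeric(), beta = numeric())
  stoppedEpoch <- 0L

  set.seed(cfg$seed)
  evalModel <- model
  for (epoch in seq_len(cfg$maxEpochs)) {
    ord <- sample(trainIdx)
    nb <- max(1L, ceiling(length(ord) / cfg$batchSize))
    epochLoss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[seq((bi - 1) * cfg$batchSize + 1,
                     min(bi * cfg$batchSize, length(ord)))]
      step <- step + 1L
      beta <- if (cfg$betaAnnealSteps > 0) {
        cfg$betaFinal * min(1, step / cfg$betaAnnealSteps)
      } else cfg$betaFinal
      eps <- matrix(rnorm(length(idx) * cfg$latentDim),
                    length(idx), cfg$latentDim)
      evalModel@params <- params
      res <- nbvaeGradients(evalModel, xAll[idx, , drop = FALSE],
                            rawAll[idx, , drop = FALSE], scAll[idx],
                            eps, beta, lapply(labVec, `[`, idx))
      if (!is.finite(res$total)) {
        model@history <- hist
        stop("training aborted: non-finite loss at epoch ", epoch,
             ", step ", step)
      }
      epochLoss <- epochLoss + res$total * length(idx)
      for (nm in names(res$grads)) {
        g <- res$grads[[nm]]
        mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g
        vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g^2
        mh <- mAdam[[nm]] / (1 - b1^step)
        vh <- vAdam[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - cfg$learningRate *
          mh / (sqrt(vh) + adamEps)
      }
    }
    epochLoss <- epochLoss / length(trainIdx)
    betaNow <- if (cfg$betaAnnealSteps > 0) {
      cfg$betaFinal * min(1, step / cfg$betaAnnealSteps)
    } else cfg$betaFinal

    evalModel@params <- params
    val <- validationLoss(evalModel, xAll[valIdx, , drop = FALSE],
                          rawAll[valIdx, , drop = FALSE], scAll[valIdx],
                          cfg$betaFinal, lapply(labVec, `[`, valIdx))
    hist$epoch <- c(hist$epoch, epoch)
    hist$trainLoss <- c(hist$trainLoss, epochLoss)
    hist$valLoss <- c(hist$valLoss, val$total)
    hist$valRecon <- c(hist$valRecon, val$recon)
    hist$valKL <- c(hist$valKL, val$kl)
    hist$beta <- c(hist$beta, betaNow)
    if (verbose) {
      message(sprintf("epoch %3d  train %.3f  val %.3f (recon %.3f)",
                      epoch, epochLoss, val$total, val$recon))
    }
    stoppedEpoch <- epoch
    if (val$total < bestVal - 1e-9) {
      bestVal <- val$total
      bestParams <- params
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest > cfg$patience) break
    }
  }

  model@params <- bestParams
  hist$stoppedEpoch <- stoppedEpoch
  hist$bestValLoss <- bestVal
  model@history <- hist
  validObject(model)
  model
}

# Deterministic validation loss: posterior mean, no sampling.
validationLoss <- function(model, xIn, xRaw, scale, beta, labels) {
  enc <- encoderForward(model, xIn)
  dec <- decoderForward(model, enc$mu)
  m <- dec$rho * scale
  R <- matrix(exp(model@params$logR), nrow(xIn), ncol(xIn), byrow = TRUE)
  recon <- mean(-rowSums(nbLogPMF(xRaw, m, R)))
  kl <- gaussianKL(enc$mu, enc$logVar)
  auxTotal <- 0
  for (h in model@auxHeads) {
    pred <- auxForward(model, enc$mu, h$name)
    auxTotal <- auxTotal + auxLoss(h, pred, labels[[h$name]])
  }
  list(total = recon + beta * kl + auxTotal, recon = recon, kl = kl)
}
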