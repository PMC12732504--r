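## Perturbation probe: exact reverse-mode gradients of decoder outputs
## (or auxiliary heads) with respect to latent variables, Euler flow
## integration, evaluation-point sampling and density masking.

resolveOutput <- function(model, output) {
  if (is.numeric(output)) {
    g <- as.integer(output)
    if (g < 1 || g > length(model@geneIds)) stop("gene index out of range")
    return(list(type = "gene", index = g, name = model@geneIds[g]))
  }
  if (output %in% model@geneIds) {
    return(list(type = "gene", index = match(output, model@geneIds),
                name = output))
  }
  if (output %in% names(model@auxHeads)) {
    return(list(type = "aux", name = output))
  }
  stop("unknown output: ", output)
}

#' Gradient of a model output with respect to the latent variables
#'
#' Exact reverse-mode derivative of the chosen scalar output — the
#' normalized NB mean of one gene (`cellScale = 1`), or an auxiliary head
#' output — evaluated at one or many latent points. This is the
#' perturbation flow direction at each point.
#'
#' @param model An [NBVAE-class] model.
#' @param z Latent point (vector) or matrix of points, one per row.
#' @param output Gene identifier, gene index, or auxiliary head name.
#' @return Matrix of gradients, one row per latent point.
#' @export
outputGradient <- function(model, z, output) {
  out <- resolveOutput(model, output)
  z <- asRowMatrix(z, model@config$latentDim)
  if (any(!is.finite(z))) stop("non-finite latent point")
  if (out$type == "aux") {
    h <- model@auxHeads[[out$name]]
    w <- drop(model@params[[paste0("auxW_", out$name)]])
    if (h$kind == "binary") {
      pr <- auxForward(model, z, out$name)
      return(outer(pr * (1 - pr), w))
    }
    return(matrix(w, nrow(z), length(w), byrow = TRUE))
  }
  dec <- decoderForward(model, z)
  g <- out$index
  p <- model@params
  cfg <- model@config
  dA <- if (cfg$decoderLink == "softplus") sigmoid(dec$A[, g]) else
    rep(1, nrow(z))
  nDec <- length(cfg$decoderHidden)
  dH <- outer(dA, p$decWout[, g])
  if (nDec) {
    for (i in rev(seq_len(nDec))) {
      dPre <- dH * activationGrad(dec$pre[[i]], cfg$activation)
      dH <- dPre %*% t(p[[paste0("decW", i)]])
    }
  }
  dH
}

#' Full decoder Jacobian at one latent point
#'
#' Derivatives of every normalized gene mean with respect to `z`, as a
#' latentDim x genes matrix. Used by the scoring module, where all genes
#' are probed at once.
#'
#' @param model An [NBVAE-class] model.
#' @param z A single latent point.
#' @return latentDim x genes Jacobian matrix.
#' @export
decoderJacobian <- function(model, z) {
  cfg <- model@config
  z <- asRowMatrix(z, cfg$latentDim)
  stopifnot(nrow(z) == 1)
  dec <- decoderForward(model, z)
  p <- model@params
  nDec <- length(cfg$decoderHidden)
  # J = dA/dz (latentDim x genes) accumulated left-to-right
  M <- diag(cfg$latentDim)
  h <- z
  for (i in seq_len(nDec)) {
    M <- M %*% p[[paste0("decW", i)]]
    M <- sweep(M, 2, drop(activationGrad(dec$pre[[i]], cfg$activation)),
               "*")
  }
  J <- M %*% p$decWout
  if (cfg$decoderLink == "softplus") {
    J <- sweep(J, 2, drop(sigmoid(dec$A)), "*")
  }
  colnames(J) <- model@geneIds
  J
}

#' Evaluate a gradient field over a set of latent points
#'
#' @param model An [NBVAE-class] model.
#' @param points Matrix of latent points, one per row.
#' @param output Gene identifier/index or auxiliary head name.
#' @return A [GradientField-class] object.
#' @export
computeGradientField <- function(model, points, output) {
  points <- asRowMatrix(points, model@config$latentDim)
  vec <- outputGradient(model, points, output)
  out <- resolveOutput(model, output)
  new("GradientField", points = points, vectors = vec,
      outputName = out$name, mask = logical(0))
}

#' Mean gradient field over a gene list
#'
#' Average of the per-gene gradient fields for a user-supplied set of
#' genes (e.g., a co-regulated module); the flow of their joint gradual
#' knockdown or overexpression.
#'
#' @param model An [NBVAE-class] model.
#' @param points Matrix of latent points.
#' @param genes Character vector of gene identifiers.
#' @return A [GradientField-class] with `outputName` `"mean(<n> genes)"`.
#' @export
meanGradientField <- function(model, points, genes) {
  stopifnot(length(genes) >= 1)
  points <- asRowMatrix(points, model@config$latentDim)
  acc <- matrix(0, nrow(points), ncol(points))
  for (g in genes) acc <- acc + outputGradient(model, points, g)
  new("GradientField", points = points, vectors = acc / length(genes),
      outputName = sprintf("mean(%d genes)", length(genes)),
      mask = logical(0))
}

#' Integrate a perturbation flow trajectory
#'
#' Forward-Euler iteration `z[t+1] = z[t] + delta * grad(y)(z[t])` for
#' `nSteps` steps, recording the decoded output value at every visited
#' state. Negative `delta` simulates knockdown of the probed output,
#' positive `delta` overexpression. If a non-finite state is reached the
#' trajectory is truncated with a warning.
#'
#' @param model An [NBVAE-class] model.
#' @param z0 Starting latent point.
#' @param output Gene identifier/index or auxiliary head name.
#' @param delta Signed step size (default -0.001, a knockdown step).
#' @param nSteps Number of Euler steps (default 400).
#' @return A [FlowTrajectory-class] object.
#' @export
integrateFlow <- function(model, z0, output, delta = -0.001,
                          nSteps = 400) {
  stopifnot(nSteps >= 0)
  out <- resolveOutput(model, output)
  d <- model@config$latentDim
  z <- drop(asRowMatrix(z0, d))
  pts <- matrix(NA_real_, nSteps + 1, d)
  vals <- numeric(nSteps + 1)
  evalOutput <- function(zz) {
    if (out$type == "gene") decodeMean(model, zz)[1, out$index]
    else auxForward(model, zz, out$name)[1]
  }
  pts[1, ] <- z
  vals[1] <- evalOutput(z)
  truncated <- FALSE
  t <- 0L
  while (t < nSteps) {
    g <- drop(outputGradient(model, pts[t + 1, ], output))
    zNext <- pts[t + 1, ] + delta * g
    if (any(!is.finite(zNext))) {
      warning("flow truncated at step ", t + 1, ": non-finite state")
      truncated <- TRUE
      break
    }
    t <- t + 1L
    pts[t + 1, ] <- zNext
    vals[t + 1] <- evalOutput(zNext)
  }
  keep <- seq_len(t + 1)
  new("FlowTrajectory", points = pts[keep, , drop = FALSE], delta = delta,
      outputName = out$name, outputValues = vals[keep],
      truncated = truncated)
}

#' Sample latent evaluation points
#'
#' Either a seeded uniform subsample (without replacement) of observed
#' cell embeddings, or a regular 2-D lattice over their bounding box
#' (2-D latents only).
#'
#' @param latents Matrix of observed latent embeddings, one cell per row.
#' @param n For `"subsample"`: number of points to draw. For `"grid2d"`:
#'   lattice resolution per axis (`n x n` points in total).
#' @param strategy `"subsample"` or `"grid2d"`.
#' @param seed Integer seed (subsampling only).
#' @return Matrix of evaluation points.
#' @export
sampleEvalPoints <- function(latents, n, strategy = c("subsample", "grid2d"),
                             seed = 1) {
  strategy <- match.arg(strategy)
  latents <- as.matrix(latents)
  if (strategy == "subsample") {
    if (n > nrow(latents)) stop("n exceeds the number of available points")
    set.seed(seed)
    latents[sort(sample.int(nrow(latents), n)), , drop = FALSE]
  } else {
    if (ncol(latents) != 2) stop("grid2d requires a 2-D latent space")
    xs <- seq(min(latents[, 1]), max(latents[, 1]), length.out = n)
    ys <- seq(min(latents[, 2]), max(latents[, 2]), length.out = n)
    as.matrix(expand.grid(z1 = xs, z2 = ys))
  }
}

# Distance from each row of `a` to its k-th nearest row of `b`.
kthNNDistance <- function(a, b, k) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  apply(d2, 1, function(row) sqrt(sort(row, partial = k)[k]))
}

#' Density mask for latent evaluation points
#'
#' Keeps a candidate point iff the distance to its `k`-th nearest training
#' latent does not exceed the given quantile of that same statistic
#' computed over the training latents themselves — masking away regions
#' distant from where the model saw data.
#'
#' @param points Candidate points (rows).
#' @param trainLatents Training latent embeddings (rows).
#' @param k Neighbor order (default 15).
#' @param quantile Quantile of the training k-NN distance distribution
#'   used as the cutoff (default 0.99).
#' @return Logical vector, `TRUE` for points kept.
#' @export
densityMask <- function(points, trainLatents, k = 15, quantile = 0.99) {
  points <- as.matrix(points); trainLatents <- as.matrix(trainLatents)
  stopifnot(k >= 1, quantile > 0, quantile <= 1)
  if (k > nrow(trainLatents)) stop("k exceeds the training set size")
  dCand <- kthNNDistance(points, trainLatents, k)
  dRef <- kthNNDistance(trainLatents, trainLatents, k)
  dCand <= stats::quantile(dRef, quantile, names = FALSE)
}

#' Apply a density mask to a gradient field
#' @param field A [GradientField-class].
#' @param trainLatents Training latent embeddings.
#' @inheritParams densityMask
#' @return The field with its `mask` slot filled.
#' @export
maskField <- function(field, trainLatents, k = 15, quantile = 0.99) {
  field@mask <- densityMask(field@points, trainLatents, k, quantile)
  field
}

#' Export a gradient field as TSV
#' @param field A [GradientField-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeGradientField <- function(field, path) {
  d <- ncol(field@points)
  tab <- data.frame(field@points, field@vectors)
  names(tab) <- c(paste0("z", seq_len(d)), paste0("grad", seq_len(d)))
  tab$mask <- if (length(field@mask)) field@mask else TRUE
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a flow trajectory as TSV
#' @param traj A [FlowTrajectory-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  d <- ncol(traj@points)
  tab <- data.frame(step = seq_len(nrow(traj@points)) - 1L, traj@points,
                    value = traj@outputValues)
  names(tab) <- c("step", paste0("z", seq_len(d)), "value")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
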