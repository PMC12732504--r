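#' @import methods
#' @importFrom stats rnorm runif rbinom rnbinom median prcomp p.adjust
#'   phyper quantile sd var qnbinom dist rlnorm
#' @importFrom utils head read.delim write.table modifyList
NULL

#' Negative-binomial beta-VAE model
#'
#' Holds encoder and decoder parameters of a multilayer perceptron
#' variational autoencoder with a negative binomial observation model,
#' one free dispersion per gene (shared across cells), and optional
#' auxiliary output heads (binary condition or continuous covariate)
#' attached to the latent space. The decoder output is strictly positive
#' and differentiable everywhere with respect to the latent variables,
#' which is what the perturbation probe relies on.
#'
#' @slot config Named list of model hyperparameters (see [nbvaeConfig()]).
#' @slot params Named list of weight matrices and bias vectors.
#' @slot geneIds Character vector of decoder output gene identifiers.
#' @slot auxHeads Named list of auxiliary head specifications
#'   (see [auxHead()]).
#' @slot history Named list with per-epoch training diagnostics
#'   (filled by [trainNBVAE()]).
#' @export
setClass("NBVAE", representation(
  config = "list",
  params = "list",
  geneIds = "character",
  auxHeads = "list",
  history = "list"
))

setValidity("NBVAE", function(object) {
  msgs <- character()
  p <- object@params
  if (!length(p)) msgs <- c(msgs, "empty parameter list")
  if (!is.null(p$logR)) {
    if (length(p$logR) != length(object@geneIds)) {
      msgs <- c(msgs, "one dispersion per gene required")
    }
    if (any(!is.finite(p$logR))) msgs <- c(msgs, "non-finite dispersions")
  }
  if (any(!vapply(p, function(x) all(is.finite(x)), logical(1)))) {
    msgs <- c(msgs, "non-finite parameters")
  }
  if (length(msgs)) msgs else TRUE
})

#' Gradient field over latent space
#'
#' A set of latent points together with one gradient vector per point for a
#' chosen model output (a gene or an auxiliary head) — the perturbation
#' flow map evaluated at those points.
#'
#' @slot points Numeric matrix, one latent point per row.
#' @slot vectors Numeric matrix of identical shape; row i is the gradient of
#'   the probed output at `points[i, ]`.
#' @slot outputName Identifier of the probed output.
#' @slot mask Logical vector flagging points kept by density masking
#'   (length 0 when no mask has been applied).
#' @export
setClass("GradientField", representation(
  points = "matrix",
  vectors = "matrix",
  outputName = "character",
  mask = "logical"
))

setValidity("GradientField", function(object) {
  msgs <- character()
  if (!identical(dim(object@points), dim(object@vectors))) {
    msgs <- c(msgs, "points and vectors must have identical dimensions")
  }
  if (any(!is.finite(object@points)) || any(!is.finite(object@vectors))) {
    msgs <- c(msgs, "points and vectors must be finite")
  }
  if (length(object@mask) &&
      length(object@mask) != nrow(object@points)) {
    msgs <- c(msgs, "mask length must equal number of points")
  }
  if (length(msgs)) msgs else TRUE
})

#' Euler flow trajectory in latent space
#'
#' Latent trajectory of the perturbation iteration
#' `z[t+1] = z[t] + delta * grad(y_i)(z[t])` together with the decoded value
#' of the probed output at every step. Negative `delta` simulates knockdown,
#' positive `delta` overexpression.
#'
#' @slot points Numeric matrix with `nSteps + 1` rows (the visited states).
#' @slot delta Signed step size.
#' @slot outputName Identifier of the probed output.
#' @slot outputValues Output value at each visited state.
#' @slot truncated TRUE when the iteration hit a non-finite state and was
#'   stopped early.
#' @export
setClass("FlowTrajectory", representation(
  points = "matrix",
  delta = "numeric",
  outputName = "character",
  outputValues = "numeric",
  truncated = "logical"
))

setValidity("FlowTrajectory", function(object) {
  if (nrow(object@points) != length(object@outputValues)) {
    return("one output value per visited point required")
  }
  TRUE
})

#' Empirical perturbation axis
#'
#' Mean latent displacement between two labeled cell populations,
#' `a = mean(z | label == 1) - mean(z | label == 0)` — e.g., the
#' healthy-to-disease axis used for alignment scoring.
#'
#' @slot axis Numeric displacement vector.
#' @slot groupMeans 2 x d matrix with rows `unperturbed` (0) and
#'   `perturbed` (1).
#' @slot groupSizes Integer vector of group sizes (0 then 1).
#' @export
setClass("PerturbationAxis", representation(
  axis = "numeric",
  groupMeans = "matrix",
  groupSizes = "integer"
))

setValidity("PerturbationAxis", function(object) {
  msgs <- character()
  if (nrow(object@groupMeans) != 2L) {
    msgs <- c(msgs, "groupMeans must have two rows")
  }
  d <- object@groupMeans[2, ] - object@groupMeans[1, ]
  if (max(abs(d - object@axis)) > 1e-12) {
    msgs <- c(msgs, "axis must equal the difference of group means")
  }
  if (length(msgs)) msgs else TRUE
})

#' 2-D projection of a gradient field
#'
#' @slot method Either "pca" or "umap_endpoint".
#' @slot points n x 2 matrix of projected latent points.
#' @slot vectors n x 2 matrix of projected/displayed gradient vectors.
#' @slot projector List describing the fitted projector (rotation and center
#'   for PCA; bridge parameters for UMAP).
#' @export
setClass("Projection2D", representation(
  method = "character",
  points = "matrix",
  vectors = "matrix",
  projector = "list"
))

setValidity("Projection2D", function(object) {
  msgs <- character()
  if (ncol(object@points) != 2L || ncol(object@vectors) != 2L) {
    msgs <- c(msgs, "projected points and vectors must be 2-D")
  }
  if (nrow(object@points) != nrow(object@vectors)) {
    msgs <- c(msgs, "one vector per projected point required")
  }
  if (length(msgs)) msgs else TRUE
})

#' Gene-set collection with background universe
#'
#' Named gene sets (e.g., read from a GMT file) plus the background universe
#' against which overrepresentation is tested.
#'
#' @slot sets Named list of character vectors (gene identifiers).
#' @slot descriptions Named character vector of set descriptions.
#' @slot universe Character vector of background gene identifiers.
#' @export
setClass("GeneSetCollection", representation(
  sets = "list",
  descriptions = "character",
  universe = "character"
))

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets))) {
    msgs <- c(msgs, "sets must be uniquely named")
  }
  if (anyDuplicated(object@universe)) {
    msgs <- c(msgs, "universe must not contain duplicates")
  }
  if (length(msgs)) msgs else TRUE
})
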