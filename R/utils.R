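## Internal numerical helpers shared across modules.

# Numerically stable softplus: log(1 + exp(x)) without overflow for large x.
softplus <- function(x) {
  out <- x
  idx <- x < 30
  out[idx] <- log1p(exp(x[idx]))
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

applyActivation <- function(x, activation) {
  switch(activation,
    softplus = softplus(x),
    relu = pmax(x, 0),
    stop("unknown activation: ", activation)
  )
}

# Derivative of the activation given the pre-activation values.
activationGrad <- function(pre, activation) {
  switch(activation,
    softplus = sigmoid(pre),
    relu = (pre > 0) * 1,
    stop("unknown activation: ", activation)
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a numeric score against binary labels.
#' Ties in the score contribute 1/2, matching the standard definition.
#'
#' @param score Numeric vector of scores (higher = more positive-like).
#' @param label Logical or 0/1 vector of the same length.
#' @return AUROC in `[0, 1]`.
#' @export
aurocScore <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  nPos <- sum(label)
  nNeg <- sum(!label)
  if (nPos == 0L || nNeg == 0L) {
    stop("aurocScore needs both positive and negative labels")
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Locate the python interpreter used for the h5ad and UMAP bridges.
pythonBinary <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found on PATH")
  unname(py)
}

runPythonScript <- function(script, args = character()) {
  path <- system.file("python", script, package = "perturbflow")
  if (!nzchar(path)) stop("bundled python script not found: ", script)
  res <- suppressWarnings(
    system2(pythonBinary(), c(shQuote(path), shQuote(args)),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("python bridge '", script, "' failed:\n", paste(res, collapse = "\n"))
  }
  invisible(res)
}

# Seed helper: all derived seeds stay below 2^31 - 1.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483629L
}
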