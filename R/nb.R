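#' Negative binomial log-probability mass
#'
#' Log pmf of the negative binomial distribution in the mean/dispersion
#' parameterization used throughout the model,
#' \deqn{NB(k; m, r) = \frac{\Gamma(k+r)}{k!\,\Gamma(r)}
#'   \left(\frac{m}{r+m}\right)^k \left(\frac{r}{r+m}\right)^r,}
#' where `m > 0` is the mean and `r > 0` the dispersion. The variance is
#' `m + m^2/r`, so small `r` means strong overdispersion. Computed on the
#' log scale via `lgamma` for numerical stability; finite for all valid
#' inputs. Arguments recycle like in base R density functions.
#'
#' @param k Non-negative integer counts.
#' @param m Positive means.
#' @param r Positive dispersions.
#' @return Log-probabilities, same length as the recycled arguments.
#' @examples
#' nbLogPMF(0, m = 1, r = 1)  # log(1/2)
#' nbLogPMF(1, m = 1, r = 1)  # log(1/4)
#' @export
nbLogPMF <- function(k, m, r) {
  if (any(m <= 0) || any(r <= 0)) {
    stop("nbLogPMF: mean and dispersion must be strictly positive")
  }
  if (any(k < 0) || any(k != floor(k))) {
    stop("nbLogPMF: counts must be non-negative integers")
  }
  lgamma(k + r) - lgamma(k + 1) - lgamma(r) +
    k * (log(m) - log(r + m)) + r * (log(r) - log(r + m))
}

# Gradient of the NB *negative* log likelihood w.r.t. the mean m.
# d(-logNB)/dm = (k + r)/(r + m) - k/m
nbNLLGradMean <- function(k, m, r) {
  (k + r) / (r + m) - k / m
}

# Gradient of the NB negative log likelihood w.r.t. log(r) (per element).
nbNLLGradLogR <- function(k, m, r) {
  dldr <- digamma(k + r) - digamma(r) + log(r) - log(r + m) +
    1 - (k + r) / (r + m)
  -dldr * r
}
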