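# Mantegna Levy-flight step sampler and the weight-parameterized sigmoid
# transfer functions that turn real-valued steps into per-bit selection
# probabilities.

#' Mantegna scale parameter
#'
#' Closed-form standard deviation of the numerator Gaussian in the Mantegna
#' sampler,
#' `sigma_mu = { Gamma(1+beta) sin(pi beta / 2) /
#'               [ Gamma((1+beta)/2) beta 2^((beta-1)/2) ] }^(1/beta)`,
#' with the denominator Gaussian fixed at unit standard deviation.
#'
#' @param beta stability exponent, in (0, 2].
#' @return `sigma_mu` as a single numeric.
#' @examples
#' mantegna_sigma(1.5)  # ~0.6966
#' @export
mantegna_sigma <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta > 2)
    stop("beta must lie in (0, 2]")
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Sample a Levy-flight step vector
#'
#' Per dimension draws `u ~ N(0, sigma_mu^2)` and `v ~ N(0, 1)` and returns
#' `step = alpha * u / |v|^(1/beta)` — the Mantegna simulation of a
#' heavy-tailed Levy-stable step. Dimensions are independent; the result is
#' reproducible from the caller's RNG state.
#'
#' @param d number of dimensions.
#' @param alpha step-size scale (> 0, default 1).
#' @param beta stability exponent in (0, 2] (default 1.5).
#' @param u,v optional test hooks overriding the Gaussian draws.
#' @return Numeric step vector of length `d`.
#' @export
levy_steps <- function(d, alpha = 1, beta = 1.5, u = NULL, v = NULL) {
  stopifnot(d >= 1, alpha > 0)
  sigma <- mantegna_sigma(beta)
  if (is.null(u)) u <- stats::rnorm(d, 0, sigma)
  if (is.null(v)) v <- stats::rnorm(d)
  av <- pmax(abs(v), .Machine$double.xmin)  # keep the ratio finite
  alpha * u / av^(1 / beta)
}

#' Weight-parameterized transfer probability
#'
#' Maps a real step and a per-feature coefficient `gamma` (the Relief
#' weight) to a bit-selection probability:
#' `1 / (1 + exp(-gamma * step))` for `step >= 0` and
#' `1 - 1 / (1 + exp(-gamma * step))` for `step < 0`.
#' Both branches give 0.5 at `step = 0`, the map is symmetric in the step
#' (`p(-s, g) = p(s, g)`), increasing in `gamma` for any nonzero step, and
#' stays below 0.5 when `gamma < 0` — a feature with negative Relief weight
#' is selected with low probability whatever the step. Numerically exact 0/1
#' saturation beyond `|gamma * step| ~ 745`. Vectorized and recycling.
#'
#' @param step numeric step value(s).
#' @param gamma numeric coefficient(s); `gamma = 1` recovers the plain
#'   binary-cuckoo-search sigmoid.
#' @return Probabilities in `[0, 1]`.
#' @export
transfer_probability <- function(step, gamma) {
  z <- gamma * step
  # step >= 0: plogis(z); step < 0: 1 - plogis(z) = plogis(-z)
  ifelse(step >= 0, stats::plogis(z), stats::plogis(-z))
}

#' Binarize a step vector through the transfer function
#'
#' Bit j is set to 1 iff an independent uniform draw is `<=` (inclusive)
#' `transfer_probability(step_j, gamma_j)`. One uniform is consumed per
#' dimension, in order, so the draw is reproducible from the RNG state.
#'
#' @param steps numeric step vector.
#' @param gammas per-dimension coefficients, same length as `steps` (a
#'   scalar is recycled).
#' @return Integer 0/1 vector.
#' @export
binarize_steps <- function(steps, gammas) {
  if (length(gammas) == 1L) gammas <- rep(gammas, length(steps))
  if (length(gammas) != length(steps))
    stop("gammas length must match steps length")
  p <- transfer_probability(steps, gammas)
  as.integer(stats::runif(length(steps)) <= p)
}
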