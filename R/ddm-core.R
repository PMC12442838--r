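#' Joint density of response and response time under the Wiener diffusion model
#'
#' Evaluates the joint (defective) density of a binary response `x` and a
#' response time `t` under the two-boundary Wiener diffusion process with
#' drift rate `mu`, boundary separation `alpha`, nondecision time `ter`,
#' diffusion coefficient fixed at 1 and an unbiased starting point midway
#' between the boundaries. `x = 1` denotes absorption at the upper
#' (affirmative) boundary, `x = 0` at the lower boundary.
#'
#' The infinite sine series is truncated adaptively; for times close to `ter`
#' the evaluation switches to the small-time (Gaussian-mirror) representation
#' of the same density, which converges quickly where the sine series does
#' not. The density is 0 for `t <= ter`.
#'
#' @param x Binary response(s), 0 or 1.
#' @param t Response time(s) in seconds.
#' @param mu Drift rate (evidence accumulation speed, per sqrt-second).
#' @param alpha Boundary separation (> 0).
#' @param ter Nondecision time in seconds (>= 0). Default 0.
#' @param log Return the log density?
#'
#' @return A numeric vector of (log) densities; arguments are recycled.
#'
#' @examples
#' ddm_density(1, 1.2, mu = 0.5, alpha = 1.5, ter = 0.3)
#' # total probability mass is 1:
#' integrate(function(t) ddm_density(1, t, 0.5, 1.5) + ddm_density(0, t, 0.5, 1.5),
#'           0, Inf)
#' @export
ddm_density <- function(x, t, mu, alpha, ter = 0, log = FALSE) {
  if (any(alpha <= 0)) abort("`alpha` must be positive.")
  if (any(ter < 0)) abort("`ter` must be non-negative.")
  if (!all(x %in% c(0, 1))) abort("`x` must be 0 or 1.")
  n <- max(length(x), length(t), length(mu), length(alpha), length(ter))
  x <- rep_len(as.integer(x), n)
  td <- rep_len(t, n) - rep_len(ter, n)
  mu <- rep_len(mu, n)
  alpha <- rep_len(alpha, n)
  signed_mu <- ifelse(x == 1L, mu, -mu)
  lp <- .wfpt_logpdf_cpp(td, signed_mu, alpha)
  lp[td <= 0] <- -Inf
  if (log) lp else exp(lp)
}

#' Defective response-time distribution function of the diffusion model
#'
#' Probability that the process is absorbed at the boundary indicated by `x`
#' at or before time `t`. As `t` grows this approaches the choice probability
#' [choice_prob_raw()] (for `x = 1`) or its complement.
#'
#' @inheritParams ddm_density
#' @return Numeric vector of probabilities.
#' @export
ddm_cdf <- function(x, t, mu, alpha, ter = 0) {
  if (any(alpha <= 0)) abort("`alpha` must be positive.")
  n <- max(length(x), length(t), length(mu), length(alpha), length(ter))
  x <- rep_len(as.integer(x), n)
  td <- pmax(rep_len(t, n) - rep_len(ter, n), 0)
  mu <- rep_len(mu, n)
  signed_mu <- ifelse(x == 1L, mu, -mu)
  .wfpt_cdf_cpp(td, signed_mu, rep_len(alpha, n))
}

#' Choice probability of the affirmative response
#'
#' Marginal probability of absorption at the upper boundary for drift `mu` and
#' boundary separation `alpha` with an unbiased start, which reduces to the
#' logistic function of `alpha * mu`. This is the link between the
#' first-passage density and the IRT response function of the D-diffusion
#' model.
#'
#' @param mu Drift rate(s).
#' @param alpha Boundary separation(s) (> 0).
#' @return Probabilities in (0, 1); overflow saturates to 0/1.
#' @examples
#' choice_prob_raw(0, 2)          # 0.5
#' choice_prob_raw(log(3) / 2, 2) # 0.75
#' @export
choice_prob_raw <- function(mu, alpha) {
  if (any(alpha <= 0)) abort("`alpha` must be positive.")
  plogis(alpha * mu)
}

#' Mean decision time of the diffusion process
#'
#' Expected first-passage time (excluding nondecision time), marginal over the
#' absorbing boundary: `(alpha / (2 mu)) tanh(mu alpha / 2)`, with the
#' continuous limit `alpha^2 / 4` at `mu = 0`. Used as an independent oracle
#' for the numerical density and sampler. It is maximal at `mu = 0` and
#' decreases in `|mu|`, which is the distance-difficulty principle: responses
#' are fastest far from an item's difficulty.
#'
#' @inheritParams choice_prob_raw
#' @return Mean decision times in seconds.
#' @export
mean_decision_time <- function(mu, alpha) {
  if (any(alpha <= 0)) abort("`alpha` must be positive.")
  n <- max(length(mu), length(alpha))
  mu <- rep_len(mu, n)
  alpha <- rep_len(alpha, n)
  out <- ifelse(abs(mu) < 1e-8, alpha^2 / 4,
                (alpha / (2 * mu)) * tanh(mu * alpha / 2))
  out
}

#' Sample responses and response times from the diffusion model
#'
#' Draws `(x, t)` pairs whose joint law is the two-boundary Wiener
#' first-passage distribution, by inverse-CDF sampling of the defective
#' response-time distribution of the sampled boundary. Deterministic given
#' `set.seed()`.
#'
#' @param n Number of draws (ignored when the parameter vectors are longer).
#' @param mu,alpha,ter Diffusion parameters, recycled to the output length.
#' @return A tibble with columns `x` (0/1) and `t` (seconds, always > `ter`).
#' @examples
#' set.seed(1)
#' draws <- sample_response(1000, mu = 0.6, alpha = 1.8, ter = 0.4)
#' mean(draws$x)             # ~ choice_prob_raw(0.6, 1.8)
#' mean(draws$t) - 0.4       # ~ mean_decision_time(0.6, 1.8)
#' @export
sample_response <- function(n, mu, alpha, ter = 0) {
  if (any(alpha <= 0)) abort("`alpha` must be positive.")
  if (any(ter < 0)) abort("`ter` must be non-negative.")
  n <- max(n, length(mu), length(alpha), length(ter))
  res <- .wfpt_sample_cpp(rep_len(mu, n), rep_len(alpha, n), rep_len(ter, n))
  tibble(x = res$x, t = res$t)
}

# Fine-step Euler random-walk sampler. Cross-validation oracle for
# sample_response() only; O(t / step) per draw, never used in the pipeline.
sample_response_walk <- function(n, mu, alpha, ter = 0, step = 1e-3) {
  x <- integer(n)
  t <- numeric(n)
  sq <- sqrt(step)
  for (i in seq_len(n)) {
    pos <- alpha / 2
    k <- 0L
    while (pos > 0 && pos < alpha) {
      pos <- pos + mu * step + sq * rnorm(1)
      k <- k + 1L
    }
    x[i] <- as.integer(pos >= alpha)
    t[i] <- ter + k * step
  }
  tibble(x = x, t = t)
}
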