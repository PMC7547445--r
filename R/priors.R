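#' Gaussian-mixture prior on the true treatment effect
#'
#' Constructs a mixture-of-normals prior for the true treatment effect
#' \eqn{\theta = -\log(HR)} (negative log hazard ratio; positive values mean
#' benefit).  Each component is specified by a weight, a mean and a variance.
#' Following the planning convention for time-to-event endpoints, a component
#' variance may be given as an event count `n_events`, which is converted to
#' the variance `4 / n_events`; likewise means may be given on the
#' hazard-ratio scale via `hr_means` and are converted by `-log()`.
#'
#' @param weights Numeric vector of nonnegative component weights summing
#'   to 1.
#' @param means Component means on the \eqn{-\log(HR)} scale.  Exactly one of
#'   `means` and `hr_means` must be given.
#' @param variances Component variances (strictly positive).  Exactly one of
#'   `variances` and `n_events` must be given.
#' @param hr_means Component means on the hazard-ratio scale; converted to
#'   `-log(hr_means)`.
#' @param n_events Event counts expressing per-component certainty; converted
#'   to variances `4 / n_events`.
#'
#' @return An object of class `prior_spec`: a list with elements `weights`,
#'   `means` and `variances` of equal length.
#'
#' @examples
#' # two-component oncology prior: strong effect (HR 0.69) with weight 0.3,
#' # moderate effect (HR 0.88) with weight 0.7
#' pr <- prior_spec(weights = c(0.3, 0.7), hr_means = c(0.69, 0.88),
#'                  n_events = c(210, 420))
#' prior_mean(pr)
#' @export
prior_spec <- function(weights, means = NULL, variances = NULL,
                       hr_means = NULL, n_events = NULL) {
  if (is.null(means) == is.null(hr_means))
    stop("exactly one of `means` and `hr_means` must be supplied")
  if (is.null(variances) == is.null(n_events))
    stop("exactly one of `variances` and `n_events` must be supplied")
  if (!is.null(hr_means)) {
    if (any(hr_means <= 0)) stop("`hr_means` must be strictly positive")
    means <- -log(hr_means)
  }
  if (!is.null(n_events)) {
    if (any(n_events <= 0)) stop("`n_events` must be strictly positive")
    variances <- 4 / n_events
  }
  x <- structure(
    list(weights = as.numeric(weights), means = as.numeric(means),
         variances = as.numeric(variances)),
    class = "prior_spec")
  validate_prior_spec(x)
  x
}

validate_prior_spec <- function(prior) {
  if (!inherits(prior, "prior_spec")) stop("not a `prior_spec` object")
  k <- length(prior$weights)
  if (k < 1L || length(prior$means) != k || length(prior$variances) != k)
    stop("weights, means and variances must have equal length >= 1")
  if (any(!is.finite(prior$weights)) || any(prior$weights < 0))
    stop("weights must be finite and nonnegative")
  if (abs(sum(prior$weights) - 1) > 1e-12)
    stop("weights must sum to 1 (within 1e-12), got ",
         format(sum(prior$weights), digits = 15))
  if (any(!is.finite(prior$means))) stop("means must be finite")
  if (any(!is.finite(prior$variances)) || any(prior$variances <= 0))
    stop("variances must be finite and strictly positive")
  invisible(prior)
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Mixture prior on theta = -log(HR),", length(x$weights),
      "component(s)\n")
  print(data.frame(weight = x$weights, mean = x$means,
                   hr = exp(-x$means), variance = x$variances,
                   row.names = NULL), ...)
  cat(sprintf("mean %.6f  (HR scale %.4f)\n",
              prior_mean(x), exp(-prior_mean(x))))
  invisible(x)
}

#' Mixture prior density
#'
#' Evaluates the prior density
#' \eqn{f(\theta) = \sum_k w_k\, N(\theta; m_k, v_k)}.
#'
#' @param theta Numeric vector of effect values (\eqn{-\log(HR)} scale).
#' @param prior A [prior_spec()].
#' @return Nonnegative density values, one per element of `theta`.
#' @export
prior_density <- function(theta, prior) {
  validate_prior_spec(prior)
  dens <- numeric(length(theta))
  for (k in seq_along(prior$weights))
    dens <- dens + prior$weights[k] *
      stats::dnorm(theta, prior$means[k], sqrt(prior$variances[k]))
  dens
}

#' Prior mean of the treatment effect
#'
#' Returns \eqn{\sum_k w_k m_k}, the prior mean of \eqn{\theta}.  Because the
#' phase II estimator is unbiased given \eqn{\theta}, this also equals the
#' unconditional mean of the phase II estimate, the reference point for the
#' selection bias \eqn{E[\hat\theta_2 \mid \mathrm{go}] - E[\hat\theta_2]}.
#'
#' @param prior A [prior_spec()].
#' @param hr_scale If `TRUE`, return `exp(-mean)` (hazard-ratio scale).
#' @return The prior mean (scalar).
#' @export
prior_mean <- function(prior, hr_scale = FALSE) {
  validate_prior_spec(prior)
  m <- sum(prior$weights * prior$means)
  if (hr_scale) exp(-m) else m
}

#' Prior variance of the treatment effect
#'
#' Mixture variance \eqn{\sum_k w_k (v_k + m_k^2) - (\sum_k w_k m_k)^2}.
#'
#' @inheritParams prior_mean
#' @return The prior variance (scalar).
#' @export
prior_variance <- function(prior) {
  validate_prior_spec(prior)
  m <- sum(prior$weights * prior$means)
  sum(prior$weights * (prior$variances + prior$means^2)) - m^2
}

#' Sample from the mixture prior
#'
#' Draws independent values of \eqn{\theta}: a component is selected with
#' probability \eqn{w_k}, then a Gaussian draw is taken from it.  Used by the
#' Monte Carlo program simulator.
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws (positive integer).
#' @param seed Optional integer seed.  If `NULL` the current RNG stream is
#'   used (so callers managing one stream per simulation batch stay
#'   reproducible).
#' @return Numeric vector of length `n`.
#' @export
prior_sample <- function(prior, n, seed = NULL) {
  validate_prior_spec(prior)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  k <- sample.int(length(prior$weights), n, replace = TRUE,
                  prob = prior$weights)
  stats::rnorm(n, prior$means[k], sqrt(prior$variances[k]))
}

# TRUE when two priors describe the same distribution (used to decide whether
# the phase II and phase III effects are one draw or independent draws)
same_prior <- function(p2, p3) {
  length(p2$weights) == length(p3$weights) &&
    isTRUE(all.equal(p2$weights, p3$weights, tolerance = 1e-12)) &&
    isTRUE(all.equal(p2$means, p3$means, tolerance = 1e-12)) &&
    isTRUE(all.equal(p2$variances, p3$variances, tolerance = 1e-12))
}
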