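#' Adjustment of the phase II treatment effect estimate
#'
#' Specifies how the phase II estimate \eqn{\hat\theta_2} is discounted
#' before it is used for phase III planning (and, optionally, for the
#' go/no-go decision):
#' \describe{
#'   \item{`"none"`}{no discounting, \eqn{\hat\theta_2^u = \hat\theta_2}.}
#'   \item{`"multiplicative"`}{retention factor \eqn{\lambda}:
#'     \eqn{\hat\theta_2^\lambda = \lambda\,\hat\theta_2}; a fraction
#'     \eqn{1-\lambda} of the observed effect is discarded.}
#'   \item{`"additive"`}{lower one-sided \eqn{(1-\alpha_{CI})} confidence
#'     bound: \eqn{\hat\theta_2^{\alpha_{CI}} = \hat\theta_2 -
#'     z_{1-\alpha_{CI}}\sqrt{4/d_2}}.}
#' }
#' \eqn{\lambda = 1} and \eqn{\alpha_{CI} = 0.5} leave the estimate
#' untouched.
#'
#' The canonical design grids restrict \eqn{\lambda} to `[0.2, 1]` and
#' \eqn{\alpha_{CI}} to `[0.025, 0.5]`; for sensitivity work this
#' constructor accepts any \eqn{\lambda \in (0, 1]} and
#' \eqn{\alpha_{CI} \in (0, 0.5]}.
#'
#' @param kind One of `"none"`, `"multiplicative"`, `"additive"`.
#' @param parameter \eqn{\lambda} or \eqn{\alpha_{CI}}; must be absent for
#'   `kind = "none"`.
#' @return An object of class `adjustment_spec`.
#' @examples
#' adjustment_spec("multiplicative", 0.75)
#' adjustment_spec("additive", 0.45)
#' @export
adjustment_spec <- function(kind = c("none", "multiplicative", "additive"),
                            parameter = NULL) {
  kind <- match.arg(kind)
  if (kind == "none") {
    if (!is.null(parameter))
      stop("`parameter` must be absent for kind = \"none\"")
    parameter <- NA_real_
  } else {
    if (is.null(parameter) || length(parameter) != 1L ||
        !is.finite(parameter))
      stop("a single finite `parameter` is required for kind = \"", kind,
           "\"")
    if (kind == "multiplicative" && (parameter <= 0 || parameter > 1))
      stop("multiplicative parameter (lambda) must lie in (0, 1]")
    if (kind == "additive" && (parameter <= 0 || parameter > 0.5))
      stop("additive parameter (alpha_CI) must lie in (0, 0.5]")
  }
  structure(list(kind = kind, parameter = as.numeric(parameter)),
            class = "adjustment_spec")
}

#' @export
print.adjustment_spec <- function(x, ...) {
  if (x$kind == "none") cat("Adjustment: none\n")
  else cat(sprintf("Adjustment: %s, parameter %s\n", x$kind,
                   format(x$parameter)))
  invisible(x)
}

#' Phase III test specification
#'
#' One-sided significance level \eqn{\alpha} and type II error \eqn{\beta}
#' of the phase III log-rank test of \eqn{H_0: \theta \le 0}.
#'
#' @param alpha One-sided significance level, in (0, 0.5).  Default 0.025.
#' @param beta Type II error (power \eqn{1-\beta}), in (0, 0.5).
#'   Default 0.1.
#' @return An object of class `test_spec` carrying `alpha`, `beta` and the
#'   standard-normal quantiles `z_alpha` (\eqn{z_{1-\alpha}}) and `z_beta`
#'   (\eqn{z_{1-\beta}}).
#' @export
test_spec <- function(alpha = 0.025, beta = 0.1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5)
    stop("`alpha` must lie in (0, 0.5)")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 0.5)
    stop("`beta` must lie in (0, 0.5)")
  structure(list(alpha = alpha, beta = beta,
                 z_alpha = stats::qnorm(1 - alpha),
                 z_beta = stats::qnorm(1 - beta)),
            class = "test_spec")
}

#' @export
print.test_spec <- function(x, ...) {
  cat(sprintf("Phase III test: one-sided alpha = %g, power = %g\n",
              x$alpha, 1 - x$beta))
  invisible(x)
}

#' Apply an adjustment to a phase II estimate
#'
#' Returns the discounted estimate: unchanged for `"none"`,
#' \eqn{\lambda\,\hat\theta_2} for `"multiplicative"`, and
#' \eqn{\hat\theta_2 - z_{1-\alpha_{CI}}\sqrt{4/d_2}} for `"additive"`.
#' The result may be nonpositive (in particular for the additive rule);
#' callers planning phase III must check this.
#'
#' @param theta2_hat Phase II estimate(s), \eqn{-\log(HR)} scale.
#' @param adj An [adjustment_spec()].
#' @param d2 Total phase II events (positive), fixing the estimate's
#'   standard error \eqn{\sqrt{4/d_2}}.
#' @return Adjusted estimate(s), same length as `theta2_hat`.
#' @export
adjust_estimate <- function(theta2_hat, adj, d2) {
  stopifnot(inherits(adj, "adjustment_spec"))
  if (!is.numeric(d2) || length(d2) != 1L || d2 <= 0)
    stop("`d2` must be a positive scalar")
  switch(adj$kind,
    none = theta2_hat,
    multiplicative = adj$parameter * theta2_hat,
    additive = theta2_hat -
      stats::qnorm(1 - adj$parameter) * sqrt(4 / d2))
}

#' Go threshold on the raw estimate scale
#'
#' The go rule is "go if \eqn{\hat\theta_2^{s_1} \ge \kappa}", where
#' \eqn{s_1} is the (possibly adjusted) estimate used for decision making.
#' This rewrites the rule as a threshold on the raw \eqn{\hat\theta_2}:
#' \eqn{\kappa} itself when the decision uses the unadjusted estimate,
#' \eqn{\kappa/\lambda} under multiplicative decision adjustment, and
#' \eqn{\kappa + z_{1-\alpha_{CI}}\sqrt{4/d_2}} under additive decision
#' adjustment.
#'
#' @param kappa Decision threshold on the \eqn{-\log(HR)} scale
#'   (\eqn{\kappa = -\log(HR_{go})}).
#' @param adj An [adjustment_spec()].
#' @param apply_to_decision If `TRUE`, the adjusted estimate is used in the
#'   decision rule (set-ups \eqn{S(\lambda,\lambda)},
#'   \eqn{S(\alpha_{CI},\alpha_{CI})}); otherwise the raw estimate decides.
#' @param d2 Total phase II events.
#' @return Threshold on the raw \eqn{\hat\theta_2} scale.
#' @export
effective_threshold <- function(kappa, adj, apply_to_decision, d2) {
  stopifnot(inherits(adj, "adjustment_spec"))
  if (!isTRUE(apply_to_decision) || adj$kind == "none") return(kappa)
  if (adj$kind == "multiplicative") {
    if (adj$parameter <= 0) stop("lambda must be positive")
    kappa / adj$parameter
  } else {
    kappa + stats::qnorm(1 - adj$parameter) * sqrt(4 / d2)
  }
}

#' Phase III event number from the planning estimate
#'
#' Required total phase III events for a balanced two-arm log-rank test with
#' power \eqn{1-\beta} at one-sided level \eqn{\alpha}, planned at the
#' (adjusted) phase II estimate:
#' \deqn{D_3 = \frac{4 (z_{1-\alpha} + z_{1-\beta})^2}{(\hat\theta_2^{s_2})^2}.}
#' The value is kept continuous: all program-level expectations integrate
#' over \eqn{D_3} as a smooth function of the estimate.
#'
#' @param adjusted_estimate Planning estimate(s), strictly positive.
#' @param test A [test_spec()].
#' @return Continuous required event number(s).
#' @export
planned_events_phase3 <- function(adjusted_estimate, test = test_spec()) {
  stopifnot(inherits(test, "test_spec"))
  if (any(!is.finite(adjusted_estimate)) || any(adjusted_estimate <= 0))
    stop("`adjusted_estimate` must be strictly positive and finite")
  4 * (test$z_alpha + test$z_beta)^2 / adjusted_estimate^2
}
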