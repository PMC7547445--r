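#' Candidate program design
#'
#' One point of the design space: phase II events `d2`, go/no-go threshold
#' (given either as `kappa` on the \eqn{-\log(HR)} scale or as `hr_go` with
#' \eqn{\kappa = -\log(HR_{go})}), the adjustment applied to the phase II
#' estimate for phase III planning, and whether the same adjusted estimate
#' also drives the go decision.
#'
#' The five canonical program set-ups map onto (`adj$kind`,
#' `apply_to_decision`) as: `"u,u"` = none; `"u,lambda"` = multiplicative,
#' `FALSE`; `"lambda,lambda"` = multiplicative, `TRUE`; `"u,alphaCI"` =
#' additive, `FALSE`; `"alphaCI,alphaCI"` = additive, `TRUE`.  When the
#' decision rule is adjusted it always uses the same parameter as planning.
#'
#' @param d2 Total phase II events (positive integer).
#' @param kappa Decision threshold, \eqn{-\log(HR)} scale.  Give exactly one
#'   of `kappa` and `hr_go`.
#' @param hr_go Decision threshold on the hazard-ratio scale.
#' @param adj An [adjustment_spec()]; default no adjustment.
#' @param apply_to_decision Logical; adjust the estimate used in the go rule
#'   as well as in planning.
#' @return An object of class `design_point`.
#' @examples
#' design_point(d2 = 82, hr_go = 0.80)
#' design_point(d2 = 84, hr_go = 0.81,
#'              adj = adjustment_spec("multiplicative", 0.75),
#'              apply_to_decision = TRUE)
#' @export
design_point <- function(d2, kappa = NULL, hr_go = NULL,
                         adj = adjustment_spec("none"),
                         apply_to_decision = FALSE) {
  if (is.null(kappa) == is.null(hr_go))
    stop("exactly one of `kappa` and `hr_go` must be supplied")
  if (!is.null(hr_go)) {
    if (hr_go <= 0) stop("`hr_go` must be positive")
    kappa <- -log(hr_go)
  }
  if (!is.numeric(d2) || length(d2) != 1L || d2 < 1)
    stop("`d2` must be a positive integer")
  if (!is.finite(kappa)) stop("`kappa` must be finite")
  stopifnot(inherits(adj, "adjustment_spec"))
  structure(list(d2 = as.numeric(d2), kappa = as.numeric(kappa),
                 adj = adj, apply_to_decision = isTRUE(apply_to_decision)),
            class = "design_point")
}

#' @export
print.design_point <- function(x, ...) {
  cat(sprintf("Design: d2 = %g, HR_go = %.4f (kappa = %.6f)\n",
              x$d2, exp(-x$kappa), x$kappa))
  print(x$adj)
  cat("Adjustment applied to go decision:", x$apply_to_decision, "\n")
  invisible(x)
}

# set-up shorthand <-> (kind, apply_to_decision)
parse_set_up <- function(set_up) {
  tab <- list(
    "u,u"               = list(kind = "none",           s1 = FALSE),
    "u,lambda"          = list(kind = "multiplicative", s1 = FALSE),
    "lambda,lambda"     = list(kind = "multiplicative", s1 = TRUE),
    "u,alphaCI"         = list(kind = "additive",       s1 = FALSE),
    "alphaCI,alphaCI"   = list(kind = "additive",       s1 = TRUE))
  if (!set_up %in% names(tab))
    stop("unknown set-up \"", set_up, "\"; use one of: ",
         paste(names(tab), collapse = ", "))
  tab[[set_up]]
}

set_up_label <- function(kind, apply_to_decision) {
  if (kind == "none") return("u,u")
  s2 <- if (kind == "multiplicative") "lambda" else "alphaCI"
  paste0(if (apply_to_decision) s2 else "u", ",", s2)
}

#' Quadrature settings
#'
#' Settings for the numerical layers of the characteristics engine.  The
#' engine integrates the true effect \eqn{\theta}, the phase III test
#' statistic, and (when distinct) the phase III effect \eqn{\theta_3} in
#' closed form per Gaussian mixture component; only the phase II estimate
#' \eqn{\hat\theta_2} is integrated numerically, by Gauss-Legendre
#' quadrature with `nodes_estimate` nodes on the go region truncated at
#' `truncation` marginal standard deviations.  `nodes_theta` sizes the
#' \eqn{\theta} grid in contexts where that direction *is* handled
#' numerically (density normalization checks; non-conjugate extensions).
#'
#' @param nodes_theta Nodes for numeric \eqn{\theta} integration (>= 16).
#' @param nodes_estimate Gauss-Legendre nodes over \eqn{\hat\theta_2}
#'   (>= 16).  Default 64; doubling changes the default-scenario
#'   characteristics by less than 1e-4 relative.
#' @param truncation Integration limits in marginal standard deviations
#'   (>= 6).  Default 8.
#' @param scheme Quadrature scheme identifier (only `"gauss-legendre"`).
#' @return An object of class `quadrature_spec` with cached reference nodes
#'   on `[0, 1]`.
#' @export
quadrature_spec <- function(nodes_theta = 64, nodes_estimate = 64,
                            truncation = 8, scheme = "gauss-legendre") {
  if (nodes_theta < 16 || nodes_estimate < 16)
    stop("at least 16 quadrature nodes are required per dimension")
  if (truncation < 6) stop("`truncation` must be at least 6 SDs")
  scheme <- match.arg(scheme, "gauss-legendre")
  ref <- pracma::gaussLegendre(as.integer(nodes_estimate), 0, 1)
  structure(list(nodes_theta = as.integer(nodes_theta),
                 nodes_estimate = as.integer(nodes_estimate),
                 truncation = truncation, scheme = scheme,
                 ref_x = ref$x, ref_w = ref$w),
            class = "quadrature_spec")
}

#' @export
print.quadrature_spec <- function(x, ...) {
  cat(sprintf("Quadrature: %s, %d theta / %d estimate nodes, +-%g SD\n",
              x$scheme, x$nodes_theta, x$nodes_estimate, x$truncation))
  invisible(x)
}

#' Design feasibility
#'
#' A design is feasible when the planning estimate is strictly positive
#' everywhere in the go region, so that the phase III event number
#' \eqn{D_3 \propto 1/(\hat\theta_2^{s_2})^2} is bounded there.  The binding
#' case is additive planning with an unadjusted decision rule
#' (\eqn{S(u, \alpha_{CI})}): the design is infeasible when
#' \eqn{\kappa - z_{1-\alpha_{CI}}\sqrt{4/d_2} \le 0}, because \eqn{D_3}
#' then has a non-integrable singularity inside the go region.
#'
#' @param design A [design_point()].
#' @return `TRUE`/`FALSE`.
#' @export
design_feasible <- function(design) {
  stopifnot(inherits(design, "design_point"))
  keff <- effective_threshold(design$kappa, design$adj,
                              design$apply_to_decision, design$d2)
  adjust_estimate(keff, design$adj, design$d2) > 0
}

assert_feasible <- function(design) {
  if (!design_feasible(design))
    stop(sprintf(paste0("infeasible design: planning estimate nonpositive ",
                        "in the go region (d2 = %g, kappa = %.4f, %s",
                        "%s)"),
                 design$d2, design$kappa, design$adj$kind,
                 if (design$adj$kind == "none") ""
                 else sprintf(" %.4g", design$adj$parameter)))
  invisible(design)
}

# Core engine, vectorized over designs.
#
# All designs in one call share the adjustment kind and the
# apply-to-decision flag; d2, kappa and the adjustment parameter vary.
# For each phase II mixture component k (weight w_k, mean m_k, variance
# v_k) and sigma2 = 4/d2:
#   theta2_hat marginal:  N(m_k, v_k + sigma2)               (closed form)
#   p_go      = sum_k w_k (1 - Phi((keff - m_k)/sqrt(v_k + sigma2)))
#   theta | theta2_hat = t, comp k:  N(mu_k(t), tau_k^2) with
#       tau_k^2 = v_k sigma2/(v_k + sigma2),
#       mu_k(t) = (m_k sigma2 + t v_k)/(v_k + sigma2)
#   P(T3 > u | t, comp k) = Phi((c(t) mu_k(t) - u)/sqrt(1 + c(t)^2 tau_k^2))
# with c(t) = sqrt(D3)/2 = (z_{1-alpha}+z_{1-beta})/a(t) and a(t) the
# planning estimate.  When the phase III effect has its own prior, the
# success layer instead averages Phi((c m3_j - u)/sqrt(1 + c^2 v3_j)) over
# the phase III components (independent draw).  The remaining integral over
# t on [keff, tmax] is Gauss-Legendre.
#
# Returns a data.frame with p_go, d3 (unconditional E[D3 1{go}]), e2
# (conditional planning estimate; NA when p_go ~ 0), psp, p_cat1..3.
characteristics_engine <- function(d2, kappa, kind, parameter,
                                   apply_to_decision,
                                   prior2, prior3, test, thresholds, quad) {
  n <- length(d2)
  stopifnot(length(kappa) == n)
  parameter <- rep_len(as.numeric(parameter), n)
  sigma2 <- 4 / d2
  sd2 <- sqrt(sigma2)
  zci <- if (kind == "additive") stats::qnorm(1 - parameter) else numeric(n)

  keff <- if (!apply_to_decision || kind == "none") kappa
          else if (kind == "multiplicative") kappa / parameter
          else kappa + zci * sd2

  w2 <- prior2$weights; m2 <- prior2$means; v2 <- prior2$variances
  K <- length(w2)
  # marginal SD of theta2_hat per design x component
  sdm <- sqrt(outer(sigma2, v2, "+"))                          # n x K
  p_go <- as.vector((1 - stats::pnorm((keff - rep(m2, each = n)) / sdm)) %*%
                      w2)

  tmax <- do.call(pmax, lapply(seq_len(K),
                               function(k) m2[k] + quad$truncation *
                                 sdm[, k]))
  len <- pmax(tmax - keff, 0)
  tt <- keff + len %o% quad$ref_x                              # n x q nodes
  wt <- len %o% quad$ref_w                                     # n x q weights

  a <- switch(kind,
              none = tt,
              multiplicative = parameter * tt,
              additive = tt - zci * sd2)
  zsum <- test$z_alpha + test$z_beta
  cc <- zsum / a                                  # sqrt(D3)/2, n x q
  D3 <- 4 * cc^2

  shared <- same_prior(prior2, prior3)
  l1 <- -log(thresholds[1]); l2 <- -log(thresholds[2])
  u0 <- test$z_alpha

  if (!shared) {
    # independent phase III effect: success layer free of the phase II
    # posterior, averaged over the phase III mixture once
    w3 <- prior3$weights; m3 <- prior3$means; v3 <- prior3$variances
    S0 <- S1 <- S2 <- 0
    for (j in seq_along(w3)) {
      den <- sqrt(1 + cc^2 * v3[j])
      S0 <- S0 + w3[j] * stats::pnorm((cc * m3[j] - u0) / den)
      S1 <- S1 + w3[j] * stats::pnorm((cc * m3[j] - u0 - l1 * cc) / den)
      S2 <- S2 + w3[j] * stats::pnorm((cc * m3[j] - u0 - l2 * cc) / den)
    }
  }

  d3 <- e2n <- psp <- p1 <- p2 <- p3 <- numeric(n)
  for (k in seq_len(K)) {
    dk <- w2[k] * stats::dnorm((tt - m2[k]) / sdm[, k]) / sdm[, k]
    wdk <- wt * dk
    d3 <- d3 + rowSums(wdk * D3)
    e2n <- e2n + rowSums(wdk * a)
    if (shared) {
      tau2 <- v2[k] * sigma2 / (v2[k] + sigma2)
      mu <- (m2[k] * sigma2 + tt * v2[k]) / (v2[k] + sigma2)
      den <- sqrt(1 + cc^2 * tau2)
      S0 <- stats::pnorm((cc * mu - u0) / den)
      S1 <- stats::pnorm((cc * mu - u0 - l1 * cc) / den)
      S2 <- stats::pnorm((cc * mu - u0 - l2 * cc) / den)
    }
    psp <- psp + rowSums(wdk * S0)
    p1 <- p1 + rowSums(wdk * (S0 - S1))
    p2 <- p2 + rowSums(wdk * (S1 - S2))
    p3 <- p3 + rowSums(wdk * S2)
  }
  e2 <- ifelse(p_go > 1e-12, e2n / p_go, NA_real_)
  data.frame(p_go = p_go, d3 = d3, e2 = e2, psp = psp,
             p_cat1 = p1, p_cat2 = p2, p_cat3 = p3)
}

engine_one <- function(design, prior2, prior3, test, thresholds, quad) {
  assert_feasible(design)
  validate_prior_spec(prior2); validate_prior_spec(prior3)
  characteristics_engine(design$d2, design$kappa, design$adj$kind,
                         design$adj$parameter, design$apply_to_decision,
                         prior2, prior3, test, thresholds, quad)
}

#' Probability to go to phase III
#'
#' The prior-weighted probability that the (possibly adjusted) phase II
#' estimate reaches the go threshold,
#' \eqn{p_{go} = \int P(\hat\theta_2^{s_1} \ge \kappa \mid \theta)
#' f(\theta)\, d\theta}.  For a Gaussian mixture prior this is evaluated in
#' closed form.
#'
#' @param design A [design_point()].
#' @param prior Prior on the true effect ([prior_spec()]).
#' @param quad A [quadrature_spec()].
#' @return Probability in `[0, 1]`.
#' @export
prob_go <- function(design, prior, quad = quadrature_spec()) {
  assert_feasible(design)
  validate_prior_spec(prior)
  keff <- effective_threshold(design$kappa, design$adj,
                              design$apply_to_decision, design$d2)
  sdm <- sqrt(prior$variances + 4 / design$d2)
  sum(prior$weights * stats::pnorm((keff - prior$means) / sdm,
                                   lower.tail = FALSE))
}

#' Expected phase III events
#'
#' The unconditional expectation
#' \eqn{d_3 = E[D_3(\hat\theta_2^{s_2})\,
#' 1\{\hat\theta_2^{s_1} \ge \kappa\}]}: the planned phase III event number,
#' counted as zero for programs stopped after phase II.  The conditional
#' value given a go decision is `d3 / prob_go`.
#'
#' @inheritParams prob_go
#' @param test A [test_spec()].
#' @return Nonnegative expected event number.
#' @export
expected_events_phase3 <- function(design, prior, test = test_spec(),
                                   quad = quadrature_spec()) {
  engine_one(design, prior, prior, test, c(0.95, 0.85), quad)$d3
}

#' Expected planning estimate given a go decision
#'
#' \eqn{e_2 = E[\hat\theta_2^{s_2} \mid \hat\theta_2^{s_1} \ge \kappa]}, the
#' mean of the (adjusted) estimate actually used for phase III planning,
#' conditional on going.  Returned together with its hazard-ratio-scale
#' value \eqn{\varepsilon_2 = \exp(-e_2)}.  For an unadjusted design with
#' \eqn{\kappa > 0}, `e2` exceeds the prior mean: the selection bias of the
#' go rule.
#'
#' @inheritParams prob_go
#' @return List with elements `e2` and `eps2`.
#' @export
expected_conditional_estimate <- function(design, prior,
                                          quad = quadrature_spec()) {
  # D3-free: defined whenever p_go > 0, even where the event-number
  # integrand would be singular (planning estimate crossing zero)
  validate_prior_spec(prior)
  keff <- effective_threshold(design$kappa, design$adj,
                              design$apply_to_decision, design$d2)
  sdm <- sqrt(prior$variances + 4 / design$d2)
  p_go <- sum(prior$weights *
                stats::pnorm((keff - prior$means) / sdm,
                             lower.tail = FALSE))
  if (p_go <= 1e-12)
    stop("probability to go is numerically zero; e2 undefined")
  tmax <- max(prior$means + quad$truncation * sdm)
  t <- keff + (tmax - keff) * quad$ref_x
  wt <- (tmax - keff) * quad$ref_w
  a <- adjust_estimate(t, design$adj, design$d2)
  marg <- numeric(length(t))
  for (k in seq_along(prior$weights))
    marg <- marg + prior$weights[k] *
      stats::dnorm(t, prior$means[k], sdm[k])
  e2 <- sum(wt * a * marg) / p_go
  list(e2 = e2, eps2 = exp(-e2))
}

#' Probability of a successful program
#'
#' The joint probability of a go decision and a significant phase III
#' result (\eqn{T_3 > z_{1-\alpha}}), averaged over the prior(s) -- the
#' program-level assurance.  With distinct phase II and phase III priors
#' the two true effects are treated as independent draws.
#'
#' @inheritParams prob_go
#' @param prior2 Prior for the phase II true effect.
#' @param prior3 Prior for the phase III true effect (defaults to
#'   `prior2`, i.e. one common effect).
#' @param test A [test_spec()].
#' @return Probability, never exceeding [prob_go()].
#' @export
prob_success <- function(design, prior2, prior3 = prior2,
                         test = test_spec(), quad = quadrature_spec()) {
  engine_one(design, prior2, prior3, test, c(0.95, 0.85), quad)$psp
}

#' Benefit-category probabilities
#'
#' Splits the success probability into the three effect-size categories
#' (small, medium, large) defined by the upper bound of the phase III 95%
#' confidence interval for the hazard ratio crossing 1, `thresholds[1]`
#' (default 0.95) and `thresholds[2]` (default 0.85).  On the test-statistic
#' scale the category bounds are \eqn{z_{1-\alpha}},
#' \eqn{z_{1-\alpha} - \log(0.95)\sqrt{D_3}/2} and
#' \eqn{z_{1-\alpha} - \log(0.85)\sqrt{D_3}/2}, moving with \eqn{D_3}
#' inside the integral.  The three probabilities sum to [prob_success()].
#'
#' @inheritParams prob_success
#' @param thresholds Decreasing pair of HR-CI category boundaries in (0,1).
#' @return Numeric vector `c(small, medium, large)`.
#' @export
prob_benefit_categories <- function(design, prior2, prior3 = prior2,
                                    test = test_spec(),
                                    thresholds = c(0.95, 0.85),
                                    quad = quadrature_spec()) {
  if (length(thresholds) != 2L || any(thresholds <= 0) ||
      any(thresholds >= 1) || diff(thresholds) >= 0)
    stop("`thresholds` must be a strictly decreasing pair in (0, 1)")
  ch <- engine_one(design, prior2, prior3, test, thresholds, quad)
  c(small = ch$p_cat1, medium = ch$p_cat2, large = ch$p_cat3)
}

# benefit-category bounds on the T3 scale for a fixed event number
category_bounds <- function(D3, test = test_spec(),
                            thresholds = c(0.95, 0.85)) {
  test$z_alpha - log(thresholds) * sqrt(D3) / 2
}

#' All program characteristics of a design
#'
#' Evaluates every expected characteristic of a candidate design in one
#' quadrature pass: probability to go, expected phase III events
#' (unconditional and given go), conditional planning estimate (log and HR
#' scale), probability of a successful program, benefit-category
#' probabilities, and the selection bias `e2 - prior mean`.
#'
#' @inheritParams prob_success
#' @param thresholds HR-CI category boundaries, decreasing pair.
#' @return Object of class `program_characteristics`.
#' @examples
#' pr <- prior_spec(weights = c(0.3, 0.7), hr_means = c(0.69, 0.88),
#'                  n_events = c(210, 420))
#' program_characteristics(design_point(d2 = 82, hr_go = 0.80), pr)
#' @export
program_characteristics <- function(design, prior2, prior3 = prior2,
                                    test = test_spec(),
                                    thresholds = c(0.95, 0.85),
                                    quad = quadrature_spec()) {
  ch <- engine_one(design, prior2, prior3, test, thresholds, quad)
  structure(list(
    design = design,
    p_go = ch$p_go,
    d3 = ch$d3,
    d3_given_go = if (ch$p_go > 1e-12) ch$d3 / ch$p_go else NA_real_,
    e2 = ch$e2,
    eps2 = exp(-ch$e2),
    psp = ch$psp,
    category_probs = c(small = ch$p_cat1, medium = ch$p_cat2,
                       large = ch$p_cat3),
    bias = ch$e2 - prior_mean(prior2)),
    class = "program_characteristics")
}

#' @export
print.program_characteristics <- function(x, ...) {
  cat(sprintf("Program characteristics (d2 = %g, HR_go = %.2f)\n",
              x$design$d2, exp(-x$design$kappa)))
  cat(sprintf("  p_go  = %.4f\n", x$p_go))
  cat(sprintf("  d3    = %.1f (unconditional), %.1f given go\n",
              x$d3, x$d3_given_go))
  cat(sprintf("  e2    = %.4f (eps2 = %.4f), bias = %+.4f\n",
              x$e2, x$eps2, x$bias))
  cat(sprintf("  PsP   = %.4f  (small %.4f / medium %.4f / large %.4f)\n",
              x$psp, x$category_probs[1], x$category_probs[2],
              x$category_probs[3]))
  invisible(x)
}
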