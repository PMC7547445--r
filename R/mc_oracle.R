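#' Monte Carlo simulation of whole development programs
#'
#' Simulates `n` independent phase II/III programs under the generative
#' model: draw the true effect(s) from the prior(s), draw the phase II
#' estimate \eqn{\hat\theta_2 \mid \theta \sim N(\theta, 4/d_2)}, apply the
#' go rule, and -- on go -- plan \eqn{D_3} from the adjusted estimate, draw
#' the phase III statistic \eqn{T_3 \sim N(\theta_3\sqrt{D_3}/2, 1)},
#' assign the benefit category, and accumulate cost and gain.  The sample
#' means estimate every expected characteristic with quantified sampling
#' error, giving an estimator that is independent of the quadrature engine.
#'
#' A single pseudo-random stream is used with a fixed draw order (phase II
#' effect, phase III effect if distinct, phase II estimate, phase III
#' statistic), so batches are reproducible for a given seed regardless of
#' the go pattern.
#'
#' @param design A [design_point()].
#' @param scenario A [scenario_spec()].
#' @param n Number of simulated programs (>= 1000 recommended for
#'   summaries).
#' @param seed Integer seed.
#' @return Object of class `simulation_batch` with elements `records` (one
#'   row per program: `theta2`, `theta3`, `theta2_hat`, `go`,
#'   `planning_estimate`, `D3`, `T3`, `category`, `cost`, `gain`,
#'   `utility`) and `summary` (mean and standard error per characteristic:
#'   `p_go`, `d3`, `e2`, `psp`, `p_cat1..3`, `cost`, `gain`, `utility`).
#' @examples
#' pr <- prior_spec(weights = c(0.3, 0.7), hr_means = c(0.69, 0.88),
#'                  n_events = c(210, 420))
#' sc <- scenario_spec(pr, benefits = benefit_spec(1000, 2000, 3000))
#' sim <- simulate_program_batch(design_point(d2 = 82, hr_go = 0.8),
#'                               sc, n = 5000, seed = 7)
#' sim$summary
#' @export
simulate_program_batch <- function(design, scenario, n, seed) {
  stopifnot(inherits(design, "design_point"),
            inherits(scenario, "scenario_spec"))
  assert_feasible(design)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer")
  n <- as.integer(n)
  set.seed(as.integer(seed))

  shared <- same_prior(scenario$prior2, scenario$prior3)
  theta2 <- prior_sample(scenario$prior2, n)
  theta3 <- if (shared) theta2 else prior_sample(scenario$prior3, n)
  theta2_hat <- stats::rnorm(n, theta2, sqrt(4 / design$d2))
  z3 <- stats::rnorm(n)   # phase III innovations, drawn for every program

  keff <- effective_threshold(design$kappa, design$adj,
                              design$apply_to_decision, design$d2)
  go <- theta2_hat >= keff
  planning <- ifelse(go, adjust_estimate(theta2_hat, design$adj, design$d2),
                     NA_real_)
  if (any(go) && any(planning[go] <= 0))
    stop("nonpositive planning estimate encountered despite feasibility")
  test <- scenario$test
  D3 <- ifelse(go, 4 * (test$z_alpha + test$z_beta)^2 / planning^2,
               NA_real_)
  T3 <- ifelse(go, theta3 * sqrt(D3) / 2 + z3, NA_real_)

  th <- scenario$benefits$hr_ci_thresholds[2:3]
  b1u <- test$z_alpha - log(th[1]) * sqrt(D3) / 2
  b2u <- test$z_alpha - log(th[2]) * sqrt(D3) / 2
  category <- integer(n)
  category[go & T3 > test$z_alpha] <- 1L
  category[go & T3 > b1u] <- 2L
  category[go & T3 > b2u] <- 3L

  cs <- scenario$costs
  cost <- cs$c02 + design$d2 / cs$xi2 * cs$c2 +
    ifelse(go, cs$c03 + D3 / cs$xi3 * cs$c3, 0)
  gain <- ifelse(category > 0L, scenario$benefits$b[pmax(category, 1L)], 0)

  records <- data.frame(theta2 = theta2, theta3 = theta3,
                        theta2_hat = theta2_hat, go = go,
                        planning_estimate = planning, D3 = D3, T3 = T3,
                        category = category, cost = cost, gain = gain,
                        utility = gain - cost)

  msd <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  e2_draws <- planning[go]
  summary <- rbind(
    p_go = msd(as.numeric(go)),
    d3 = msd(ifelse(go, D3, 0)),
    e2 = if (length(e2_draws) > 1L) msd(e2_draws)
         else c(mean = NA_real_, se = NA_real_),
    psp = msd(as.numeric(category > 0L)),
    p_cat1 = msd(as.numeric(category == 1L)),
    p_cat2 = msd(as.numeric(category == 2L)),
    p_cat3 = msd(as.numeric(category == 3L)),
    cost = msd(cost), gain = msd(gain), utility = msd(gain - cost))
  summary <- data.frame(characteristic = rownames(summary),
                        mean = summary[, "mean"], se = summary[, "se"],
                        row.names = NULL)

  structure(list(design = design, n = n, seed = as.integer(seed),
                 records = records, summary = summary),
            class = "simulation_batch")
}

#' @export
print.simulation_batch <- function(x, ...) {
  cat(sprintf("Simulated programs: n = %d (seed %d), d2 = %g, HR_go = %.2f\n",
              x$n, x$seed, x$design$d2, exp(-x$design$kappa)))
  s <- x$summary
  s$mean <- signif(s$mean, 5); s$se <- signif(s$se, 3)
  print(s, row.names = FALSE)
  invisible(x)
}
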