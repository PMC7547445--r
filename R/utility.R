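#' Cost parameters of a phase II/III program
#'
#' Fixed costs `c02`, `c03` and per-patient costs `c2`, `c3` for phase II
#' and III, all in units of $10^5, plus the event rates `xi2`, `xi3`
#' converting planned events into enrolled patients
#' (patients = events / xi).
#'
#' @param c02,c03 Fixed costs of phase II / phase III ($10^5).
#' @param c2,c3 Variable per-patient costs ($10^5).
#' @param xi2,xi3 Event rates in (0, 1].
#' @return Object of class `cost_spec`.
#' @export
cost_spec <- function(c02 = 100, c03 = 150, c2 = 0.75, c3 = 1,
                      xi2 = 0.7, xi3 = 0.7) {
  vals <- c(c02 = c02, c03 = c03, c2 = c2, c3 = c3)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("costs must be finite and nonnegative")
  if (any(!is.finite(c(xi2, xi3))) || xi2 <= 0 || xi2 > 1 ||
      xi3 <= 0 || xi3 > 1)
    stop("event rates must lie in (0, 1]")
  structure(list(c02 = c02, c03 = c03, c2 = c2, c3 = c3,
                 xi2 = xi2, xi3 = xi3), class = "cost_spec")
}

#' Benefit parameters
#'
#' Gains `b1 <= b2 <= b3` (in $10^5) obtained on program success, tiered by
#' the effect size observed in phase III: the upper bound of the 95%
#' confidence interval for the hazard ratio falling below 1 (small effect,
#' `b1`), below `hr_ci_thresholds[2]` (medium, `b2`), or below
#' `hr_ci_thresholds[3]` (large, `b3`).
#'
#' @param b1,b2,b3 Benefit per category ($10^5), nondecreasing.
#' @param hr_ci_thresholds Decreasing category boundaries for the HR CI
#'   upper bound; default `c(1, 0.95, 0.85)`.
#' @return Object of class `benefit_spec`.
#' @export
benefit_spec <- function(b1, b2, b3, hr_ci_thresholds = c(1, 0.95, 0.85)) {
  b <- c(b1, b2, b3)
  if (any(!is.finite(b)) || any(b < 0) || is.unsorted(b))
    stop("benefits must satisfy 0 <= b1 <= b2 <= b3")
  th <- hr_ci_thresholds
  if (length(th) != 3L || any(th <= 0) || any(th > 1) ||
      any(diff(th) >= 0))
    stop("`hr_ci_thresholds` must be strictly decreasing in (0, 1]")
  structure(list(b = b, hr_ci_thresholds = th), class = "benefit_spec")
}

#' Full planning scenario
#'
#' Bundles everything the utility calculation needs: the prior(s) on the
#' true effect, cost and benefit parameters, the phase III test
#' specification, and an optional budget cap on expected cost.
#'
#' @param prior2 Prior for the phase II true effect ([prior_spec()]).
#' @param prior3 Prior for the phase III true effect; defaults to `prior2`
#'   (one common effect).  When distinct, the two effects are independent
#'   draws.
#' @param costs A [cost_spec()].
#' @param benefits A [benefit_spec()].
#' @param test A [test_spec()].
#' @param budget Optional positive cap `K` on expected program cost.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(prior2, prior3 = NULL, costs = cost_spec(),
                          benefits, test = test_spec(), budget = NULL) {
  validate_prior_spec(prior2)
  if (is.null(prior3)) prior3 <- prior2 else validate_prior_spec(prior3)
  stopifnot(inherits(costs, "cost_spec"), inherits(benefits, "benefit_spec"),
            inherits(test, "test_spec"))
  if (!is.null(budget) && (!is.numeric(budget) || length(budget) != 1L ||
                           budget <= 0))
    stop("`budget` must be a positive scalar (or NULL)")
  structure(list(prior2 = prior2, prior3 = prior3, costs = costs,
                 benefits = benefits, test = test, budget = budget),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Phase II/III planning scenario\n")
  cat(sprintf("  costs ($1e5): c02 = %g, c03 = %g, c2 = %g, c3 = %g, ",
              x$costs$c02, x$costs$c03, x$costs$c2, x$costs$c3))
  cat(sprintf("xi2 = %g, xi3 = %g\n", x$costs$xi2, x$costs$xi3))
  cat(sprintf("  benefits ($1e5): (%s), HR-CI thresholds (%s)\n",
              paste(x$benefits$b, collapse = ", "),
              paste(x$benefits$hr_ci_thresholds, collapse = ", ")))
  cat(sprintf("  test: alpha = %g (one-sided), power = %g\n",
              x$test$alpha, 1 - x$test$beta))
  if (!is.null(x$budget)) cat(sprintf("  budget: E[cost] <= %g\n", x$budget))
  if (!same_prior(x$prior2, x$prior3))
    cat("  distinct phase II / phase III priors (independent effects)\n")
  invisible(x)
}

# cost/gain/utility from an engine characteristics row (vectorized)
utility_columns <- function(ch, d2, scenario) {
  cs <- scenario$costs
  cost <- cs$c02 + d2 / cs$xi2 * cs$c2 + cs$c03 * ch$p_go +
    cs$c3 / cs$xi3 * ch$d3
  b <- scenario$benefits$b
  gain <- b[1] * ch$p_cat1 + b[2] * ch$p_cat2 + b[3] * ch$p_cat3
  data.frame(cost = cost, gain = gain, utility = gain - cost)
}

scenario_engine <- function(design, scenario, quad) {
  engine_one(design, scenario$prior2, scenario$prior3, scenario$test,
             scenario$benefits$hr_ci_thresholds[2:3], quad)
}

#' Expected program cost
#'
#' \deqn{E[c] = c_{02} + \frac{d_2}{\xi_2} c_2 + c_{03}\, p_{go} +
#'   \frac{c_3}{\xi_3}\, d_3,}
#' i.e. the sunk phase II cost plus the phase III cost weighted by the go
#' probability and the expected phase III events.
#'
#' @param design A [design_point()].
#' @param scenario A [scenario_spec()].
#' @param quad A [quadrature_spec()].
#' @return Expected cost in $10^5.
#' @export
expected_cost <- function(design, scenario, quad = quadrature_spec()) {
  ch <- scenario_engine(design, scenario, quad)
  utility_columns(ch, design$d2, scenario)$cost
}

#' Expected program gain
#'
#' \eqn{E[g] = b_1 P_1 + b_2 P_2 + b_3 P_3} with \eqn{P_j} the
#' benefit-category probabilities; bounded above by `b3 * prob_success`.
#'
#' @inheritParams expected_cost
#' @return Expected gain in $10^5.
#' @export
expected_gain <- function(design, scenario, quad = quadrature_spec()) {
  ch <- scenario_engine(design, scenario, quad)
  utility_columns(ch, design$d2, scenario)$gain
}

#' Expected program utility
#'
#' \eqn{E[u] = E[g] - E[c]}, the quantity maximized by
#' [optimize_program()].
#'
#' @inheritParams expected_cost
#' @return Expected utility in $10^5.
#' @export
expected_utility <- function(design, scenario, quad = quadrature_spec()) {
  ch <- scenario_engine(design, scenario, quad)
  utility_columns(ch, design$d2, scenario)$utility
}

#' Design grid for program optimization
#'
#' The optimization set: phase II event numbers, go thresholds on the
#' hazard-ratio scale, and the adjustment-parameter grid matching the
#' set-up.  Defaults follow the canonical oncology illustration:
#' `d2` 50 to 350 by 2, `HR_go` 0.70 to 0.90 by 0.01, \eqn{\lambda} 0.2 to
#' 1 by 0.025, \eqn{\alpha_{CI}} 0.025 to 0.5 by 0.025.  A minimal
#' clinically relevant effect can be imposed by raising the lower end of
#' the `hr_go` range (smaller `hr_go` = stricter rule, so the cap is on
#' `max(hr_go)`).
#'
#' @param set_up Program set-up: `"u,u"`, `"u,lambda"`, `"lambda,lambda"`,
#'   `"u,alphaCI"` or `"alphaCI,alphaCI"` (decision-rule selection s1,
#'   planning selection s2).
#' @param d2 Integer vector of phase II event numbers.
#' @param hr_go Vector of go thresholds, HR scale, in (0, 1).
#' @param adjustment Adjustment-parameter grid; defaults per set-up, `NA`
#'   for `"u,u"`.
#' @return Object of class `optimization_grid`.
#' @export
optimization_grid <- function(set_up = "u,u", d2 = seq(50, 350, by = 2),
                              hr_go = seq(0.70, 0.90, by = 0.01),
                              adjustment = NULL) {
  su <- parse_set_up(set_up)
  if (is.null(adjustment))
    adjustment <- switch(su$kind,
                         none = NA_real_,
                         multiplicative = seq(0.2, 1, by = 0.025),
                         additive = seq(0.025, 0.5, by = 0.025))
  if (su$kind == "none" && !all(is.na(adjustment)))
    stop("set-up \"u,u\" takes no adjustment grid")
  if (length(d2) < 1L || any(d2 < 1)) stop("`d2` grid must be positive")
  if (any(hr_go <= 0) || any(hr_go >= 1))
    stop("`hr_go` grid must lie in (0, 1)")
  if (su$kind == "multiplicative" &&
      (any(adjustment <= 0) || any(adjustment > 1)))
    stop("lambda grid must lie in (0, 1]")
  if (su$kind == "additive" &&
      (any(adjustment <= 0) || any(adjustment > 0.5)))
    stop("alpha_CI grid must lie in (0, 0.5]")
  structure(list(set_up = set_up, kind = su$kind,
                 apply_to_decision = su$s1,
                 d2 = sort(unique(as.numeric(d2))),
                 hr_go = sort(unique(as.numeric(hr_go))),
                 adjustment = if (su$kind == "none") NA_real_
                              else sort(unique(as.numeric(adjustment)))),
            class = "optimization_grid")
}

#' @export
print.optimization_grid <- function(x, ...) {
  cat(sprintf("Optimization grid, set-up S(%s): %d x d2, %d x HR_go",
              x$set_up, length(x$d2), length(x$hr_go)))
  if (x$kind != "none")
    cat(sprintf(", %d x %s", length(x$adjustment),
                if (x$kind == "multiplicative") "lambda" else "alpha_CI"))
  cat(sprintf("  (%d designs)\n",
              length(x$d2) * length(x$hr_go) * length(x$adjustment)))
  invisible(x)
}

#' Evaluate every design on a grid
#'
#' Computes all characteristics, expected cost, gain and utility for each
#' feasible design of the grid in vectorized chunks, and flags infeasible
#' designs (those whose planning estimate can be nonpositive in the go
#' region) without evaluating them.
#'
#' @param grid An [optimization_grid()].
#' @param scenario A [scenario_spec()].
#' @param quad A [quadrature_spec()].
#' @param chunk_size Designs per vectorized chunk (memory/speed trade-off).
#' @return A data.frame with one row per design: `d2`, `hr_go`, `kappa`,
#'   `adj_param`, `feasible`, and for feasible rows `p_go`, `d3`, `e2`,
#'   `eps2`, `psp`, `p_cat1..3`, `cost`, `gain`, `utility`.
#' @export
evaluate_design_grid <- function(grid, scenario, quad = quadrature_spec(),
                                 chunk_size = 8000L) {
  stopifnot(inherits(grid, "optimization_grid"),
            inherits(scenario, "scenario_spec"))
  g <- expand.grid(d2 = grid$d2, hr_go = grid$hr_go,
                   adj_param = grid$adjustment, KEEP.OUT.ATTRS = FALSE)
  g$kappa <- -log(g$hr_go)
  # feasibility: planning estimate must stay positive over the go region
  zci <- if (grid$kind == "additive") stats::qnorm(1 - g$adj_param) else 0
  keff <- if (!grid$apply_to_decision || grid$kind == "none") g$kappa
          else if (grid$kind == "multiplicative") g$kappa / g$adj_param
          else g$kappa + zci * sqrt(4 / g$d2)
  a_min <- switch(grid$kind,
                  none = keff,
                  multiplicative = g$adj_param * keff,
                  additive = keff - zci * sqrt(4 / g$d2))
  g$feasible <- a_min > 0
  num_cols <- c("p_go", "d3", "e2", "eps2", "psp", "p_cat1", "p_cat2",
                "p_cat3", "cost", "gain", "utility")
  for (cl in num_cols) g[[cl]] <- NA_real_
  idx <- which(g$feasible)
  th <- scenario$benefits$hr_ci_thresholds[2:3]
  for (start in seq(1L, length(idx), by = chunk_size)) {
    ii <- idx[start:min(start + chunk_size - 1L, length(idx))]
    ch <- characteristics_engine(g$d2[ii], g$kappa[ii], grid$kind,
                                 g$adj_param[ii], grid$apply_to_decision,
                                 scenario$prior2, scenario$prior3,
                                 scenario$test, th, quad)
    uc <- utility_columns(ch, g$d2[ii], scenario)
    g$p_go[ii] <- ch$p_go; g$d3[ii] <- ch$d3; g$e2[ii] <- ch$e2
    g$eps2[ii] <- exp(-ch$e2); g$psp[ii] <- ch$psp
    g$p_cat1[ii] <- ch$p_cat1; g$p_cat2[ii] <- ch$p_cat2
    g$p_cat3[ii] <- ch$p_cat3
    g$cost[ii] <- uc$cost; g$gain[ii] <- uc$gain; g$utility[ii] <- uc$utility
  }
  g
}

# deterministic tie-breaking: max utility, then smallest d2, then largest
# hr_go, then parameter closest to "no adjustment" (lambda 1 / alpha_CI 0.5)
pick_optimum <- function(tab, kind) {
  stopifnot(nrow(tab) > 0L)
  best <- tab[tab$utility == max(tab$utility), , drop = FALSE]
  no_adj <- switch(kind, none = NA_real_, multiplicative = 1, additive = 0.5)
  o <- order(best$d2, -best$hr_go,
             if (kind == "none") rep(0, nrow(best))
             else abs(best$adj_param - no_adj))
  best[o[1L], , drop = FALSE]
}

build_result <- function(grid, scenario, quad, tab, budget = NULL,
                         elapsed = NA_real_) {
  feas <- tab[tab$feasible & is.finite(tab$utility), , drop = FALSE]
  within <- if (is.null(budget)) feas
            else feas[feas$cost <= budget, , drop = FALSE]
  if (nrow(within) == 0L && is.null(budget))
    stop("no feasible design on the grid; infeasible reasons: planning ",
         "estimate nonpositive in the go region for all designs")
  optimal <- if (nrow(within) > 0L) pick_optimum(within, grid$kind) else NULL
  binding <- NA
  if (!is.null(budget) && nrow(feas) > 0L) {
    unconstrained <- pick_optimum(feas, grid$kind)
    binding <- unconstrained$cost > budget
  }
  if (!is.null(optimal)) {
    optimal$d_total <- optimal$d2 + optimal$d3
    row.names(optimal) <- NULL
  }
  structure(list(
    set_up = grid$set_up, kind = grid$kind,
    optimal = optimal, grid = tab,
    n_designs = nrow(tab), n_feasible = nrow(feas),
    n_infeasible = sum(!tab$feasible),
    budget = budget, n_within_budget = if (is.null(budget)) NA_integer_
                                      else nrow(within),
    budget_binding = binding,
    quad = list(nodes_theta = quad$nodes_theta,
                nodes_estimate = quad$nodes_estimate,
                truncation = quad$truncation, scheme = quad$scheme),
    elapsed_s = elapsed),
    class = "optimization_result")
}

#' Grid optimization of the expected utility
#'
#' Exhaustively evaluates every feasible design of the grid and returns the
#' design maximizing expected utility, with deterministic tie-breaking
#' (smallest `d2`, then largest `hr_go`, then least discounting).  The full
#' evaluated grid is retained for reporting, and the run is bit-identical
#' on re-execution (no randomness).
#'
#' @param grid An [optimization_grid()].
#' @param scenario A [scenario_spec()].
#' @param quad A [quadrature_spec()].
#' @return An `optimization_result`: the optimal design and its
#'   characteristics, the evaluated grid, and a feasibility/settings log.
#' @examples
#' \donttest{
#' pr <- prior_spec(weights = c(0.3, 0.7), hr_means = c(0.69, 0.88),
#'                  n_events = c(210, 420))
#' sc <- scenario_spec(pr, benefits = benefit_spec(1000, 2000, 3000))
#' opt <- optimize_program(optimization_grid("u,u"), sc)
#' opt$optimal
#' }
#' @export
optimize_program <- function(grid, scenario, quad = quadrature_spec()) {
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(scenario$budget))
    return(optimize_with_budget(grid, scenario, scenario$budget, quad))
  tab <- evaluate_design_grid(grid, scenario, quad)
  build_result(grid, scenario, quad, tab,
               elapsed = proc.time()[["elapsed"]] - t0)
}

#' Grid optimization under a budget constraint
#'
#' As [optimize_program()], restricted to designs with expected cost at
#' most `K`.  Records whether the constraint is binding (the unconstrained
#' optimum exceeds the budget).  If no feasible design fits the budget the
#' result carries `optimal = NULL` and `n_within_budget = 0` rather than
#' failing.
#'
#' @inheritParams optimize_program
#' @param K Positive budget on expected cost ($10^5); `Inf` disables the
#'   constraint.
#' @return An `optimization_result`.
#' @export
optimize_with_budget <- function(grid, scenario, K,
                                 quad = quadrature_spec()) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0)
    stop("`K` must be a positive scalar")
  t0 <- proc.time()[["elapsed"]]
  scenario$budget <- NULL
  tab <- evaluate_design_grid(grid, scenario, quad)
  build_result(grid, scenario, quad, tab, budget = K,
               elapsed = proc.time()[["elapsed"]] - t0)
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Program optimization, set-up S(%s)\n", x$set_up))
  cat(sprintf("  %d designs evaluated (%d infeasible excluded)",
              x$n_designs, x$n_infeasible))
  if (is.finite(x$elapsed_s)) cat(sprintf(", %.1f s", x$elapsed_s))
  cat("\n")
  cat(sprintf("  quadrature: %s, %d estimate nodes, +-%g SD\n",
              x$quad$scheme, x$quad$nodes_estimate, x$quad$truncation))
  if (!is.null(x$budget)) {
    cat(sprintf("  budget K = %g: %d designs within, constraint %s\n",
                x$budget, x$n_within_budget,
                if (isTRUE(x$budget_binding)) "binding"
                else if (isFALSE(x$budget_binding)) "not binding"
                else "status unknown"))
    if (is.null(x$optimal)) {
      cat("  no design within budget\n")
      return(invisible(x))
    }
  }
  o <- x$optimal
  cat(sprintf("  optimal: d2 = %g, HR_go = %.2f", o$d2, o$hr_go))
  if (x$kind != "none")
    cat(sprintf(", %s = %.3f",
                if (x$kind == "multiplicative") "lambda" else "alpha_CI",
                o$adj_param))
  cat("\n")
  cat(sprintf(paste0("  u* = %.1f, d3 = %.0f, d = %.0f, p_go = %.2f, ",
                     "sP = %.2f, eps2 = %.2f\n"),
              o$utility, o$d3, o$d_total, o$p_go, o$psp, o$eps2))
  invisible(x)
}
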