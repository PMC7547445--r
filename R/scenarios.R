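#' Canonical oncology planning fixtures
#'
#' Named presets reproducing the reference oncology parameterization used
#' throughout the package examples: fixed costs 100/150, per-patient costs
#' 0.75/1 (all $10^5), event rates 0.7, seven benefit scenarios `bs1`-`bs7`
#' ranging from low to medium-large overall benefit, and a two-component
#' mixture prior placing weight `w` on a strong effect (HR 0.69, certainty
#' 210 events) and `1 - w` on a moderate one (HR 0.88, certainty 420
#' events).
#'
#' @name oncology_fixtures
#' @keywords internal
NULL

# benefit scenarios bs1..bs7, $1e5
.benefit_table <- list(
  bs1 = c(1000, 2000, 3000), bs2 = c(1000, 2000, 4000),
  bs3 = c(1000, 3000, 4000), bs4 = c(1000, 3000, 5000),
  bs5 = c(1000, 4000, 5000), bs6 = c(1000, 3000, 6000),
  bs7 = c(1000, 4000, 6000))

#' Default cost preset
#'
#' @return A [cost_spec()] with `c02 = 100`, `c03 = 150`, `c2 = 0.75`,
#'   `c3 = 1`, `xi2 = xi3 = 0.7`.
#' @export
default_costs <- function() cost_spec()

#' Benefit scenario presets bs1-bs7
#'
#' @param bs Scenario number 1-7 (or name `"bs1"`..`"bs7"`).
#' @return A [benefit_spec()] with the preset `(b1, b2, b3)`.
#' @export
benefit_scenario <- function(bs) {
  if (is.character(bs)) bs <- match(bs, names(.benefit_table))
  if (is.na(bs) || !bs %in% 1:7) stop("`bs` must be 1..7 or \"bs1\"..\"bs7\"")
  b <- .benefit_table[[bs]]
  benefit_spec(b[1], b[2], b[3])
}

#' Two-component oncology prior with weight w
#'
#' @param w Weight on the strong-effect component (HR 0.69, 210 events);
#'   `1 - w` goes to the moderate component (HR 0.88, 420 events).
#' @return A [prior_spec()].
#' @export
default_prior <- function(w) {
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1)
    stop("`w` must lie in [0, 1]")
  if (w == 0 || w == 1) {
    keep <- if (w == 1) 1L else 2L
    return(prior_spec(weights = 1, hr_means = c(0.69, 0.88)[keep],
                      n_events = c(210, 420)[keep]))
  }
  prior_spec(weights = c(w, 1 - w), hr_means = c(0.69, 0.88),
             n_events = c(210, 420))
}

#' Scenario preset by name
#'
#' Builds the full (scenario, grid, quadrature) triple for preset names of
#' the form `"bs<1-7>_w<03|06|09>_<set-up>"`, where set-up is one of
#' `unadjusted`, `mult_planning` (S(u,lambda)), `mult` (S(lambda,lambda)),
#' `add_planning` (S(u,alphaCI)), `add` (S(alphaCI,alphaCI)).
#'
#' @param name Preset name, e.g. `"bs1_w03_unadjusted"`.
#' @return List with elements `scenario`, `grid`, `quad`.
#' @examples
#' p <- scenario_preset("bs1_w03_unadjusted")
#' p$scenario
#' @export
scenario_preset <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) < 3L || !grepl("^bs[1-7]$", parts[1]) ||
      !grepl("^w0[369]$", parts[2]))
    stop("preset name must look like \"bs1_w03_unadjusted\"")
  bs <- as.integer(sub("bs", "", parts[1]))
  w <- as.integer(sub("w0", "", parts[2])) / 10
  su <- switch(paste(parts[-(1:2)], collapse = "_"),
               unadjusted = "u,u",
               mult_planning = "u,lambda",
               mult = "lambda,lambda",
               add_planning = "u,alphaCI",
               add = "alphaCI,alphaCI",
               stop("unknown set-up suffix in preset \"", name, "\""))
  list(scenario = scenario_spec(default_prior(w),
                                costs = default_costs(),
                                benefits = benefit_scenario(bs)),
       grid = optimization_grid(su),
       quad = quadrature_spec())
}

# ---- structured-text (YAML) scenario files ------------------------------

.scenario_keys <- list(
  top = c("prior", "prior3", "costs", "benefits", "test", "budget",
          "grid", "quadrature"),
  prior = c("weights", "hr_means", "log_means", "variances", "n_events"),
  costs = c("c02", "c03", "c2", "c3", "xi2", "xi3"),
  benefits = c("b", "hr_ci_thresholds"),
  test = c("alpha", "beta"),
  grid = c("set_up", "d2", "hr_go", "adjustment"),
  quadrature = c("nodes_theta", "nodes_estimate", "truncation", "scheme"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
}

prior_from_config <- function(p, where) {
  check_keys(p, .scenario_keys$prior, where)
  if (is.null(p$weights)) stop(where, ": `weights` is required")
  means <- NULL; hr_means <- NULL
  if (!is.null(p$log_means)) means <- p$log_means
  if (!is.null(p$hr_means)) hr_means <- p$hr_means
  prior_spec(weights = unlist(p$weights), means = means,
             hr_means = hr_means,
             variances = if (is.null(p$variances)) NULL
                         else unlist(p$variances),
             n_events = if (is.null(p$n_events)) NULL
                        else unlist(p$n_events))
}

seq_from_config <- function(x, name) {
  if (is.null(x)) return(NULL)
  if (is.list(x) && all(c("from", "to", "by") %in% names(x)))
    return(seq(x$from, x$to, by = x$by))
  if (is.numeric(unlist(x))) return(unlist(x))
  stop("grid entry `", name, "` must be a numeric vector or {from, to, by}")
}

#' Read a scenario configuration file
#'
#' Loads and validates a YAML scenario file into a [scenario_spec()], an
#' [optimization_grid()] and a [quadrature_spec()].  Unknown keys are
#' rejected with a message naming the offender; nothing is silently
#' defaulted except whole missing blocks (`costs`, `test`, `grid`,
#' `quadrature`), which take the documented package defaults.
#'
#' The schema (all monetary values in $10^5):
#' ```yaml
#' prior:      {weights: [...], hr_means: [...] | log_means: [...],
#'              n_events: [...] | variances: [...]}
#' prior3:     optional, same shape as prior
#' costs:      {c02, c03, c2, c3, xi2, xi3}
#' benefits:   {b: [b1, b2, b3], hr_ci_thresholds: [1, 0.95, 0.85]}
#' test:       {alpha, beta}
#' budget:     optional number
#' grid:       {set_up, d2: {from, to, by} | [...], hr_go: ..., adjustment: ...}
#' quadrature: {nodes_theta, nodes_estimate, truncation, scheme}
#' ```
#'
#' @param path Path to the YAML file.
#' @return List with elements `scenario`, `grid`, `quad`.
#' @seealso [write_scenario()] for the inverse.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, .scenario_keys$top, "scenario file")
  if (is.null(cfg$prior)) stop("scenario file: `prior` block is required")
  if (is.null(cfg$benefits))
    stop("scenario file: `benefits` block is required")
  prior2 <- prior_from_config(cfg$prior, "prior")
  prior3 <- if (is.null(cfg$prior3)) NULL
            else prior_from_config(cfg$prior3, "prior3")
  costs <- if (is.null(cfg$costs)) cost_spec() else {
    check_keys(cfg$costs, .scenario_keys$costs, "costs")
    do.call(cost_spec, cfg$costs)
  }
  check_keys(cfg$benefits, .scenario_keys$benefits, "benefits")
  if (is.null(cfg$benefits$b) || length(unlist(cfg$benefits$b)) != 3L)
    stop("benefits: `b` must give exactly (b1, b2, b3)")
  b <- unlist(cfg$benefits$b)
  benefits <- if (is.null(cfg$benefits$hr_ci_thresholds))
    benefit_spec(b[1], b[2], b[3])
  else benefit_spec(b[1], b[2], b[3],
                    unlist(cfg$benefits$hr_ci_thresholds))
  test <- if (is.null(cfg$test)) test_spec() else {
    check_keys(cfg$test, .scenario_keys$test, "test")
    do.call(test_spec, cfg$test)
  }
  grid <- if (is.null(cfg$grid)) optimization_grid() else {
    check_keys(cfg$grid, .scenario_keys$grid, "grid")
    optimization_grid(
      set_up = if (is.null(cfg$grid$set_up)) "u,u" else cfg$grid$set_up,
      d2 = seq_from_config(cfg$grid$d2, "d2") %||% seq(50, 350, by = 2),
      hr_go = seq_from_config(cfg$grid$hr_go, "hr_go") %||%
        seq(0.70, 0.90, by = 0.01),
      adjustment = seq_from_config(cfg$grid$adjustment, "adjustment"))
  }
  quad <- if (is.null(cfg$quadrature)) quadrature_spec() else {
    check_keys(cfg$quadrature, .scenario_keys$quadrature, "quadrature")
    do.call(quadrature_spec, cfg$quadrature)
  }
  list(scenario = scenario_spec(prior2, prior3, costs, benefits, test,
                                cfg$budget),
       grid = grid, quad = quad)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration file
#'
#' Serializes a (scenario, grid, quadrature) triple to YAML such that
#' [load_scenario()] reproduces it exactly.
#'
#' @param scenario A [scenario_spec()].
#' @param grid An [optimization_grid()].
#' @param quad A [quadrature_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, grid, quad, path) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(grid, "optimization_grid"),
            inherits(quad, "quadrature_spec"))
  prior_block <- function(p) list(weights = p$weights, log_means = p$means,
                                  variances = p$variances)
  cfg <- list(
    prior = prior_block(scenario$prior2),
    costs = scenario$costs[c("c02", "c03", "c2", "c3", "xi2", "xi3")],
    benefits = list(b = scenario$benefits$b,
                    hr_ci_thresholds = scenario$benefits$hr_ci_thresholds),
    test = list(alpha = scenario$test$alpha, beta = scenario$test$beta),
    grid = list(set_up = grid$set_up, d2 = grid$d2, hr_go = grid$hr_go,
                adjustment = grid$adjustment),
    quadrature = list(nodes_theta = quad$nodes_theta,
                      nodes_estimate = quad$nodes_estimate,
                      truncation = quad$truncation, scheme = quad$scheme))
  if (!same_prior(scenario$prior2, scenario$prior3))
    cfg$prior3 <- prior_block(scenario$prior3)
  if (!is.null(scenario$budget)) cfg$budget <- scenario$budget
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Render optimization results as a report table
#'
#' Formats one row per optimization result with the conventional column
#' order (`set_up`, `adj_param`, `HRgo`, `d2`, `eps2`, `d3`, `d`, `pgo`,
#' `sP`, `u`): hazard ratios and probabilities rounded to 2 decimals,
#' utilities and event numbers to integers, `d = d2 + round(d3)`.  All
#' monetary columns are in $10^5.  The unrounded values are attached as
#' attribute `"full"`, and an aligned text rendering as attribute
#' `"aligned"`.  Rendering is a pure function of its input.
#'
#' @param results A single `optimization_result` or a list of them.
#' @param file Optional path; when given the rounded table is also written
#'   as CSV.
#' @return The rounded `data.frame` (invisibly if `file` is given).
#' @export
render_results_table <- function(results, file = NULL) {
  if (inherits(results, "optimization_result")) results <- list(results)
  if (length(results) == 0L) stop("`results` must be nonempty")
  rows <- lapply(results, function(r) {
    if (is.null(r$optimal)) stop("result for set-up S(", r$set_up,
                                 ") has no design within budget")
    o <- r$optimal
    data.frame(set_up = r$set_up,
               adj_param = if (r$kind == "none") NA_real_ else o$adj_param,
               HRgo = o$hr_go, d2 = o$d2, eps2 = o$eps2, d3 = o$d3,
               d = o$d2 + round(o$d3), pgo = o$p_go, sP = o$psp,
               u = o$utility)
  })
  full <- do.call(rbind, rows)
  out <- full
  out$HRgo <- round(out$HRgo, 2)
  out$eps2 <- round(out$eps2, 2)
  out$pgo <- round(out$pgo, 2)
  out$sP <- round(out$sP, 2)
  out$adj_param <- round(out$adj_param, 3)
  out$d3 <- round(out$d3)
  out$u <- round(out$u)
  attr(out, "full") <- full
  attr(out, "aligned") <- paste(utils::capture.output(print(out,
                                                            row.names = FALSE)),
                                collapse = "\n")
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
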