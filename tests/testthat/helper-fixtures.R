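# shared fixtures: canonical oncology parameterization
prior_w03 <- default_prior(0.3)
prior_w06 <- default_prior(0.6)
prior_w09 <- default_prior(0.9)

scenario_bs1_w03 <- scenario_spec(prior_w03, benefits = benefit_scenario(1))

design_82 <- design_point(d2 = 82, hr_go = 0.80)

quad_default <- quadrature_spec()

# near-degenerate single-component prior for closed-form checks
point_prior <- function(theta0) {
  prior_spec(weights = 1, means = theta0, variances = 1e-10)
}

# a feasible design for each of the five program set-ups
design_panel <- list(
  design_point(d2 = 82, hr_go = 0.80),
  design_point(d2 = 150, hr_go = 0.85),
  design_point(d2 = 116, hr_go = 0.83,
               adj = adjustment_spec("multiplicative", 0.725)),
  design_point(d2 = 200, hr_go = 0.77,
               adj = adjustment_spec("multiplicative", 0.9)),
  design_point(d2 = 84, hr_go = 0.81,
               adj = adjustment_spec("multiplicative", 0.75),
               apply_to_decision = TRUE),
  design_point(d2 = 220, hr_go = 0.87,
               adj = adjustment_spec("multiplicative", 0.5),
               apply_to_decision = TRUE),
  design_point(d2 = 88, hr_go = 0.78,
               adj = adjustment_spec("additive", 0.45)),
  design_point(d2 = 250, hr_go = 0.75,
               adj = adjustment_spec("additive", 0.25)),
  design_point(d2 = 88, hr_go = 0.81,
               adj = adjustment_spec("additive", 0.425),
               apply_to_decision = TRUE),
  design_point(d2 = 160, hr_go = 0.84,
               adj = adjustment_spec("additive", 0.3),
               apply_to_decision = TRUE))
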