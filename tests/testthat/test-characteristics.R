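test_that("near-degenerate prior reproduces Gaussian closed forms", {
  # prior mass at the threshold: half the estimates clear it
  d <- design_point(d2 = 100, kappa = 0.3)
  expect_equal(prob_go(d, point_prior(0.3)), 0.5, tolerance = 1e-4)

  # off-center: one-line normal tail
  for (theta0 in c(0.2, 0.35, 0.5)) {
    expect_equal(prob_go(d, point_prior(theta0)),
                 pnorm((0.3 - theta0) / sqrt(4 / 100), lower.tail = FALSE),
                 tolerance = 1e-4)
  }

  # conditional mean of the estimate: truncated normal,
  # theta0 + sd * phi(0) / 0.5 for kappa = theta0, sd = 0.2
  est <- expected_conditional_estimate(d, point_prior(0.3))
  expect_equal(est$e2, 0.459577, tolerance = 1e-4)
  expect_equal(est$eps2, exp(-est$e2), tolerance = 1e-12)

  # no selection: kappa far below the prior mass removes the bias
  d_low <- design_point(d2 = 100, kappa = -5)
  est_low <- expected_conditional_estimate(d_low, point_prior(0.3))
  expect_equal(est_low$e2, 0.3, tolerance = 1e-6)
})

test_that("engine agrees with the independent 2-D quadrature oracle", {
  for (d in design_panel) {
    ora <- oracle_characteristics(d, prior_w03)
    ch <- program_characteristics(d, prior_w03)
    expect_equal(ch$p_go, ora$p_go, tolerance = 1e-6)
    expect_equal(ch$d3, ora$d3, tolerance = 1e-6)
    expect_equal(ch$e2, ora$e2, tolerance = 1e-6)
    expect_equal(ch$psp, ora$psp, tolerance = 1e-6)
    expect_equal(unname(ch$category_probs), ora$category_probs,
                 tolerance = 1e-5)
  }
})

test_that("lambda = 1 and alpha_CI = 0.5 reduce to the unadjusted design", {
  base <- program_characteristics(design_82, prior_w03)
  for (s1 in c(FALSE, TRUE)) {
    for (adj in list(adjustment_spec("multiplicative", 1),
                     adjustment_spec("additive", 0.5))) {
      d <- design_point(d2 = 82, hr_go = 0.80, adj = adj,
                        apply_to_decision = s1)
      ch <- program_characteristics(d, prior_w03)
      for (f in c("p_go", "d3", "e2", "psp"))
        expect_equal(ch[[f]], base[[f]], tolerance = 1e-10)
      expect_equal(ch$category_probs, base$category_probs,
                   tolerance = 1e-10)
    }
  }
})

test_that("probability orderings and monotonicity hold across designs", {
  kappas <- -log(seq(0.70, 0.90, by = 0.02))
  pgos <- vapply(kappas, function(k)
    prob_go(design_point(d2 = 82, kappa = k), prior_w03), 0)
  # larger kappa = stricter rule = lower go probability
  expect_true(all(diff(pgos[order(kappas)]) < 0))

  for (d in design_panel) {
    pgo <- prob_go(d, prior_w03)
    psp <- prob_success(d, prior_w03)
    expect_gte(pgo, psp)
    cats <- prob_benefit_categories(d, prior_w03)
    expect_true(all(cats >= 0))
    expect_equal(sum(cats), psp, tolerance = 1e-8)
  }
})

test_that("selection bias is positive for unadjusted designs with kappa > 0", {
  pm <- prior_mean(prior_w03)
  for (hr in c(0.70, 0.80, 0.90)) {
    for (d2 in c(50, 150, 350)) {
      ch <- program_characteristics(design_point(d2 = d2, hr_go = hr),
                                    prior_w03)
      expect_gt(ch$e2, pm)
      expect_gt(ch$bias, 0)
    }
  }
})

test_that("conditional phase III events dominate the plug-in value", {
  # Jensen: E[D3 | go] >= D3(E[planning estimate | go])
  for (d in design_panel) {
    ch <- program_characteristics(d, prior_w03)
    expect_gte(ch$d3 / ch$p_go, planned_events_phase3(ch$e2))
  }
})

test_that("quadrature is converged at the default settings", {
  q1 <- quadrature_spec(nodes_estimate = 64)
  q2 <- quadrature_spec(nodes_estimate = 128)
  for (d in design_panel[c(1, 5, 9)]) {
    a <- program_characteristics(d, prior_w03, quad = q1)
    b <- program_characteristics(d, prior_w03, quad = q2)
    for (f in c("p_go", "d3", "e2", "psp"))
      expect_equal(a[[f]], b[[f]], tolerance = 1e-4)
  }
})

test_that("benefit-category bounds sit at the documented cut points", {
  # fixed D3 = 400: upper bound of the small-effect interval on the
  # test-statistic scale is z_0.975 - log(0.95) * 10
  b <- phase23opt:::category_bounds(400, test_spec(), c(0.95, 0.85))
  expect_equal(b[1], 2.472897, tolerance = 1e-6)
  expect_equal(b[2], qnorm(0.975) - log(0.85) * 10, tolerance = 1e-12)
})

test_that("infeasible additive designs are refused with a clear error", {
  # planning on the CI lower bound that can be negative in the go region
  d_bad <- design_point(d2 = 88, hr_go = 0.90,
                        adj = adjustment_spec("additive", 0.25))
  expect_false(design_feasible(d_bad))
  expect_error(prob_go(d_bad, prior_w03), "infeasible")
  expect_error(expected_events_phase3(d_bad, prior_w03), "infeasible")
  # same parameter with the adjusted decision rule shifts the go region
  # away from zero and is feasible
  d_ok <- design_point(d2 = 88, hr_go = 0.90,
                       adj = adjustment_spec("additive", 0.25),
                       apply_to_decision = TRUE)
  expect_true(design_feasible(d_ok))
})

test_that("distinct phase II/III priors lower success for a weaker phase III", {
  # pessimistic phase III population: success probability must drop
  psp_same <- prob_success(design_82, prior_w03)
  psp_weak <- prob_success(design_82, prior_w03, prior3 = default_prior(0))
  psp_strong <- prob_success(design_82, prior_w03, prior3 = default_prior(1))
  expect_lt(psp_weak, psp_same)
  expect_gt(psp_strong, psp_same)
  expect_lte(psp_weak, prob_go(design_82, prior_w03))
})
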