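test_that("expected cost decomposes into its defining pieces", {
  # impossible go threshold: only the sunk phase II cost remains
  d_never <- design_point(d2 = 100, kappa = 10)
  expect_equal(expected_cost(d_never, scenario_bs1_w03),
               100 + 100 * 0.75 / 0.7, tolerance = 1e-6)
  expect_equal(expected_gain(d_never, scenario_bs1_w03), 0,
               tolerance = 1e-10)
  expect_equal(expected_utility(d_never, scenario_bs1_w03),
               -(100 + 100 * 0.75 / 0.7), tolerance = 1e-6)

  # composition identity against the characteristic building blocks
  pgo <- prob_go(design_82, prior_w03)
  d3 <- expected_events_phase3(design_82, prior_w03)
  expect_equal(expected_cost(design_82, scenario_bs1_w03),
               100 + 82 * 0.75 / 0.7 + 150 * pgo + d3 / 0.7,
               tolerance = 1e-10)

  # gain is the benefit-weighted category vector
  cats <- prob_benefit_categories(design_82, prior_w03)
  expect_equal(expected_gain(design_82, scenario_bs1_w03),
               sum(c(1000, 2000, 3000) * cats), tolerance = 1e-10)
  expect_equal(expected_utility(design_82, scenario_bs1_w03),
               expected_gain(design_82, scenario_bs1_w03) -
                 expected_cost(design_82, scenario_bs1_w03),
               tolerance = 1e-12)
})

test_that("cost and gain respond monotonically to their parameters", {
  sc_hi_c <- scenario_spec(prior_w03,
                           costs = cost_spec(c03 = 300, c3 = 2),
                           benefits = benefit_scenario(1))
  expect_gt(expected_cost(design_82, sc_hi_c),
            expected_cost(design_82, scenario_bs1_w03))
  sc_hi_b <- scenario_spec(prior_w03, benefits = benefit_scenario(7))
  expect_gt(expected_gain(design_82, sc_hi_b),
            expected_gain(design_82, scenario_bs1_w03))
})

test_that("grid evaluation matches single-design evaluation", {
  grid <- optimization_grid("lambda,lambda", d2 = c(82, 120),
                            hr_go = c(0.78, 0.82),
                            adjustment = c(0.7, 0.9))
  tab <- evaluate_design_grid(grid, scenario_bs1_w03)
  expect_equal(nrow(tab), 8L)
  i <- which(tab$d2 == 120 & tab$hr_go == 0.78 & tab$adj_param == 0.9)
  d <- design_point(d2 = 120, hr_go = 0.78,
                    adj = adjustment_spec("multiplicative", 0.9),
                    apply_to_decision = TRUE)
  expect_equal(tab$utility[i], expected_utility(d, scenario_bs1_w03),
               tolerance = 1e-12)
  expect_equal(tab$p_go[i], prob_go(d, prior_w03), tolerance = 1e-12)
})

test_that("optimizer returns the grid argmax, deterministically", {
  grid <- optimization_grid("u,u", d2 = seq(70, 100, by = 10),
                            hr_go = c(0.78, 0.80, 0.82))
  r1 <- optimize_program(grid, scenario_bs1_w03)
  r2 <- optimize_program(grid, scenario_bs1_w03)
  expect_identical(r1$optimal, r2$optimal)
  expect_identical(r1$grid$utility, r2$grid$utility)
  expect_equal(r1$optimal$utility, max(r1$grid$utility, na.rm = TRUE))
  expect_equal(r1$optimal$d_total, r1$optimal$d2 + r1$optimal$d3,
               tolerance = 1e-12)
  expect_equal(r1$n_designs, 12L)
  expect_equal(r1$n_infeasible, 0L)
})

test_that("adjusted set-ups dominate the unadjusted one on the same grid", {
  d2g <- seq(70, 120, by = 10)
  hrg <- seq(0.76, 0.84, by = 0.02)
  u_base <- optimize_program(optimization_grid("u,u", d2 = d2g,
                                               hr_go = hrg),
                             scenario_bs1_w03)$optimal$utility
  # the lambda grid contains 1, the alpha_CI grid contains 0.5, so each
  # adjusted set-up nests the unadjusted one as a slice
  u_mult <- optimize_program(
    optimization_grid("u,lambda", d2 = d2g, hr_go = hrg,
                      adjustment = seq(0.5, 1, by = 0.125)),
    scenario_bs1_w03)$optimal$utility
  u_add <- optimize_program(
    optimization_grid("u,alphaCI", d2 = d2g, hr_go = hrg,
                      adjustment = c(0.25, 0.375, 0.5)),
    scenario_bs1_w03)$optimal$utility
  expect_gte(u_mult, u_base)
  expect_gte(u_add, u_base)
})

test_that("infeasible additive designs are excluded and logged", {
  grid <- optimization_grid("u,alphaCI", d2 = c(60, 88),
                            hr_go = c(0.80, 0.90),
                            adjustment = c(0.1, 0.45))
  tab <- evaluate_design_grid(grid, scenario_bs1_w03)
  expect_true(any(!tab$feasible))
  expect_true(all(is.na(tab$utility[!tab$feasible])))
  r <- optimize_program(grid, scenario_bs1_w03)
  expect_equal(r$n_infeasible, sum(!tab$feasible))
  expect_true(r$optimal$feasible)
})

test_that("budget constraint restricts, binds and degrades gracefully", {
  grid <- optimization_grid("u,u", d2 = seq(70, 110, by = 10),
                            hr_go = c(0.78, 0.80, 0.82))
  free <- optimize_program(grid, scenario_bs1_w03)
  # infinite budget: identical optimum
  r_inf <- optimize_with_budget(grid, scenario_bs1_w03, Inf)
  expect_equal(r_inf$optimal$utility, free$optimal$utility)
  expect_false(r_inf$budget_binding)

  # binding budget: the returned design respects it
  K <- free$optimal$cost - 10
  r_k <- optimize_with_budget(grid, scenario_bs1_w03, K)
  expect_true(r_k$budget_binding)
  expect_lte(r_k$optimal$cost, K)
  expect_lte(r_k$optimal$utility, free$optimal$utility)
  expect_equal(r_k$optimal$cost,
               expected_cost(design_point(d2 = r_k$optimal$d2,
                                          hr_go = r_k$optimal$hr_go),
                             scenario_bs1_w03), tolerance = 1e-10)

  # budget below the sunk phase II cost: nothing fits
  r_none <- optimize_with_budget(grid, scenario_bs1_w03, 100)
  expect_null(r_none$optimal)
  expect_equal(r_none$n_within_budget, 0L)
  expect_output(print(r_none), "no design within budget")

  # a scenario carrying a budget routes through the constrained path
  sc_b <- scenario_spec(prior_w03, benefits = benefit_scenario(1),
                        budget = K)
  expect_equal(optimize_program(grid, sc_b)$optimal$utility,
               r_k$optimal$utility)
})
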