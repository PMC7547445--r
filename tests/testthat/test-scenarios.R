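test_that("fixture presets carry the canonical parameter values", {
  cs <- default_costs()
  expect_equal(cs[c("c02", "c03", "c2", "c3", "xi2", "xi3")],
               list(c02 = 100, c03 = 150, c2 = 0.75, c3 = 1,
                    xi2 = 0.7, xi3 = 0.7))

  expected_b <- list(c(1000, 2000, 3000), c(1000, 2000, 4000),
                     c(1000, 3000, 4000), c(1000, 3000, 5000),
                     c(1000, 4000, 5000), c(1000, 3000, 6000),
                     c(1000, 4000, 6000))
  for (i in 1:7) {
    bs <- benefit_scenario(i)
    expect_equal(bs$b, expected_b[[i]])
    expect_equal(bs$hr_ci_thresholds, c(1, 0.95, 0.85))
  }
  expect_equal(benefit_scenario("bs4")$b, c(1000, 3000, 5000))

  pr <- default_prior(0.3)
  expect_equal(pr$weights, c(0.3, 0.7))
  expect_equal(pr$means, c(-log(0.69), -log(0.88)))
  expect_equal(pr$variances, c(4 / 210, 4 / 420))

  g <- optimization_grid("lambda,lambda")
  expect_equal(g$d2, seq(50, 350, by = 2))
  expect_equal(g$hr_go, seq(0.70, 0.90, by = 0.01))
  expect_equal(g$adjustment, seq(0.2, 1, by = 0.025))
  expect_equal(optimization_grid("u,alphaCI")$adjustment,
               seq(0.025, 0.5, by = 0.025))
})

test_that("named presets expand to the full scenario triple", {
  p <- scenario_preset("bs1_w03_unadjusted")
  expect_s3_class(p$scenario, "scenario_spec")
  expect_equal(p$scenario$benefits$b, c(1000, 2000, 3000))
  expect_equal(p$scenario$prior2$weights, c(0.3, 0.7))
  expect_equal(p$grid$set_up, "u,u")
  expect_equal(p$scenario$costs$c02, 100)

  expect_equal(scenario_preset("bs4_w06_mult_planning")$grid$set_up,
               "u,lambda")
  expect_equal(scenario_preset("bs7_w09_add")$grid$set_up,
               "alphaCI,alphaCI")
  expect_error(scenario_preset("bs8_w03_unadjusted"), "preset")
  expect_error(scenario_preset("bs1_w03_bogus"), "set-up")
})

test_that("scenario files round-trip exactly and reject bad input", {
  p <- scenario_preset("bs3_w06_mult")
  p$scenario$budget <- 700
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(p$scenario, p$grid, p$quad, path)
  q <- load_scenario(path)
  expect_equal(q$scenario$prior2$weights, p$scenario$prior2$weights)
  expect_equal(q$scenario$prior2$means, p$scenario$prior2$means)
  expect_equal(q$scenario$prior2$variances, p$scenario$prior2$variances)
  expect_equal(q$scenario$costs, p$scenario$costs)
  expect_equal(q$scenario$benefits, p$scenario$benefits)
  expect_equal(q$scenario$test$alpha, p$scenario$test$alpha)
  expect_equal(q$scenario$budget, 700)
  expect_equal(q$grid$set_up, p$grid$set_up)
  expect_equal(q$grid$d2, p$grid$d2)
  expect_equal(q$grid$adjustment, p$grid$adjustment)
  expect_equal(q$quad$nodes_estimate, p$quad$nodes_estimate)

  # schema violations are named, not defaulted
  writeLines(c("prior:", "  weights: [1]", "  hr_means: [0.8]",
               "  n_events: [200]", "benefits:",
               "  b: [1000, 2000, 3000]", "typo_key: 1"), path)
  expect_error(load_scenario(path), "typo_key")

  writeLines(c("prior:", "  weights: [0.4, 0.5]",
               "  hr_means: [0.69, 0.88]", "  n_events: [210, 420]",
               "benefits:", "  b: [1000, 2000, 3000]"), path)
  expect_error(load_scenario(path), "sum to 1")

  writeLines(c("prior:", "  weights: [1]", "  hr_means: [0.8]",
               "  n_events: [200]"), path)
  expect_error(load_scenario(path), "benefits")
})

test_that("results tables follow the reporting conventions", {
  grid <- optimization_grid("u,u", d2 = c(80, 82, 84),
                            hr_go = c(0.79, 0.80, 0.81))
  r <- optimize_program(grid, scenario_bs1_w03)
  tab <- render_results_table(r)
  expect_equal(tab$d, tab$d2 + round(attr(tab, "full")$d3))
  expect_equal(tab$pgo, round(attr(tab, "full")$pgo, 2))
  expect_equal(tab$sP, round(attr(tab, "full")$sP, 2))
  expect_equal(tab$u, round(attr(tab, "full")$u))
  expect_true(is.na(tab$adj_param))
  expect_identical(render_results_table(r), tab)  # pure function

  # two rows, CSV output
  grid2 <- optimization_grid("u,lambda", d2 = c(80, 84),
                             hr_go = c(0.79, 0.81),
                             adjustment = c(0.75, 1))
  r2 <- optimize_program(grid2, scenario_bs1_w03)
  path <- withr::local_tempfile(fileext = ".csv")
  tab2 <- render_results_table(list(r, r2), file = path)
  expect_equal(nrow(tab2), 2L)
  back <- read.csv(path)
  expect_equal(back$u, tab2$u)
  expect_equal(back$set_up, c("u,u", "u,lambda"))
})
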