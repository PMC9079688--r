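test_that("degenerate distributions collapse the Monte Carlo onto the closed form", {
  inp <- tiny_inputs()
  res <- run_two_stage(inp, degenerate_mc(), point_crf(), keep_draws = TRUE)
  oracle <- tiny_oracle()
  nat <- res$national
  # zero UI width everywhere
  expect_equal(nat$ui_low, nat$mean, tolerance = 1e-12)
  expect_equal(nat$ui_high, nat$mean, tolerance = 1e-12)
  # means equal the hand-computed closed form
  for (l in names(oracle$an)) {
    expect_equal(national_value(res, "attributable_cases", l), oracle$an[[l]],
                 tolerance = 1e-9)
    expect_equal(national_value(res, "attributable_cost", l),
                 oracle$an_cost[[l]], tolerance = 1e-9)
  }
  for (s in names(oracle$ran)) {
    expect_equal(national_value(res, "reduction_cases", s), oracle$ran[[s]],
                 tolerance = 1e-9)
    expect_equal(national_value(res, "reduction_cost", s), oracle$ran_cost[[s]],
                 tolerance = 1e-9)
  }
})

test_that("deterministic pipeline reproduces the closed-form oracle", {
  det <- run_deterministic(tiny_inputs())
  oracle <- tiny_oracle()
  val <- function(kind, label) det$value[det$kind == kind & det$label == label]
  expect_equal(val("attributable_cases", "total"), oracle$an$total,
               tolerance = 1e-12)
  expect_equal(val("attributable_cases", "cooking"), oracle$an$cooking,
               tolerance = 1e-12)
  expect_equal(val("reduction_cases", "AQG"), oracle$ran$AQG, tolerance = 1e-12)
  expect_equal(val("reduction_cost", "EC"), oracle$ran_cost$EC, tolerance = 1e-12)
})

test_that("interval summaries recover analytic normal quantiles", {
  set.seed(601)
  x <- rnorm(1000)
  q <- no2burden:::ui_quantiles(x)
  expect_lt(abs(q[1] - (-1.96)), 0.15)
  expect_lt(abs(q[2] - 1.96), 0.15)
})

test_that("identical inputs and seed reproduce the result bit-for-bit", {
  inp <- generate_inputs(small_config())
  mc <- mc_config(n_variability = 60, n_uncertainty = 40, seed = 77)
  r1 <- run_two_stage(inp, mc, by_city = TRUE)
  r2 <- run_two_stage(inp, mc, by_city = TRUE)
  expect_identical(r1$national, r2$national)
  expect_identical(r1$by_city, r2$by_city)
  r3 <- run_two_stage(inp, mc_config(n_variability = 60, n_uncertainty = 40,
                                     seed = 78))
  expect_false(identical(r1$national, r3$national))
})

test_that("case reductions are monotone across tightening outdoor targets", {
  inp <- generate_inputs(small_config())
  res <- run_two_stage(inp, mc_config(n_variability = 40, n_uncertainty = 30,
                                      seed = 21), keep_draws = TRUE)
  draws <- res$draws$ran
  tol <- 1e-9
  # per uncertainty draw, thanks to common random numbers
  expect_true(all(draws$IT1 <= draws$IT2 + tol))
  expect_true(all(draws$IT2 <= draws$IT3 + tol))
  expect_true(all(draws$IT3 <= draws$AQG + tol))
  # and in the mean
  m <- sapply(c("IT1", "IT2", "IT3", "AQG"),
              function(s) national_value(res, "reduction_cases", s))
  expect_true(all(diff(m) >= -tol))
})

test_that("uncertainty intervals bracket the mean in every emitted row", {
  inp <- generate_inputs(small_config())
  res <- run_two_stage(inp, mc_config(n_variability = 40, n_uncertainty = 50,
                                      seed = 31), by_city = TRUE)
  expect_true(all(res$national$ui_low <= res$national$mean + 1e-12))
  expect_true(all(res$national$mean <= res$national$ui_high + 1e-12))
  expect_true(all(res$by_city$ui_low <= res$by_city$mean + 1e-12))
})

test_that("point estimates are stable to halving the variability draws", {
  inp <- generate_inputs(small_config())
  full <- run_two_stage(inp, mc_config(n_variability = 500, n_uncertainty = 60,
                                       seed = 41), scenarios = character(0))
  half <- run_two_stage(inp, mc_config(n_variability = 250, n_uncertainty = 60,
                                       seed = 41), scenarios = character(0))
  a <- national_value(full, "attributable_cases", "total")
  b <- national_value(half, "attributable_cases", "total")
  expect_lt(abs(a - b) / a, 0.01)
})

test_that("robustness error is zero under degenerate distributions", {
  inp <- tiny_inputs()
  mc <- degenerate_mc()
  mc$n_robustness <- 10L
  rb <- robustness_check(inp, mc, point_crf())
  expect_equal(rb$max_rel_error, 0)
})

test_that("repeat-to-repeat spread shrinks as uncertainty draws increase", {
  inp <- generate_inputs(small_config(n_cities = 5L))
  base <- mc_config(n_variability = 60, n_uncertainty = 40,
                    n_robustness = 15, seed = 51)
  more <- mc_config(n_variability = 60, n_uncertainty = 400,
                    n_robustness = 15, seed = 51)
  rb_small <- robustness_check(inp, base)
  rb_large <- robustness_check(inp, more)
  expect_lt(rb_large$sd_rel_error, rb_small$sd_rel_error)
})

test_that("truncated-normal variability is an accepted alternative family", {
  inp <- generate_inputs(small_config())
  mc <- mc_config(n_variability = 50, n_uncertainty = 30, seed = 61,
                  variability_family = "truncnorm")
  res <- run_two_stage(inp, mc, scenarios = character(0))
  expect_true(all(is.finite(res$national$mean)))
  expect_gt(national_value(res, "attributable_cases", "total"), 0)
})
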