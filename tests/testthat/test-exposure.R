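test_that("second-hand-smoke concentration is the indoor/cooking difference, clamped at zero", {
  expect_equal(derive_shs(15, 10), 5)
  expect_equal(derive_shs(10, 10), 0)
  expect_warning(res <- derive_shs(9, 10), "clamping")
  expect_equal(res, 0)
  expect_error(derive_shs(-1, 5), "validation error")
  expect_error(derive_shs(5, NA), "validation error")
})

test_that("total exposure sums the household-appropriate sources", {
  expect_equal(total_exposure(10, 30, household = "non-smoking"), 40)
  expect_equal(total_exposure(10, 30, shs = 5, household = "smoking"), 45)
  expect_equal(total_exposure(10, 30, shs = 5, household = "non-smoking"), 40)
  expect_equal(total_exposure(0, 0, shs = 0, household = "smoking"), 0)
})

test_that("source proportions follow the shared-denominator formulas", {
  expect_equal(unlist(source_proportions(0, 30, 20, 0)),
               c(ps_ambient = 1, ps_cooking = 0, ps_shs = 0))
  # denominator 10 + 30 + 0.5 * 20 = 50
  ps <- source_proportions(10, 30, 20, 0.5)
  expect_equal(unlist(ps), c(ps_ambient = 0.6, ps_cooking = 0.2, ps_shs = 0.2))
  expect_error(source_proportions(0, 0, 5, 0), "degenerate-input")
})

test_that("source proportions normalize and are scale invariant", {
  set.seed(301)
  for (i in 1:20) {
    v <- runif(3, 0, 50)
    p <- runif(1)
    ps <- source_proportions(v[1], v[2], v[3], p)
    expect_equal(sum(unlist(ps)), 1, tolerance = 1e-12)
    ps2 <- source_proportions(7.3 * v[1], 7.3 * v[2], 7.3 * v[3], p)
    expect_equal(unlist(ps), unlist(ps2), tolerance = 1e-12)
  }
})

stratum_row <- function(cooking = 10, ambient = 30, f_exp = 0.7, p_shs = 0.4) {
  data.frame(province = "PA", cooking_mean = cooking, cooking_sd = 0.4 * cooking,
             ambient_mean = ambient, ambient_sd = 0.4 * ambient,
             f_exp = f_exp, p_shs = p_shs, stringsAsFactors = FALSE)
}

test_that("scenario transformations follow their stated rules", {
  g <- stratum_row()
  ec <- apply_scenario(g, "EC")
  expect_equal(ec$cooking_mean, 0)
  expect_equal(ec$ambient_mean, 30)

  # IT3 (target 20): outdoor 14 / 0.7 = 20 <= 20, unchanged
  it3 <- apply_scenario(stratum_row(ambient = 14), "IT3")
  expect_equal(it3$ambient_mean, 14)

  # AQG (target 10): outdoor 35 / 0.7 = 50 > 10 -> 10 * 0.7
  aqg <- apply_scenario(stratum_row(ambient = 35), "AQG")
  expect_equal(aqg$ambient_mean, 7.0)
  expect_equal(aqg$ambient_sd, 0.4 * 35 * (7 / 35))  # constant CV

  sb <- apply_scenario(g, "SB")
  expect_equal(sb$cooking_mean, g$cooking_mean)
  expect_equal(sb$ambient_mean, g$ambient_mean)
  expect_equal(sb$p_shs, 0)

  base <- apply_scenario(g, "BASELINE2019")
  expect_equal(base$ambient_mean, g$ambient_mean)
})

test_that("f_exp is looked up from context and missing provinces error", {
  g <- stratum_row()
  g$f_exp <- NULL
  g$p_shs <- NULL
  ctx <- list(province = data.frame(province = "PA", f_exp = 0.7, p_shs = 0.4))
  out <- apply_scenario(g, "AQG", ctx)
  expect_equal(out$f_exp, 0.7)
  g$province <- "PZ"
  expect_error(apply_scenario(g, "AQG", ctx), "PZ")
})

test_that("ambient exposure is monotone across tightening outdoor targets", {
  set.seed(302)
  for (i in 1:15) {
    g <- stratum_row(cooking = runif(1, 0, 20), ambient = runif(1, 5, 60),
                     f_exp = runif(1, 0.55, 0.95))
    amb <- sapply(c("IT1", "IT2", "IT3", "AQG"),
                  function(s) apply_scenario(g, s)$ambient_mean)
    expect_true(all(diff(amb) <= 1e-12))
    expect_lte(amb[["IT1"]], g$ambient_mean)
  }
})

test_that("scenario application is idempotent", {
  g <- stratum_row(ambient = 45)
  for (s in c("SB", "EC", "IT2", "AQG", "BASELINE2019")) {
    once <- apply_scenario(g, s)
    twice <- apply_scenario(once, s)
    expect_equal(twice, once)
  }
})

test_that("scenario table stacks one block per scenario", {
  g <- stratum_row()
  tab <- scenario_exposure_table(g, c("BASELINE2019", "EC", "AQG"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$scenario, c("BASELINE2019", "EC", "AQG"))
})
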