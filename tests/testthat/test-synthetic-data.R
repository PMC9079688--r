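test_that("same configuration and seed give byte-identical tables", {
  cfg <- small_config()
  expect_identical(generate_exposure_table(cfg), generate_exposure_table(cfg))
  expect_identical(generate_population_incidence(cfg),
                   generate_population_incidence(cfg))
  expect_identical(generate_context_tables(cfg), generate_context_tables(cfg))
  cfg2 <- small_config(seed = 4343L)
  expect_false(identical(generate_exposure_table(cfg),
                         generate_exposure_table(cfg2)))
})

test_that("zero cooking share target zeroes all cooking means", {
  cfg <- small_config(cooking_share_target = 0)
  ex <- generate_exposure_table(cfg)
  expect_true(all(ex$cooking_mean == 0))
  expect_true(all(ex$cooking_sd == 0))
})

test_that("default generator hits the cooking share target at full scale", {
  ex <- generate_exposure_table(synthetic_config())
  expect_equal(nrow(ex), 330 * 6 * 2 * 2)
  share <- mean(ex$cooking_mean / (ex$cooking_mean + ex$ambient_mean))
  expect_lt(abs(share - 0.25), 0.05)
})

test_that("smoking-household indoor mean strictly exceeds the cooking mean", {
  ex <- generate_exposure_table(small_config())
  sm <- ex[ex$household == "smoking", ]
  expect_true(all(sm$indoor_smoking_mean > sm$cooking_mean))
  expect_true(all(is.na(ex$indoor_smoking_mean[ex$household == "non-smoking"])))
})

test_that("per-city indoor share increases with the latitude covariate", {
  ex <- generate_exposure_table(synthetic_config(n_cities = 100L))
  per_city <- aggregate(cbind(cooking_mean, ambient_mean) ~ city + latitude,
                        data = ex, FUN = mean)
  per_city$share <- per_city$cooking_mean /
    (per_city$cooking_mean + per_city$ambient_mean)
  slope <- coef(lm(share ~ latitude, data = per_city))[["latitude"]]
  expect_gt(slope, 0)
})

test_that("population totals are conserved and incidence echoes the config", {
  cfg <- small_config()  # population_total = 1e6
  pop <- generate_population_incidence(cfg)
  expect_lte(abs(sum(pop$N) - 1e6), nrow(pop))
  # no province modifiers: rates echo the configured table exactly
  ir_tab <- cfg$incidence_by_age_sex
  expected <- ir_tab$rate[match(paste(pop$age_group, pop$sex),
                                paste(ir_tab$age_group, ir_tab$sex))]
  expect_identical(pop$IR, expected)
  # incidence decreases with age within sex and boys >= girls
  for (s in c("boy", "girl")) {
    r <- sapply(c("0-0.5", "0.5-1", "1-2", "3-6", "7-11", "12-17"),
                function(a) pop$IR[pop$age_group == a & pop$sex == s][1])
    expect_true(all(diff(r) <= 0))
  }
})

test_that("province incidence modifiers scale rates by their ratio", {
  cities <- sprintf("C%03d", 1:4)
  provs <- list(A = cities[1:2], B = cities[3:4])
  cfg <- synthetic_config(n_cities = 4L, city_labels = cities,
                          provinces = provs, population_total = 1e5,
                          province_ir_modifiers = c(A = 1.2, B = 0.8),
                          seed = 99L)
  pop <- generate_population_incidence(cfg)
  a <- pop[pop$province == "A", ]
  b <- pop[pop$province == "B", ]
  key <- function(d) paste(d$age_group, d$sex)
  ratio <- a$IR[match(unique(key(a)), key(a))] /
    b$IR[match(unique(key(a)), key(b))]
  expect_equal(ratio, rep(1.5, length(ratio)))
})

test_that("context tables honour their configured ranges", {
  cfg <- small_config()
  ctx <- generate_context_tables(cfg)
  expect_true(all(ctx$province$f_exp >= cfg$fexp_range[1] &
                  ctx$province$f_exp <= cfg$fexp_range[2]))
  expect_true(all(ctx$province$p_shs >= cfg$pshs_range[1] &
                  ctx$province$p_shs <= cfg$pshs_range[2]))
  expect_true(all(ctx$cost$cost_direct > 0))
  expect_true(all(ctx$cost$treatment_days > 0))
  expect_true(all(ctx$gdp$gdp_daily > 0))

  degen <- small_config(fexp_range = c(0.7, 0.7))
  expect_true(all(generate_context_tables(degen)$province$f_exp == 0.7))
})

test_that("zero second-hand-smoke proportion removes the SHS contribution", {
  cfg <- small_config(pshs_range = c(0, 0))
  inp <- generate_inputs(cfg)
  res <- run_deterministic(build_groups(inp), scenarios = "SB")
  expect_equal(res$value[res$kind == "attributable_cases" & res$label == "SHS"], 0)
  expect_equal(res$value[res$kind == "reduction_cases" & res$label == "SB"], 0)
})

test_that("invalid configurations are rejected with configuration errors", {
  expect_error(synthetic_config(ambient_mean_range = c(-1, 10)),
               "configuration error")
  expect_error(synthetic_config(fexp_range = c(0, 0.5)), "configuration error")
  expect_error(synthetic_config(pshs_range = c(0.2, 1.4)), "configuration error")
  expect_error(synthetic_config(population_total = -5), "configuration error")
  expect_error(synthetic_config(n_cities = 2, city_labels = c("A", "A")),
               "duplicate city labels")
  bad_ir <- default_ir <- synthetic_config(n_cities = 2)$incidence_by_age_sex
  bad_ir$rate[bad_ir$age_group == "12-17" & bad_ir$sex == "boy"] <- 0.5
  expect_error(synthetic_config(incidence_by_age_sex = bad_ir),
               "decrease with age")
})

test_that("emitted tables round-trip through the bundle readers unchanged", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  paths <- simulate_inputs(cfg, dir)
  expect_true(all(file.exists(paths)))
  inp <- read_input_bundle(dir)
  expect_silent(validate_inputs(inp))
  direct <- generate_inputs(cfg)
  expect_equal(inp$exposure$cooking_mean, direct$exposure$cooking_mean)
  expect_equal(inp$population$N, direct$population$N)
  expect_equal(inp$province, direct$province)
})
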