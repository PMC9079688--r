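#' Read an input CSV bundle from a directory
#'
#' Expects the four files written by [simulate_inputs()] (or real data in
#' the same dictionary): `exposure.csv`, `population_incidence.csv`,
#' `context_province.csv`, `context_cost.csv`.
#'
#' @param dir directory containing the bundle.
#' @return list with `exposure`, `population`, `province`, `cost`, `gdp`.
#' @export
read_input_bundle <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("missing input file: %s", p), call. = FALSE)
    p
  }
  exposure <- read.csv(path("exposure.csv"), stringsAsFactors = FALSE)
  population <- read.csv(path("population_incidence.csv"), stringsAsFactors = FALSE)
  province <- read.csv(path("context_province.csv"), stringsAsFactors = FALSE)
  cost <- read.csv(path("context_cost.csv"), stringsAsFactors = FALSE)
  gdp <- NULL
  if ("gdp_daily" %in% names(population)) {
    gdp <- unique(population[, c("city", "gdp_daily")])
  }
  list(exposure = exposure, population = population, province = province,
       cost = cost, gdp = gdp)
}

required_columns <- list(
  exposure = c("city", "province", "age_group", "sex", "household",
               "cooking_mean", "cooking_sd", "ambient_mean", "ambient_sd",
               "indoor_smoking_mean", "indoor_smoking_sd"),
  population = c("city", "province", "age_group", "sex", "N", "IR"),
  province = c("province", "f_exp", "p_shs"),
  cost = c("age_group", "sex", "cost_direct", "treatment_days")
)

#' Validate an input bundle
#'
#' Checks schema completeness and referential integrity, and raises a single
#' error itemizing every problem found (missing columns, provinces absent
#' from the context table, strata without both household types, missing
#' population or cost rows, out-of-range values).
#'
#' @param inputs list as returned by [read_input_bundle()] or
#'   [generate_inputs()].
#' @return the inputs, invisibly, if valid.
#' @export
validate_inputs <- function(inputs) {
  issues <- character()
  note <- function(...) issues <<- c(issues, sprintf(...))
  for (tab in names(required_columns)) {
    if (is.null(inputs[[tab]])) {
      note("missing table: %s", tab)
      next
    }
    miss <- setdiff(required_columns[[tab]], names(inputs[[tab]]))
    if (length(miss))
      note("table '%s' lacks column(s): %s", tab, paste(miss, collapse = ", "))
  }
  if (!length(issues)) {
    ex <- inputs$exposure
    key <- paste(ex$city, ex$age_group, ex$sex)
    ns <- key[ex$household == "non-smoking"]
    sm <- key[ex$household == "smoking"]
    if (anyDuplicated(ns) || anyDuplicated(sm))
      note("duplicate exposure rows for stratum/household combinations")
    odd <- union(setdiff(ns, sm), setdiff(sm, ns))
    if (length(odd))
      note("strata missing one household type: %s",
           paste(utils::head(odd, 5), collapse = "; "))
    missing_prov <- setdiff(unique(ex$province), inputs$province$province)
    if (length(missing_prov))
      note("provinces absent from context_province: %s",
           paste(missing_prov, collapse = ", "))
    pop_key <- paste(inputs$population$city, inputs$population$age_group,
                     inputs$population$sex)
    no_pop <- setdiff(unique(key), pop_key)
    if (length(no_pop))
      note("strata without population/incidence rows: %s",
           paste(utils::head(no_pop, 5), collapse = "; "))
    cost_key <- paste(inputs$cost$age_group, inputs$cost$sex)
    no_cost <- setdiff(unique(paste(ex$age_group, ex$sex)), cost_key)
    if (length(no_cost))
      note("age/sex groups without cost parameters: %s",
           paste(no_cost, collapse = "; "))
    gdp <- inputs$gdp
    if (is.null(gdp) && !"gdp_daily" %in% names(inputs$population))
      note("no city GDP available (need inputs$gdp or a gdp_daily column)")
    if (any(inputs$province$f_exp <= 0 | inputs$province$f_exp > 1))
      note("f_exp values outside (0, 1]")
    if (any(inputs$province$p_shs < 0 | inputs$province$p_shs > 1))
      note("p_shs values outside [0, 1]")
    if (any(inputs$population$N < 0)) note("negative population sizes")
    if (any(inputs$population$IR <= 0 | inputs$population$IR >= 1))
      note("incidence rates outside (0, 1)")
  }
  if (length(issues)) {
    stop(paste0("input validation failed:\n  - ",
                paste(issues, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(inputs)
}

#' Assemble the per-group analysis table
#'
#' Joins the exposure, population, context and cost tables into one row per
#' population group (city x age group x sex), with both household types'
#' concentration parameters side by side and the second-hand-smoke
#' concentration derived by subtraction. The SHS standard deviation inherits
#' the coefficient of variation of the smoking-household indoor
#' concentration.
#'
#' @param inputs validated input bundle.
#' @return data frame of class `burden_groups`.
#' @export
build_groups <- function(inputs) {
  validate_inputs(inputs)
  ex <- inputs$exposure
  key <- function(d) paste(d$city, d$age_group, d$sex, sep = "\r")
  ns <- ex[ex$household == "non-smoking", ]
  sm <- ex[ex$household == "smoking", ]
  ns <- ns[order(ns$city, ns$age_group, ns$sex), ]
  i <- match(key(ns), key(sm))
  shs_mean <- derive_shs(sm$indoor_smoking_mean[i], sm$cooking_mean[i])
  rel_sd <- ifelse(sm$indoor_smoking_mean[i] > 0,
                   sm$indoor_smoking_sd[i] / sm$indoor_smoking_mean[i], 0)
  g <- data.frame(
    city = ns$city, province = ns$province,
    age_group = ns$age_group, sex = ns$sex,
    cook_ns_mean = ns$cooking_mean, cook_ns_sd = ns$cooking_sd,
    amb_ns_mean = ns$ambient_mean, amb_ns_sd = ns$ambient_sd,
    cook_s_mean = sm$cooking_mean[i], cook_s_sd = sm$cooking_sd[i],
    amb_s_mean = sm$ambient_mean[i], amb_s_sd = sm$ambient_sd[i],
    shs_mean = shs_mean, shs_sd = shs_mean * rel_sd,
    stringsAsFactors = FALSE
  )
  pop <- inputs$population
  pi <- match(key(g), key(pop))
  g$N <- pop$N[pi]
  g$IR <- pop$IR[pi]
  pr <- inputs$province
  vi <- match(g$province, pr$province)
  g$f_exp <- pr$f_exp[vi]
  g$p_shs <- pr$p_shs[vi]
  co <- inputs$cost
  ci <- match(paste(g$age_group, g$sex), paste(co$age_group, co$sex))
  g$cost_direct <- co$cost_direct[ci]
  g$treatment_days <- co$treatment_days[ci]
  gdp <- inputs$gdp
  if (is.null(gdp)) gdp <- unique(pop[, c("city", "gdp_daily")])
  g$gdp_daily <- gdp$gdp_daily[match(g$city, gdp$city)]
  class(g) <- c("burden_groups", "data.frame")
  g
}

#' Run the full pipeline on an input bundle
#'
#' Reads (or accepts) an input bundle, runs the two-stage Monte Carlo across
#' all scenarios, and optionally writes the national and per-city burden
#' tables plus a run manifest to `out_dir`.
#'
#' @param inputs directory containing the bundle, or the bundle list itself.
#' @param mc an [mc_config()].
#' @param crf a [cr_function()].
#' @param scenarios scenario names to evaluate.
#' @param out_dir optional output directory; created if missing.
#' @return the [run_two_stage()] result, invisibly when writing.
#' @export
run_pipeline <- function(inputs, mc = mc_config(), crf = cr_function(),
                         scenarios = c("SB", "EC", "IT1", "IT2", "IT3", "AQG"),
                         out_dir = NULL) {
  if (is.character(inputs)) inputs <- read_input_bundle(inputs)
  res <- run_two_stage(inputs, mc, crf, scenarios, by_city = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$national, file.path(out_dir, "burden_national.csv"),
              row.names = FALSE)
    write.csv(res$by_city, file.path(out_dir, "burden_by_city.csv"),
              row.names = FALSE)
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' Rounded percentage share
#'
#' `round(100 * x / total)`: the presentation rounding used for source
#' shares and scenario reduction percentages.
#' @param x,total numerator and denominator (same units).
#' @return integer percent.
#' @export
share_percent <- function(x, total) {
  stopifnot(all(total > 0))
  round(100 * x / total)
}

round_thousands <- function(x) round(x / 1e3)
round_millions <- function(x) round(x / 1e6)

#' Summary report tables from a burden result
#'
#' Renders the national results at presentation precision: cases to the
#' nearest thousand, shares and scenario reductions to the nearest integer
#' percent, and costs to the nearest million RMB.
#'
#' @param res a `burden_result` from [run_two_stage()]/[run_pipeline()].
#' @return list of data frames `cases_by_source`, `reductions_by_scenario`,
#'   `costs`.
#' @export
report_results <- function(res) {
  nat <- res$national
  pick <- function(kind) nat[nat$kind == kind, , drop = FALSE]
  an <- pick("attributable_cases")
  total <- an$mean[an$label == "total"]
  src <- an[an$label != "total", , drop = FALSE]
  cases_by_source <- data.frame(
    source = src$label,
    cases_thousands = round_thousands(src$mean),
    ui_low_thousands = round_thousands(src$ui_low),
    ui_high_thousands = round_thousands(src$ui_high),
    share_percent = share_percent(src$mean, total),
    stringsAsFactors = FALSE
  )
  cases_by_source <- rbind(cases_by_source, data.frame(
    source = "total",
    cases_thousands = round_thousands(total),
    ui_low_thousands = round_thousands(an$ui_low[an$label == "total"]),
    ui_high_thousands = round_thousands(an$ui_high[an$label == "total"]),
    share_percent = 100L, stringsAsFactors = FALSE))
  ran <- pick("reduction_cases")
  reductions_by_scenario <- if (nrow(ran)) data.frame(
    scenario = ran$label,
    reduction_thousands = round_thousands(ran$mean),
    ui_low_thousands = round_thousands(ran$ui_low),
    ui_high_thousands = round_thousands(ran$ui_high),
    reduction_percent = share_percent(ran$mean, total),
    stringsAsFactors = FALSE
  ) else NULL
  costs_at <- pick("attributable_cost")
  costs_rd <- pick("reduction_cost")
  costs <- rbind(
    data.frame(item = paste0("attributable_", costs_at$label),
               cost_million_rmb = round_millions(costs_at$mean),
               ui_low_million = round_millions(costs_at$ui_low),
               ui_high_million = round_millions(costs_at$ui_high),
               stringsAsFactors = FALSE),
    if (nrow(costs_rd)) data.frame(
      item = paste0("reduction_", costs_rd$label),
      cost_million_rmb = round_millions(costs_rd$mean),
      ui_low_million = round_millions(costs_rd$ui_low),
      ui_high_million = round_millions(costs_rd$ui_high),
      stringsAsFactors = FALSE)
  )
  list(cases_by_source = cases_by_source,
       reductions_by_scenario = reductions_by_scenario,
       costs = costs)
}
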