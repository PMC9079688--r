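#' Age groups and their widths (years) used throughout the pipeline
#'
#' Six pediatric age bands spanning 0-17 years. Widths are used to split a
#' city's child population across bands.
#' @keywords internal
AGE_GROUPS <- c("0-0.5", "0.5-1", "1-2", "3-6", "7-11", "12-17")
AGE_WIDTHS <- c(`0-0.5` = 0.5, `0.5-1` = 0.5, `1-2` = 2, `3-6` = 4,
                `7-11` = 5, `12-17` = 6)
SEXES <- c("boy", "girl")
HOUSEHOLDS <- c("non-smoking", "smoking")

default_incidence <- function() {
  boys <- c(0.0165, 0.0150, 0.0130, 0.0100, 0.0065, 0.0045)
  data.frame(
    age_group = rep(AGE_GROUPS, times = 2),
    sex = rep(SEXES, each = length(AGE_GROUPS)),
    rate = c(boys, 0.78 * boys),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic study-input generator
#'
#' Defines the statistical structure of the emulated study: 330 urban cities
#' grouped into 31 provinces, positive right-skewed exposure concentrations
#' with a north-high indoor-source share gradient, age-declining asthma
#' incidence that is higher in boys, heavy-tailed city sizes, and province
#' level exposure factors and second-hand-smoke exposure proportions. The
#' defaults are the package's reference study conditions; they are not fitted
#' to any restricted dataset.
#'
#' @param n_cities number of cities (default 330).
#' @param n_provinces number of provinces cities are partitioned into
#'   (default 31). Ignored when `provinces` is given.
#' @param seed master RNG seed for the generator (integer < 2^31).
#' @param ambient_mean_range µg/m³ interval for city-level mean exposure to
#'   NO2 from outdoor sources.
#' @param cooking_share_target target grand-mean share of cooking in
#'   cooking + ambient exposure (unitless, ~0.25).
#' @param shs_mean_range µg/m³ interval for the mean second-hand-smoke
#'   increment experienced in smoking households.
#' @param cv_within_group coefficient of variation of the intra-population
#'   variability distribution attached to every concentration mean.
#' @param fexp_range unitless interval in (0, 1] for provincial exposure
#'   factors.
#' @param pshs_range interval between 0 and 1 for provincial proportions of the
#'   population exposed to second-hand smoke.
#' @param incidence_by_age_sex data frame with columns `age_group`, `sex`,
#'   `rate` (per person-year), one row per age band and sex. Rates must
#'   decrease with age within sex and be at least as high in boys as girls.
#' @param province_ir_modifiers optional named vector of multiplicative
#'   province-level incidence modifiers (default: all 1).
#' @param population_total total number of urban children across all cities.
#' @param cost_direct_range RMB interval for age/sex-specific direct cost per
#'   case.
#' @param treatment_days_range interval (days) for age/sex-specific treatment
#'   and hospitalization days per case.
#' @param gdp_daily_range RMB/day interval for city-level daily per-capita GDP.
#' @param variability_family intra-population variability family used when
#'   sampling exposure draws: `"lognormal"` (default) or `"truncnorm"`.
#' @param lat_range latitude-like covariate range (degrees) for cities.
#' @param lat_share_slope logit-scale slope of the cooking share on the
#'   latitude covariate; positive values give the north-high indoor gradient.
#' @param share_noise_sd logit-scale SD of city-level noise in cooking share.
#' @param age_exposure_factors named multiplier per age band applied to all
#'   concentration means (activity-pattern differences between ages).
#' @param sex_boy_share share of boys among children.
#' @param city_labels optional character vector of unique city labels.
#' @param provinces optional named list mapping province label -> character
#'   vector of city labels (a full partition of `city_labels`).
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_cities = 330L,
                             n_provinces = 31L,
                             seed = 20190101L,
                             ambient_mean_range = c(10, 40),
                             cooking_share_target = 0.25,
                             shs_mean_range = c(0.5, 2.5),
                             cv_within_group = 0.4,
                             fexp_range = c(0.55, 0.85),
                             pshs_range = c(0.30, 0.60),
                             incidence_by_age_sex = default_incidence(),
                             province_ir_modifiers = NULL,
                             population_total = 1.7e8,
                             cost_direct_range = c(900, 1500),
                             treatment_days_range = c(2, 6),
                             gdp_daily_range = c(120, 550),
                             variability_family = c("lognormal", "truncnorm"),
                             lat_range = c(18, 50),
                             lat_share_slope = 0.045,
                             share_noise_sd = 0.25,
                             age_exposure_factors = c(`0-0.5` = 0.95, `0.5-1` = 0.95,
                                                      `1-2` = 1, `3-6` = 1,
                                                      `7-11` = 1.05, `12-17` = 1.05),
                             sex_boy_share = 0.52,
                             city_labels = NULL,
                             provinces = NULL) {
  cfg <- list(
    n_cities = as.integer(n_cities), n_provinces = as.integer(n_provinces),
    seed = as.integer(seed),
    ambient_mean_range = ambient_mean_range,
    cooking_share_target = cooking_share_target,
    shs_mean_range = shs_mean_range,
    cv_within_group = cv_within_group,
    fexp_range = fexp_range, pshs_range = pshs_range,
    incidence_by_age_sex = incidence_by_age_sex,
    province_ir_modifiers = province_ir_modifiers,
    population_total = population_total,
    cost_direct_range = cost_direct_range,
    treatment_days_range = treatment_days_range,
    gdp_daily_range = gdp_daily_range,
    variability_family = match.arg(variability_family),
    lat_range = lat_range, lat_share_slope = lat_share_slope,
    share_noise_sd = share_noise_sd,
    age_exposure_factors = age_exposure_factors,
    sex_boy_share = sex_boy_share,
    city_labels = city_labels, provinces = provinces
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  err <- function(...) stop(sprintf(...), call. = FALSE)
  if (cfg$n_cities < 1L) err("configuration error: n_cities must be >= 1")
  if (cfg$seed >= 2^31 - 10 || cfg$seed < 0) err("configuration error: seed must be a non-negative 32-bit integer")
  rng_pos <- function(r, name, allow_zero_lo = FALSE) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      err("configuration error: %s must be a finite ascending interval", name)
    if ((allow_zero_lo && r[1] < 0) || (!allow_zero_lo && r[1] <= 0))
      err("configuration error: %s must be strictly positive", name)
  }
  rng_pos(cfg$ambient_mean_range, "ambient_mean_range")
  rng_pos(cfg$shs_mean_range, "shs_mean_range")
  rng_pos(cfg$cost_direct_range, "cost_direct_range")
  rng_pos(cfg$treatment_days_range, "treatment_days_range")
  rng_pos(cfg$gdp_daily_range, "gdp_daily_range")
  if (cfg$cooking_share_target < 0 || cfg$cooking_share_target >= 1)
    err("configuration error: cooking_share_target must lie in [0, 1)")
  if (cfg$cv_within_group < 0) err("configuration error: cv_within_group must be >= 0")
  f <- cfg$fexp_range
  if (f[1] <= 0 || f[2] > 1 || f[1] > f[2])
    err("configuration error: fexp_range must be a sub-interval of (0, 1]")
  p <- cfg$pshs_range
  if (p[1] < 0 || p[2] > 1 || p[1] > p[2])
    err("configuration error: pshs_range must be a sub-interval of [0, 1]")
  if (cfg$population_total <= 0)
    err("configuration error: population_total must be > 0")
  ir <- cfg$incidence_by_age_sex
  need <- c("age_group", "sex", "rate")
  if (!all(need %in% names(ir))) err("configuration error: incidence_by_age_sex needs columns %s",
                                     paste(need, collapse = ", "))
  if (any(ir$rate <= 0 | ir$rate >= 1))
    err("configuration error: incidence rates must lie in (0, 1)")
  for (s in SEXES) {
    r <- ir$rate[ir$sex == s][match(AGE_GROUPS, ir$age_group[ir$sex == s])]
    if (any(is.na(r))) err("configuration error: incidence_by_age_sex must cover all age groups for '%s'", s)
    if (any(diff(r) > 0)) err("configuration error: incidence must decrease with age within sex")
  }
  rb <- cfg$incidence_by_age_sex
  boy <- rb$rate[rb$sex == "boy"][match(AGE_GROUPS, rb$age_group[rb$sex == "boy"])]
  girl <- rb$rate[rb$sex == "girl"][match(AGE_GROUPS, rb$age_group[rb$sex == "girl"])]
  if (any(boy < girl)) err("configuration error: boys' incidence must be >= girls' at each age")
  if (!is.null(cfg$city_labels)) {
    if (length(cfg$city_labels) != cfg$n_cities)
      err("validation error: city_labels must have length n_cities")
    if (anyDuplicated(cfg$city_labels))
      err("validation error: duplicate city labels: %s",
          paste(unique(cfg$city_labels[duplicated(cfg$city_labels)]), collapse = ", "))
  }
  if (!is.null(cfg$provinces)) {
    all_cities <- unlist(cfg$provinces, use.names = FALSE)
    labels <- cfg$city_labels %||% default_city_labels(cfg$n_cities)
    if (anyDuplicated(all_cities) || !setequal(all_cities, labels))
      err("validation error: provinces must partition the city labels")
  }
  cfg
}

default_city_labels <- function(n) sprintf("C%03d", seq_len(n))

# City-level frame shared by all three generators so exposure, population and
# context tables refer to the same cities, provinces and latitudes.
city_frame <- function(config) {
  with_seed(config$seed, {
    n <- config$n_cities
    city <- config$city_labels %||% default_city_labels(n)
    if (!is.null(config$provinces)) {
      map <- rep(names(config$provinces), lengths(config$provinces))
      province <- map[match(city, unlist(config$provinces, use.names = FALSE))]
    } else {
      province <- sprintf("P%02d", ((seq_len(n) - 1L) %% config$n_provinces) + 1L)
    }
    lat <- runif(n, config$lat_range[1], config$lat_range[2])
    ambient <- runif(n, config$ambient_mean_range[1], config$ambient_mean_range[2])
    shs_inc <- runif(n, config$shs_mean_range[1], config$shs_mean_range[2])
    # Cooking share of (cooking + ambient) exposure on the logit scale:
    # centred on the target, increasing with latitude (north-high indoor
    # share), plus city-level noise.
    lg <- qlogis(config$cooking_share_target) +
      config$lat_share_slope * (lat - mean(config$lat_range)) +
      rnorm(n, 0, config$share_noise_sd)
    share <- plogis(lg)
    size_w <- exp(rnorm(n, 0, 1))  # heavy-tailed city sizes
    data.frame(city = city, province = province, latitude = lat,
               ambient_city = ambient, shs_increment = shs_inc,
               cooking_share = share, size_w = size_w,
               stringsAsFactors = FALSE)
  })
}

#' Generate the per-stratum source-specific exposure table
#'
#' One row per city x age group (6) x sex (2) x household type (2), with the
#' mean and SD of annual NO2 exposure concentration from cooking and outdoor
#' sources, and (smoking households only) from all indoor sources combined.
#' SDs are `cv_within_group` times the mean. The smoking-household indoor
#' mean is constructed as cooking mean + a strictly positive second-hand
#' smoke increment, so deriving the SHS concentration by subtraction is
#' non-negative by construction.
#'
#' @param config a [synthetic_config()].
#' @return data frame with columns `city`, `province`, `latitude`,
#'   `age_group`, `sex`, `household`, `cooking_mean`, `cooking_sd`,
#'   `ambient_mean`, `ambient_sd`, `indoor_smoking_mean`,
#'   `indoor_smoking_sd` (NA for non-smoking households). Units µg/m³.
#' @export
generate_exposure_table <- function(config) {
  config <- validate_synthetic_config(config)
  cf <- city_frame(config)
  grid <- expand.grid(household = HOUSEHOLDS, sex = SEXES, age_group = AGE_GROUPS,
                      city = cf$city, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  i <- match(grid$city, cf$city)
  af <- config$age_exposure_factors[grid$age_group]
  share <- cf$cooking_share[i]
  cook_city <- cf$ambient_city[i] * share / (1 - share)
  out <- data.frame(
    city = grid$city,
    province = cf$province[i],
    latitude = cf$latitude[i],
    age_group = grid$age_group,
    sex = grid$sex,
    household = grid$household,
    cooking_mean = cook_city * af,
    ambient_mean = cf$ambient_city[i] * af,
    stringsAsFactors = FALSE
  )
  out$cooking_sd <- config$cv_within_group * out$cooking_mean
  out$ambient_sd <- config$cv_within_group * out$ambient_mean
  smoking <- out$household == "smoking"
  out$indoor_smoking_mean <- ifelse(smoking,
                                    (cook_city + cf$shs_increment[i]) * af, NA_real_)
  out$indoor_smoking_sd <- ifelse(smoking,
                                  config$cv_within_group * out$indoor_smoking_mean,
                                  NA_real_)
  out[order(out$city, out$age_group, out$sex, out$household),
      c("city", "province", "latitude", "age_group", "sex", "household",
        "cooking_mean", "cooking_sd", "ambient_mean", "ambient_sd",
        "indoor_smoking_mean", "indoor_smoking_sd")]
}

#' Generate the per-stratum child population and incidence table
#'
#' City child populations follow a heavy-tailed (lognormal) size distribution
#' normalized to `population_total`, split across age bands proportional to
#' band width and between sexes by `sex_boy_share`. Incidence echoes the
#' configured age/sex rates, multiplied by any province-level modifiers.
#'
#' @param config a [synthetic_config()].
#' @return data frame with columns `city`, `province`, `age_group`, `sex`,
#'   `N` (children, integer-rounded), `IR` (per person-year), and `gdp_daily`
#'   (RMB/day, city-level, denormalized for a self-contained table).
#' @export
generate_population_incidence <- function(config) {
  config <- validate_synthetic_config(config)
  cf <- city_frame(config)
  ctx <- generate_context_tables(config)
  children_city <- config$population_total * cf$size_w / sum(cf$size_w)
  grid <- expand.grid(sex = SEXES, age_group = AGE_GROUPS, city = cf$city,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$city, cf$city)
  wfrac <- AGE_WIDTHS[grid$age_group] / sum(AGE_WIDTHS)
  sexfrac <- ifelse(grid$sex == "boy", config$sex_boy_share, 1 - config$sex_boy_share)
  ir_tab <- config$incidence_by_age_sex
  base_ir <- ir_tab$rate[match(paste(grid$age_group, grid$sex),
                               paste(ir_tab$age_group, ir_tab$sex))]
  province <- cf$province[i]
  mod <- rep(1, nrow(grid))
  if (!is.null(config$province_ir_modifiers)) {
    m <- config$province_ir_modifiers[province]
    mod <- ifelse(is.na(m), 1, m)
  }
  out <- data.frame(
    city = grid$city, province = province,
    age_group = grid$age_group, sex = grid$sex,
    N = round(children_city[i] * wfrac * sexfrac),
    IR = base_ir * mod,
    gdp_daily = ctx$gdp$gdp_daily[match(grid$city, ctx$gdp$city)],
    stringsAsFactors = FALSE
  )
  out[order(out$city, out$age_group, out$sex), ]
}

#' Generate province- and city-level context tables
#'
#' @param config a [synthetic_config()].
#' @return list with elements `province` (columns `province`, `f_exp`,
#'   `p_shs`), `cost` (columns `age_group`, `sex`, `cost_direct` RMB,
#'   `treatment_days`), and `gdp` (columns `city`, `gdp_daily` RMB/day).
#' @export
generate_context_tables <- function(config) {
  config <- validate_synthetic_config(config)
  cf <- city_frame(config)
  provs <- sort(unique(cf$province))
  with_seed(config$seed + 2L, {
    province <- data.frame(
      province = provs,
      f_exp = runif(length(provs), config$fexp_range[1], config$fexp_range[2]),
      p_shs = runif(length(provs), config$pshs_range[1], config$pshs_range[2]),
      stringsAsFactors = FALSE
    )
    cost <- expand.grid(sex = SEXES, age_group = AGE_GROUPS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cost$cost_direct <- runif(nrow(cost), config$cost_direct_range[1],
                              config$cost_direct_range[2])
    cost$treatment_days <- runif(nrow(cost), config$treatment_days_range[1],
                                 config$treatment_days_range[2])
    gdp <- data.frame(
      city = cf$city,
      gdp_daily = runif(nrow(cf), config$gdp_daily_range[1],
                        config$gdp_daily_range[2]),
      stringsAsFactors = FALSE
    )
    list(province = province, cost = cost[, c("age_group", "sex", "cost_direct",
                                              "treatment_days")], gdp = gdp)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits the four input CSVs (`exposure.csv`, `population_incidence.csv`,
#' `context_province.csv`, `context_cost.csv`) plus a JSON sidecar recording
#' the generator configuration and seed. City-level daily GDP is carried as a
#' column of `population_incidence.csv` (see the data dictionary in
#' `inst/extdata/`).
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
simulate_inputs <- function(config, dir) {
  config <- validate_synthetic_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exposure <- generate_exposure_table(config)
  population <- generate_population_incidence(config)
  ctx <- generate_context_tables(config)
  paths <- c(
    exposure = file.path(dir, "exposure.csv"),
    population_incidence = file.path(dir, "population_incidence.csv"),
    context_province = file.path(dir, "context_province.csv"),
    context_cost = file.path(dir, "context_cost.csv"),
    sidecar = file.path(dir, "synthetic_config.json")
  )
  write.csv(exposure, paths["exposure"], row.names = FALSE)
  write.csv(population, paths["population_incidence"], row.names = FALSE)
  write.csv(ctx$province, paths["context_province"], row.names = FALSE)
  write.csv(ctx$cost, paths["context_cost"], row.names = FALSE)
  side <- config
  class(side) <- NULL
  jsonlite::write_json(side, paths["sidecar"], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}

#' Assemble the in-memory input bundle from a configuration
#'
#' Convenience wrapper returning the same structure [read_input_bundle()]
#' produces, without touching disk.
#' @param config a [synthetic_config()].
#' @return list with `exposure`, `population`, `province`, `cost`, `gdp`.
#' @export
generate_inputs <- function(config) {
  config <- validate_synthetic_config(config)
  ctx <- generate_context_tables(config)
  list(exposure = generate_exposure_table(config),
       population = generate_population_incidence(config),
       province = ctx$province, cost = ctx$cost, gdp = ctx$gdp)
}
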