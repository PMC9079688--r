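#' Two-stage Monte Carlo configuration
#'
#' Draw counts and uncertainty-distribution settings for the nested
#' simulation separating intra-population exposure variability (inner stage)
#' from parameter uncertainty (outer stage). Defaults follow the study
#' design: 2000 variability draws, 1000 uncertainty draws, and a 250-repeat
#' robustness check.
#'
#' Uncertainty families: RR0 is lognormal matched to its median and 95%
#' interval (positivity, asymmetric interval); the low-concentration
#' threshold is triangular over its stated range with the stated central
#' value as mode (a uniform alternative is available but its mean differs
#' from the central value); incidence, direct cost and treatment days get
#' multiplicative Normal(1, cv) factors censored at 0, drawn independently.
#'
#' @param n_variability inner-stage draws per stratum and household type.
#' @param n_uncertainty outer-stage draws.
#' @param n_robustness repeated full simulations in [robustness_check()].
#' @param seed master seed; recorded in every result manifest.
#' @param cv_incidence,cv_cost,cv_days coefficients of variation of the
#'   multiplicative uncertainty on baseline incidence, direct cost, and
#'   treatment days.
#' @param variability_family intra-population variability family
#'   (`"lognormal"` default, `"truncnorm"` alternative).
#' @param lc_dist distribution of the low-concentration threshold
#'   (`"triangular"` default, `"uniform"` alternative).
#' @return object of class `mc_config`.
#' @export
mc_config <- function(n_variability = 2000L, n_uncertainty = 1000L,
                      n_robustness = 250L, seed = 1L,
                      cv_incidence = 0.1, cv_cost = 0.2, cv_days = 0.2,
                      variability_family = c("lognormal", "truncnorm"),
                      lc_dist = c("triangular", "uniform")) {
  stopifnot(n_variability >= 1L, n_uncertainty >= 1L, n_robustness >= 1L,
            cv_incidence >= 0, cv_cost >= 0, cv_days >= 0,
            seed >= 0, seed < 2^31 - 1)
  structure(list(n_variability = as.integer(n_variability),
                 n_uncertainty = as.integer(n_uncertainty),
                 n_robustness = as.integer(n_robustness),
                 seed = as.integer(seed),
                 cv_incidence = cv_incidence, cv_cost = cv_cost,
                 cv_days = cv_days,
                 variability_family = match.arg(variability_family),
                 lc_dist = match.arg(lc_dist)),
            class = "mc_config")
}

# Outer-stage parameter draws, in a fixed documented order so results are
# bit-reproducible for a given seed. RR0 sdlog is matched to the 95% UI;
# a degenerate UI (both bounds equal to rr0) gives point draws.
draw_uncertainty <- function(mc, crf) {
  u <- mc$n_uncertainty
  sdlog <- (log(crf$rr0_ui[2]) - log(crf$rr0_ui[1])) / (2 * qnorm(0.975))
  rr0 <- if (sdlog > 0) exp(rnorm(u, log(crf$rr0), sdlog)) else rep(crf$rr0, u)
  lc <- if (mc$lc_dist == "triangular") {
    rtri(u, crf$lc_range[1], crf$lc, crf$lc_range[2])
  } else {
    if (crf$lc_range[1] == crf$lc_range[2]) rep(crf$lc_range[1], u)
    else runif(u, crf$lc_range[1], crf$lc_range[2])
  }
  list(rr0 = rr0, lc = lc,
       ir_mult = runc_mult(u, mc$cv_incidence),
       cost_mult = runc_mult(u, mc$cv_cost),
       days_mult = runc_mult(u, mc$cv_days))
}

result_row <- function(kind, label, unit, draws) {
  s <- summarise_draws(draws)
  data.frame(kind = kind, label = label, unit = unit,
             mean = s[["mean"]], ui_low = s[["ui_low"]], ui_high = s[["ui_high"]],
             stringsAsFactors = FALSE)
}

#' Run the two-stage variability/uncertainty Monte Carlo
#'
#' For each outer (uncertainty) draw of the concentration-response
#' parameters, baseline incidence and cost parameters, the inner stage
#' averages the relative risk over intra-population exposure draws per
#' stratum and household type; household-type averages are mixed by the
#' proportion exposed to second-hand smoke, then converted to attributable
#' fractions, attributable cases by source, scenario case reductions, and
#' costs. Results are summarized across uncertainty draws as the mean and
#' the 2.5th-97.5th percentile interval.
#'
#' Variability draws are generated once per run (per stratum, household type
#' and source) and shared between the baseline and every scenario within
#' each uncertainty draw (common random numbers), so scenario contrasts are
#' not noise-dominated.
#'
#' @param inputs input bundle (list with `exposure`, `population`,
#'   `province`, `cost`, optionally `gdp`) or a prebuilt groups table from
#'   [build_groups()].
#' @param mc an [mc_config()].
#' @param crf a [cr_function()].
#' @param scenarios scenario names to evaluate (default all restriction
#'   scenarios); use `character(0)` for the baseline burden only.
#' @param by_city also summarize total attributable cases per city.
#' @param keep_draws attach per-draw vectors (for diagnostics and tests).
#' @return object of class `burden_result`: list with `national` (data frame
#'   of kind/label/mean/ui), optional `by_city`, optional `draws`, and a
#'   `manifest` recording seed, draw counts and distribution choices.
#' @export
run_two_stage <- function(inputs, mc = mc_config(), crf = cr_function(),
                          scenarios = c("SB", "EC", "IT1", "IT2", "IT3", "AQG"),
                          by_city = FALSE, keep_draws = FALSE) {
  groups <- if (inherits(inputs, "burden_groups")) inputs else build_groups(inputs)
  if (length(scenarios)) {
    scenarios <- vapply(scenarios, function(s) as_scenario(s)$name, "")
  }
  G <- nrow(groups)
  V <- mc$n_variability
  U <- mc$n_uncertainty

  dr <- with_seed(mc$seed, {
    list(z_cook = matrix(rnorm(G * V), G, V),
         z_amb = matrix(rnorm(G * V), G, V),
         z_shs = matrix(rnorm(G * V), G, V),
         unc = draw_uncertainty(mc, crf))
  })
  unc <- dr$unc
  b <- log(unc$rr0) / crf$delta_c0

  fam <- mc$variability_family
  # Source-specific exposure draws; cooking and ambient reuse the same
  # standard-normal draws across household types (common random numbers).
  Xc_ns <- draw_variability(groups$cook_ns_mean, groups$cook_ns_sd, dr$z_cook, fam)
  Xa_ns <- draw_variability(groups$amb_ns_mean, groups$amb_ns_sd, dr$z_amb, fam)
  Xc_s <- draw_variability(groups$cook_s_mean, groups$cook_s_sd, dr$z_cook, fam)
  Xa_s <- draw_variability(groups$amb_s_mean, groups$amb_s_sd, dr$z_amb, fam)
  Xshs <- draw_variability(groups$shs_mean, groups$shs_sd, dr$z_shs, fam)

  k <- crf$ugm3_to_ppb / groups$f_exp  # µg/m³ exposure -> equivalent ambient ppb
  bad <- !is.finite(k) | k <= 0
  if (any(bad)) {
    stop(sprintf("non-finite exposure scaling for strata: %s",
                 paste(utils::head(paste(groups$city, groups$age_group,
                                         groups$sex)[bad], 3), collapse = "; ")),
         call. = FALSE)
  }

  rr_ns_base <- rr_pop_mean_cpp((Xc_ns + Xa_ns) * k, b, unc$lc)
  rr_s_base <- rr_pop_mean_cpp((Xc_s + Xa_s + Xshs) * k, b, unc$lc)
  p <- groups$p_shs
  rrbar_base <- (1 - p) * rr_ns_base + p * rr_s_base
  if (any(!is.finite(rrbar_base))) {
    stop("non-finite relative risk encountered; check exposure inputs",
         call. = FALSE)
  }
  paf_gu <- (rrbar_base - 1) / rrbar_base

  w <- groups$IR * groups$N
  ps <- source_proportions(groups$cook_ns_mean, groups$amb_ns_mean,
                           groups$shs_mean, groups$p_shs)
  unit_d <- groups$cost_direct
  unit_i <- groups$gdp_daily * groups$treatment_days

  cases_u <- function(frac_gu, weight) {
    as.vector(crossprod(frac_gu, weight)) * unc$ir_mult
  }
  cost_u <- function(frac_gu, weight) {
    unc$ir_mult * (unc$cost_mult * as.vector(crossprod(frac_gu, weight * unit_d)) +
                   unc$days_mult * as.vector(crossprod(frac_gu, weight * unit_i)))
  }

  an <- list(ambient = cases_u(paf_gu, ps$ps_ambient * w),
             cooking = cases_u(paf_gu, ps$ps_cooking * w),
             SHS = cases_u(paf_gu, ps$ps_shs * w),
             total = cases_u(paf_gu, w))
  an_cost <- list(ambient = cost_u(paf_gu, ps$ps_ambient * w),
                  cooking = cost_u(paf_gu, ps$ps_cooking * w),
                  SHS = cost_u(paf_gu, ps$ps_shs * w),
                  total = cost_u(paf_gu, w))

  ran <- list()
  ran_cost <- list()
  pif_draws <- list()
  for (s in scenarios) {
    if (s == "SB") {
      rrbar_po <- rr_ns_base
    } else if (s == "EC") {
      rr_ns_po <- rr_pop_mean_cpp(Xa_ns * k, b, unc$lc)
      rr_s_po <- rr_pop_mean_cpp((Xa_s + Xshs) * k, b, unc$lc)
      rrbar_po <- (1 - p) * rr_ns_po + p * rr_s_po
    } else if (s %in% names(OUTDOOR_TARGETS)) {
      target <- OUTDOOR_TARGETS[[s]]
      ratio_ns <- ifelse(groups$amb_ns_mean / groups$f_exp > target,
                         target * groups$f_exp / groups$amb_ns_mean, 1)
      ratio_s <- ifelse(groups$amb_s_mean / groups$f_exp > target,
                        target * groups$f_exp / groups$amb_s_mean, 1)
      if (all(ratio_ns == 1) && all(ratio_s == 1)) {
        rrbar_po <- rrbar_base
      } else {
        rr_ns_po <- rr_pop_mean_cpp((Xc_ns + Xa_ns * ratio_ns) * k, b, unc$lc)
        rr_s_po <- rr_pop_mean_cpp((Xc_s + Xa_s * ratio_s + Xshs) * k, b, unc$lc)
        rrbar_po <- (1 - p) * rr_ns_po + p * rr_s_po
      }
    } else {
      rrbar_po <- rrbar_base  # BASELINE2019
    }
    pif_gu <- (rrbar_base - rrbar_po) / rrbar_base
    ran[[s]] <- cases_u(pif_gu, w)
    ran_cost[[s]] <- cost_u(pif_gu, w)
    if (keep_draws) pif_draws[[s]] <- pif_gu
  }

  national <- rbind(
    do.call(rbind, lapply(names(an), function(l)
      result_row("attributable_cases", l, "cases/year", an[[l]]))),
    result_row("attributable_rate", "total", "per 100,000 children/year",
               an$total / sum(groups$N) * 1e5),
    if (length(ran)) do.call(rbind, lapply(names(ran), function(l)
      result_row("reduction_cases", l, "cases/year", ran[[l]]))),
    do.call(rbind, lapply(names(an_cost), function(l)
      result_row("attributable_cost", l, "RMB/year", an_cost[[l]]))),
    if (length(ran_cost)) do.call(rbind, lapply(names(ran_cost), function(l)
      result_row("reduction_cost", l, "RMB/year", ran_cost[[l]])))
  )
  rownames(national) <- NULL

  by_city_df <- NULL
  if (by_city) {
    m <- rowsum(paf_gu * w, groups$city)
    m <- t(t(m) * unc$ir_mult)
    s <- t(apply(m, 1, summarise_draws))
    by_city_df <- data.frame(city = rownames(m), mean = s[, "mean"],
                             ui_low = s[, "ui_low"], ui_high = s[, "ui_high"],
                             stringsAsFactors = FALSE)
    rownames(by_city_df) <- NULL
  }

  manifest <- list(
    seed = mc$seed, n_variability = V, n_uncertainty = U,
    variability_family = fam, lc_dist = mc$lc_dist,
    cv_incidence = mc$cv_incidence, cv_cost = mc$cv_cost, cv_days = mc$cv_days,
    crf = unclass(crf), scenarios = scenarios,
    n_strata = G, total_children = sum(groups$N),
    package = as.character(utils::packageVersion("no2burden"))
  )

  out <- list(national = national, by_city = by_city_df, manifest = manifest)
  if (keep_draws) {
    out$draws <- list(an = an, ran = ran, an_cost = an_cost,
                      ran_cost = ran_cost, rr0 = unc$rr0, lc = unc$lc)
  }
  class(out) <- "burden_result"
  out
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("Two-stage Monte Carlo burden result (%d strata, %d x %d draws, seed %d)\n",
              x$manifest$n_strata, x$manifest$n_variability,
              x$manifest$n_uncertainty, x$manifest$seed))
  print(x$national, digits = 4)
  invisible(x)
}

#' Deterministic (point-estimate) pipeline
#'
#' Evaluates the full chain on concentration means with central parameters
#' and no sampling. Coincides with the Monte Carlo mean when all variability
#' SDs are zero and all uncertainty distributions are degenerate.
#'
#' @inheritParams run_two_stage
#' @return data frame with kind, label, unit, value.
#' @export
run_deterministic <- function(inputs, crf = cr_function(),
                              scenarios = c("SB", "EC", "IT1", "IT2", "IT3", "AQG")) {
  groups <- if (inherits(inputs, "burden_groups")) inputs else build_groups(inputs)
  rr_mix <- function(cook_ns, amb_ns, cook_s, amb_s, shs, p) {
    rr_ns <- rr_from_exposure(cook_ns + amb_ns, groups$f_exp, crf)
    rr_s <- rr_from_exposure(cook_s + amb_s + shs, groups$f_exp, crf)
    mean_rr_group(rr_ns, rr_s, p)
  }
  rrbar <- rr_mix(groups$cook_ns_mean, groups$amb_ns_mean,
                  groups$cook_s_mean, groups$amb_s_mean, groups$shs_mean,
                  groups$p_shs)
  paf_g <- paf(rrbar)
  w <- groups$IR * groups$N
  ps <- source_proportions(groups$cook_ns_mean, groups$amb_ns_mean,
                           groups$shs_mean, groups$p_shs)
  unit_cost <- groups$cost_direct + groups$gdp_daily * groups$treatment_days
  rows <- list()
  add <- function(kind, label, unit, value) {
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, label = label,
                                             unit = unit, value = value,
                                             stringsAsFactors = FALSE)
  }
  for (l in c("ambient", "cooking", "SHS")) {
    psl <- ps[[paste0("ps_", tolower(sub("SHS", "shs", l)))]]
    add("attributable_cases", l, "cases/year",
        attributable_cases(groups, paf_g, psl))
    add("attributable_cost", l, "RMB/year", sum(psl * paf_g * w * unit_cost))
  }
  add("attributable_cases", "total", "cases/year", attributable_cases(groups, paf_g))
  add("attributable_cost", "total", "RMB/year", sum(paf_g * w * unit_cost))
  for (s in scenarios) {
    sc <- as_scenario(s)
    if (sc$name == "SB") {
      rr_ns <- rr_from_exposure(groups$cook_ns_mean + groups$amb_ns_mean,
                                groups$f_exp, crf)
      rrbar_po <- rr_ns
    } else if (sc$name == "EC") {
      rrbar_po <- rr_mix(0, groups$amb_ns_mean, 0, groups$amb_s_mean,
                         groups$shs_mean, groups$p_shs)
    } else if (sc$name %in% names(OUTDOOR_TARGETS)) {
      t0 <- sc$outdoor_target
      r_ns <- ifelse(groups$amb_ns_mean / groups$f_exp > t0,
                     t0 * groups$f_exp / groups$amb_ns_mean, 1)
      r_s <- ifelse(groups$amb_s_mean / groups$f_exp > t0,
                    t0 * groups$f_exp / groups$amb_s_mean, 1)
      rrbar_po <- rr_mix(groups$cook_ns_mean, groups$amb_ns_mean * r_ns,
                         groups$cook_s_mean, groups$amb_s_mean * r_s,
                         groups$shs_mean, groups$p_shs)
    } else {
      rrbar_po <- rrbar
    }
    pif_g <- pif(rrbar, rrbar_po)
    add("reduction_cases", sc$name, "cases/year", reduction_cases(groups, pif_g))
    add("reduction_cost", sc$name, "RMB/year", sum(pif_g * w * unit_cost))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeated-simulation robustness check
#'
#' Repeats the full two-stage simulation with distinct sub-seeds and reports
#' the maximum relative deviation of the headline estimate (national
#' attributable cases, all sources) from the grand mean, together with the
#' standard deviation of the relative deviations.
#'
#' @param inputs input bundle or prebuilt groups table.
#' @param mc an [mc_config()]; `n_robustness` controls the repeat count.
#' @param crf a [cr_function()].
#' @return list with `max_rel_error`, `sd_rel_error`, `estimates`,
#'   `grand_mean`, and the sub-seeds used.
#' @export
robustness_check <- function(inputs, mc = mc_config(), crf = cr_function()) {
  groups <- if (inherits(inputs, "burden_groups")) inputs else build_groups(inputs)
  sub_seeds <- with_seed(mc$seed,
                         sample.int(.Machine$integer.max, mc$n_robustness))
  estimates <- vapply(sub_seeds, function(s) {
    mci <- mc
    mci$seed <- s
    res <- run_two_stage(groups, mci, crf, scenarios = character(0))
    nat <- res$national
    nat$mean[nat$kind == "attributable_cases" & nat$label == "total"]
  }, numeric(1))
  grand <- mean(estimates)
  rel <- abs(estimates - grand) / grand
  list(max_rel_error = max(rel), sd_rel_error = sd(estimates / grand),
       estimates = estimates, grand_mean = grand, sub_seeds = sub_seeds)
}
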