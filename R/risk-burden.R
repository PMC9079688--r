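#' Concentration-response function parameters
#'
#' Log-linear concentration-response relationship between ambient-equivalent
#' NO2 and pediatric asthma incidence, with a low-concentration threshold
#' below which no excess risk is assumed. Central values come from a
#' meta-analysis of cohort studies: relative risk 1.26 (95% UI 1.10-1.37)
#' per 10 ppb, threshold 2 ppb (range 0-5). Concentrations in µg/m³ are
#' converted to ppb with `ppb = ugm3_to_ppb * µg/m³`.
#'
#' @param rr0 central relative risk per `delta_c0` increment.
#' @param rr0_ui length-2 vector, 95% uncertainty interval of `rr0`.
#' @param delta_c0 concentration increment for `rr0`, ppb.
#' @param lc central low-concentration threshold, ppb.
#' @param lc_range length-2 vector, range of the threshold, ppb.
#' @param ugm3_to_ppb unitless µg/m³-to-ppb conversion factor for NO2.
#' @return object of class `cr_function`.
#' @export
cr_function <- function(rr0 = 1.26, rr0_ui = c(1.10, 1.37), delta_c0 = 10,
                        lc = 2, lc_range = c(0, 5), ugm3_to_ppb = 0.487) {
  stopifnot(rr0 > 0, delta_c0 > 0, lc >= 0, ugm3_to_ppb > 0,
            length(rr0_ui) == 2L, all(rr0_ui > 0), rr0_ui[1] <= rr0_ui[2],
            length(lc_range) == 2L, lc_range[1] >= 0,
            lc_range[1] <= lc, lc <= lc_range[2])
  structure(list(rr0 = rr0, rr0_ui = rr0_ui, delta_c0 = delta_c0,
                 lc = lc, lc_range = lc_range, ugm3_to_ppb = ugm3_to_ppb),
            class = "cr_function")
}

#' Relative risk from an exposure concentration
#'
#' Converts a (total) NO2 exposure concentration to the equivalent ambient
#' concentration by dividing by the exposure factor, converts to ppb, and
#' applies the piecewise log-linear concentration-response function:
#' RR = 1 at or below the threshold, `rr0^((C - LC)/delta_c0)` above it.
#' The exponential is evaluated in log space.
#'
#' @param c_exp exposure concentration, µg/m³ (vectorized).
#' @param f_exp exposure factor in (0, 1].
#' @param crf a [cr_function()].
#' @param rr0,lc optional overrides of the central parameters (used by the
#'   uncertainty stage); default to the central values in `crf`.
#' @return relative risk (unitless, >= 1).
#' @export
rr_from_exposure <- function(c_exp, f_exp, crf = cr_function(),
                             rr0 = crf$rr0, lc = crf$lc) {
  check_range(c_exp, "c_exp", lo = 0)
  if (any(!is.finite(f_exp)) || any(f_exp <= 0) || any(f_exp > 1))
    stop("domain error: f_exp must lie in (0, 1]", call. = FALSE)
  ceq_ppb <- c_exp / f_exp * crf$ugm3_to_ppb
  ifelse(ceq_ppb <= lc, 1,
         exp(log(rr0) * (ceq_ppb - lc) / crf$delta_c0))
}

#' Population-average relative risk mixing household types
#'
#' Weighted mean of the average relative risks of non-smoking and smoking
#' households, weighted by the proportion of the population exposed to
#' second-hand smoke.
#'
#' @param rr_nonsmoking,rr_smoking average relative risks per household type.
#' @param p_shs proportion exposed to second-hand smoke, between 0 and 1.
#' @return population-average relative risk (vectorized).
#' @export
mean_rr_group <- function(rr_nonsmoking, rr_smoking, p_shs) {
  tol <- 1e-9
  stopifnot(all(rr_nonsmoking >= 1 - tol), all(rr_smoking >= 1 - tol))
  check_range(p_shs, "p_shs", lo = 0, hi = 1)
  (1 - p_shs) * rr_nonsmoking + p_shs * rr_smoking
}

#' Population attributable fraction
#'
#' Proportion of incidence attributable to the risk factor:
#' `(RR - 1) / RR`. Relative risks below 1 cannot arise from the
#' concentration-response function used here; they are rejected unless
#' `floor_negative = TRUE`, which warns and floors the fraction at 0 (guard
#' for user-supplied relative-risk tables).
#'
#' @param rr_bar population-average relative risk.
#' @param floor_negative floor sub-1 relative risks at PAF 0 instead of
#'   raising an error.
#' @return attributable fraction in [0, 1).
#' @export
paf <- function(rr_bar, floor_negative = FALSE) {
  if (any(rr_bar < 1)) {
    if (!floor_negative)
      stop("domain error: average relative risk below 1", call. = FALSE)
    warning("average relative risk below 1; flooring attributable fraction at 0")
    rr_bar <- pmax(rr_bar, 1)
  }
  (rr_bar - 1) / rr_bar
}

#' Potential impact fraction
#'
#' Proportional reduction in incidence when exposure moves from baseline to a
#' counterfactual: `(RR - RR') / RR`. Reduces to the attributable fraction
#' when the counterfactual removes all excess risk (RR' = 1).
#'
#' @param rr_bar baseline population-average relative risk.
#' @param rr_bar_po counterfactual population-average relative risk.
#' @return impact fraction (vectorized).
#' @export
pif <- function(rr_bar, rr_bar_po) {
  if (any(rr_bar <= 0)) stop("domain error: baseline relative risk must be > 0",
                             call. = FALSE)
  tol <- 1e-9
  stopifnot(all(rr_bar >= 1 - tol), all(rr_bar_po >= 1 - tol))
  (rr_bar - rr_bar_po) / rr_bar
}

check_aligned <- function(groups, x, what) {
  if (!all(c("N", "IR") %in% names(groups)))
    stop("validation error: groups table needs columns N and IR", call. = FALSE)
  if (length(x) != 1L && length(x) != nrow(groups))
    stop(sprintf("validation error: %s is not aligned with the groups table (%d vs %d rows)",
                 what, length(x), nrow(groups)), call. = FALSE)
  if (any(is.na(x)))
    stop(sprintf("validation error: %s contains missing values", what), call. = FALSE)
  invisible(TRUE)
}

#' Attributable new cases for one source
#'
#' Sums `PS * PAF * IR * N` over population groups: the share of the source
#' in each group's exposure, times the group's attributable fraction,
#' incidence and child population.
#'
#' @param groups table with columns `N` and `IR` (one row per group).
#' @param paf_g attributable fraction per group.
#' @param ps_g source contribution proportion per group (default 1 = all
#'   sources combined).
#' @param aggregate return the sum (default) or the per-group vector.
#' @return attributable cases per year.
#' @export
attributable_cases <- function(groups, paf_g, ps_g = 1, aggregate = TRUE) {
  check_aligned(groups, paf_g, "paf_g")
  check_aligned(groups, ps_g, "ps_g")
  check_range(paf_g, "paf_g", lo = 0, hi = 1)
  check_range(ps_g, "ps_g", lo = 0, hi = 1)
  an <- ps_g * paf_g * groups$IR * groups$N
  if (aggregate) sum(an) else an
}

#' Reduction in cases under a restriction scenario
#'
#' Sums `PIF * IR * N` over population groups.
#'
#' @param groups table with columns `N` and `IR`.
#' @param pif_g potential impact fraction per group.
#' @param aggregate return the sum (default) or the per-group vector.
#' @return avoided cases per year.
#' @export
reduction_cases <- function(groups, pif_g, aggregate = TRUE) {
  check_aligned(groups, pif_g, "pif_g")
  ran <- pif_g * groups$IR * groups$N
  if (aggregate) sum(ran) else ran
}

# Pure-R reference for the compiled variability-averaging kernel: mean over
# variability draws of max(1, exp(b * (ceq - lc))), per stratum (rows of
# `ceq`, ppb) and uncertainty draw (elements of `b` = log(RR0)/delta_c0 and
# `lc`). Used in tests to validate the Rcpp implementation.
rr_pop_mean_r <- function(ceq, b, lc) {
  out <- matrix(NA_real_, nrow(ceq), length(b))
  for (j in seq_along(b)) {
    out[, j] <- rowMeans(pmax(exp(b[j] * (ceq - lc[j])), 1))
  }
  out
}
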