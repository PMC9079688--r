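#' Cost of illness for attributable or avoided cases
#'
#' Monetizes cases with the cost-of-illness model: direct treatment costs
#' plus indirect productivity losses (caregiver absence priced at daily
#' per-capita GDP times treatment and hospitalization days), per case:
#' `(cost_direct + gdp_daily * treatment_days) * cases`. Computed per
#' stratum, so age/sex-specific costs and city-specific GDP bind correctly,
#' and summed by the caller.
#'
#' @param cases attributable or avoided cases per year (vectorized).
#' @param cost_direct direct cost per case, RMB (age/sex-specific).
#' @param gdp_daily daily per-capita GDP, RMB/day (city-specific).
#' @param treatment_days treatment and hospitalization days per case.
#' @return cost in RMB per year.
#' @export
cost_of_cases <- function(cases, cost_direct, gdp_daily, treatment_days) {
  for (nm in c("cases", "cost_direct", "gdp_daily", "treatment_days")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < 0))
      stop(sprintf("validation error: %s must be finite and >= 0", nm),
           call. = FALSE)
  }
  (cost_direct + gdp_daily * treatment_days) * cases
}
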