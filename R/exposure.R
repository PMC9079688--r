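#' Derive the second-hand-smoke exposure concentration
#'
#' The NO2 exposure attributable to second-hand smoke in smoking households
#' is the indoor-source exposure of smoking households minus the cooking
#' exposure. Negative differences (possible under measurement noise) are
#' clamped to zero with a warning: a negative source concentration is
#' physically meaningless.
#'
#' @param indoor_smoking_mean mean indoor-source exposure of smoking
#'   households, µg/m³.
#' @param cooking_mean mean cooking-source exposure, µg/m³.
#' @return mean second-hand-smoke exposure concentration, µg/m³ (vectorized).
#' @export
derive_shs <- function(indoor_smoking_mean, cooking_mean) {
  if (any(!is.finite(indoor_smoking_mean)) || any(!is.finite(cooking_mean)) ||
      any(indoor_smoking_mean < 0) || any(cooking_mean < 0)) {
    stop("validation error: concentrations must be finite and >= 0", call. = FALSE)
  }
  d <- indoor_smoking_mean - cooking_mean
  if (any(d < 0)) {
    warning(sprintf(
      "%d smoking-household indoor mean(s) below the cooking mean; clamping SHS concentration to 0",
      sum(d < 0)))
    d <- pmax(d, 0)
  }
  d
}

#' Total NO2 exposure concentration per stratum
#'
#' Cooking + ambient for non-smoking households; cooking + second-hand smoke
#' + ambient for smoking households.
#'
#' @param cooking,ambient mean source exposures, µg/m³ (vectorized).
#' @param shs mean second-hand-smoke exposure, µg/m³; ignored (treated as 0)
#'   for non-smoking households.
#' @param household `"smoking"` or `"non-smoking"` (recycled).
#' @return total exposure mean, µg/m³.
#' @export
total_exposure <- function(cooking, ambient, shs = 0, household = "non-smoking") {
  stopifnot(all(cooking >= 0), all(ambient >= 0), all(shs >= 0))
  household <- match.arg(household, HOUSEHOLDS, several.ok = TRUE)
  cooking + ambient + ifelse(rep_len(household, length(cooking)) == "smoking", shs, 0)
}

#' Source contribution proportions of NO2 exposure
#'
#' Shares of outdoor, cooking and second-hand-smoke sources in a stratum's
#' NO2 exposure. The second-hand-smoke term is weighted by the proportion of
#' the population exposed to second-hand smoke, so the three shares describe
#' the population mixture of smoking and non-smoking households and sum to 1.
#'
#' @param cooking,ambient,shs mean source exposure concentrations, µg/m³.
#' @param p_shs proportion of the population exposed to second-hand smoke,
#'   between 0 and 1.
#' @return data frame with columns `ps_ambient`, `ps_cooking`, `ps_shs`.
#' @export
source_proportions <- function(cooking, ambient, shs, p_shs) {
  check_range(cooking, "cooking", lo = 0)
  check_range(ambient, "ambient", lo = 0)
  check_range(shs, "shs", lo = 0)
  check_range(p_shs, "p_shs", lo = 0, hi = 1)
  denom <- cooking + ambient + p_shs * shs
  if (any(denom <= 0)) {
    stop("degenerate-input error: all source contributions are zero", call. = FALSE)
  }
  data.frame(ps_ambient = ambient / denom,
             ps_cooking = cooking / denom,
             ps_shs = p_shs * shs / denom)
}

SCENARIO_NAMES <- c("BASELINE2019", "SB", "EC", "IT1", "IT2", "IT3", "AQG")
OUTDOOR_TARGETS <- c(IT1 = 40, IT2 = 30, IT3 = 20, AQG = 10)  # µg/m³ outdoor

#' Define an emission-restriction scenario
#'
#' * `BASELINE2019`: identity (2019 conditions).
#' * `SB` (smoking ban): no second-hand smoke; concentrations unchanged, the
#'   proportion exposed to second-hand smoke is set to 0 downstream.
#' * `EC` (electric cooking): cooking-source exposure set to 0.
#' * `IT1`/`IT2`/`IT3`/`AQG`: outdoor air brought down to the WHO interim
#'   targets (40/30/20 µg/m³) or the 2021 air quality guideline (10 µg/m³)
#'   wherever the 2019 outdoor concentration exceeds the target.
#'
#' @param name one of `r paste(SCENARIO_NAMES, collapse = ", ")`.
#' @param outdoor_target optional override of the outdoor target (µg/m³) for
#'   the interim-target/guideline scenarios.
#' @return object of class `scenario`.
#' @export
scenario <- function(name, outdoor_target = NULL) {
  name <- match.arg(name, SCENARIO_NAMES)
  target <- outdoor_target %||% unname(OUTDOOR_TARGETS[name])
  if (name %in% names(OUTDOOR_TARGETS)) {
    if (is.na(target) || target <= 0)
      stop("outdoor_target must be > 0 for interim-target/guideline scenarios",
           call. = FALSE)
  } else {
    target <- NA_real_
  }
  structure(list(name = name, outdoor_target = target), class = "scenario")
}

as_scenario <- function(x) if (inherits(x, "scenario")) x else scenario(x)

#' Transform a stratum exposure table under a restriction scenario
#'
#' Operates on a table with columns `cooking_mean`, `cooking_sd`,
#' `ambient_mean`, `ambient_sd` and (for the smoking-ban and
#' source-proportion logic) `p_shs`; `f_exp` is taken from the table or
#' looked up from `ctx$province` by the `province` column.
#'
#' The outdoor scenarios condition on the 2019 *outdoor* concentration, which
#' is recovered from the stored outdoor-source *exposure* as
#' `ambient_mean / f_exp`. Where it exceeds the target, the ambient exposure
#' mean becomes `target * f_exp` and its SD is scaled by the same ratio
#' (constant coefficient of variation). The smoking ban leaves all
#' concentrations unchanged and zeroes `p_shs`.
#'
#' @param g exposure table (one row per stratum).
#' @param sc a [scenario()] or scenario name.
#' @param ctx optional list with element `province` (columns `province`,
#'   `f_exp`, `p_shs`) used when `g` lacks `f_exp`/`p_shs` columns.
#' @return the transformed table, with a `scenario` column appended.
#' @export
apply_scenario <- function(g, sc, ctx = NULL) {
  sc <- as_scenario(sc)
  out <- g
  if (!"f_exp" %in% names(out)) {
    if (is.null(ctx$province) || !"province" %in% names(out))
      stop("lookup error: f_exp not available (supply an f_exp column or ctx$province)",
           call. = FALSE)
    idx <- match(out$province, ctx$province$province)
    if (any(is.na(idx)))
      stop(sprintf("lookup error: no f_exp for province(s): %s",
                   paste(unique(out$province[is.na(idx)]), collapse = ", ")),
           call. = FALSE)
    out$f_exp <- ctx$province$f_exp[idx]
    if (!"p_shs" %in% names(out)) out$p_shs <- ctx$province$p_shs[idx]
  }
  if (sc$name == "SB") {
    if ("p_shs" %in% names(out)) out$p_shs <- 0
  } else if (sc$name == "EC") {
    out$cooking_mean <- 0
    if ("cooking_sd" %in% names(out)) out$cooking_sd <- 0
  } else if (sc$name %in% names(OUTDOOR_TARGETS)) {
    outdoor_2019 <- out$ambient_mean / out$f_exp
    ratio <- ifelse(outdoor_2019 > sc$outdoor_target,
                    sc$outdoor_target * out$f_exp / out$ambient_mean, 1)
    out$ambient_mean <- out$ambient_mean * ratio
    if ("ambient_sd" %in% names(out)) out$ambient_sd <- out$ambient_sd * ratio
  }
  out$scenario <- sc$name
  out
}

#' Per-stratum exposure table across a set of scenarios
#'
#' @param g baseline exposure table (see [apply_scenario()]).
#' @param scenarios character vector of scenario names.
#' @param ctx context list with `province` table.
#' @return row-bound table keyed by stratum and `scenario`.
#' @export
scenario_exposure_table <- function(g, scenarios = SCENARIO_NAMES, ctx = NULL) {
  do.call(rbind, lapply(scenarios, function(s) apply_scenario(g, s, ctx)))
}
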