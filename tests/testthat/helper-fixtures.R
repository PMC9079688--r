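# Shared fixtures: a two-group zero-variance input bundle whose burden can be
# computed by hand, plus small synthetic configurations for property tests.

# One city, one age band, two sexes; all SDs zero so every exposure draw
# equals its mean and the Monte Carlo collapses onto the closed form.
tiny_inputs <- function() {
  exposure <- expand.grid(sex = c("boy", "girl"),
                          household = c("non-smoking", "smoking"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  exposure$city <- "X1"
  exposure$province <- "PA"
  exposure$age_group <- "3-6"
  boy <- exposure$sex == "boy"
  exposure$cooking_mean <- ifelse(boy, 10, 8)
  exposure$ambient_mean <- ifelse(boy, 30, 25)
  exposure$cooking_sd <- 0
  exposure$ambient_sd <- 0
  exposure$indoor_smoking_mean <- ifelse(exposure$household == "smoking",
                                         ifelse(boy, 15, 12), NA_real_)
  exposure$indoor_smoking_sd <- ifelse(exposure$household == "smoking", 0, NA_real_)
  population <- data.frame(
    city = "X1", province = "PA", age_group = "3-6",
    sex = c("boy", "girl"), N = c(100000, 90000), IR = c(0.004, 0.003),
    gdp_daily = 300, stringsAsFactors = FALSE
  )
  province <- data.frame(province = "PA", f_exp = 0.7, p_shs = 0.4,
                         stringsAsFactors = FALSE)
  cost <- data.frame(age_group = "3-6", sex = c("boy", "girl"),
                     cost_direct = c(1000, 1200), treatment_days = c(3, 2),
                     stringsAsFactors = FALSE)
  list(exposure = exposure, population = population, province = province,
       cost = cost, gdp = data.frame(city = "X1", gdp_daily = 300,
                                     stringsAsFactors = FALSE))
}

# Closed-form burden for tiny_inputs(), written out with plain arithmetic
# (the `^` operator, explicit sums) so it is independent of the package's
# log-space implementation.
tiny_oracle <- function(rr0 = 1.26, lc = 2, dc0 = 10, conv = 0.487) {
  f <- 0.7; p <- 0.4
  cook <- c(10, 8); amb <- c(30, 25); shs <- c(15, 12) - cook
  n <- c(100000, 90000); ir <- c(0.004, 0.003)
  costd <- c(1000, 1200); days <- c(3, 2); gdp <- 300

  rr_at <- function(cexp) {
    ceq <- cexp / f * conv
    ifelse(ceq <= lc, 1, rr0^((ceq - lc) / dc0))
  }
  rr_ns <- rr_at(cook + amb)
  rr_s <- rr_at(cook + shs + amb)
  rrbar <- (1 - p) * rr_ns + p * rr_s
  paf_g <- (rrbar - 1) / rrbar
  denom <- cook + amb + p * shs
  ps <- list(ambient = amb / denom, cooking = cook / denom,
             shs = p * shs / denom)
  w <- ir * n
  unit_cost <- costd + gdp * days

  pif_of <- function(rrbar_po) (rrbar - rrbar_po) / rrbar
  scenarios <- list(
    SB = rr_ns,
    EC = (1 - p) * rr_at(amb) + p * rr_at(shs + amb),
    IT1 = {
      r <- ifelse(amb / f > 40, 40 * f / amb, 1)
      (1 - p) * rr_at(cook + amb * r) + p * rr_at(cook + shs + amb * r)
    },
    IT2 = {
      r <- ifelse(amb / f > 30, 30 * f / amb, 1)
      (1 - p) * rr_at(cook + amb * r) + p * rr_at(cook + shs + amb * r)
    },
    IT3 = {
      r <- ifelse(amb / f > 20, 20 * f / amb, 1)
      (1 - p) * rr_at(cook + amb * r) + p * rr_at(cook + shs + amb * r)
    },
    AQG = {
      r <- ifelse(amb / f > 10, 10 * f / amb, 1)
      (1 - p) * rr_at(cook + amb * r) + p * rr_at(cook + shs + amb * r)
    }
  )
  ran <- lapply(scenarios, function(rrp) sum(pif_of(rrp) * w))
  ran_cost <- lapply(scenarios, function(rrp) sum(pif_of(rrp) * w * unit_cost))

  list(
    paf = paf_g, rrbar = rrbar,
    an = list(ambient = sum(ps$ambient * paf_g * w),
              cooking = sum(ps$cooking * paf_g * w),
              SHS = sum(ps$shs * paf_g * w),
              total = sum(paf_g * w)),
    an_cost = list(ambient = sum(ps$ambient * paf_g * w * unit_cost),
                   cooking = sum(ps$cooking * paf_g * w * unit_cost),
                   SHS = sum(ps$shs * paf_g * w * unit_cost),
                   total = sum(paf_g * w * unit_cost)),
    ran = ran, ran_cost = ran_cost
  )
}

# Degenerate uncertainty: point C-R parameters.
point_crf <- function() {
  cr_function(rr0 = 1.26, rr0_ui = c(1.26, 1.26), lc = 2, lc_range = c(2, 2))
}

# Degenerate outer stage: no parameter uncertainty at all.
degenerate_mc <- function(n_variability = 20, n_uncertainty = 15, seed = 11) {
  mc_config(n_variability = n_variability, n_uncertainty = n_uncertainty,
            seed = seed, cv_incidence = 0, cv_cost = 0, cv_days = 0)
}

small_config <- function(n_cities = 6L, seed = 4242L, ...) {
  synthetic_config(n_cities = n_cities, n_provinces = min(3L, n_cities),
                   population_total = 1e6, seed = seed, ...)
}

national_value <- function(res, kind, label) {
  nat <- res$national
  nat$mean[nat$kind == kind & nat$label == label]
}
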