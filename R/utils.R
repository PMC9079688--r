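# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Lognormal (meanlog, sdlog) matched to an arithmetic mean and SD.
# mean == 0 collapses to a point mass at 0; sd == 0 to a point mass at mean.
lnorm_params <- function(mean, sd) {
  stopifnot(all(mean >= 0), all(sd >= 0))
  sigma2 <- ifelse(mean > 0, log1p((sd / pmax(mean, .Machine$double.xmin))^2), 0)
  mu <- ifelse(mean > 0, log(pmax(mean, .Machine$double.xmin)) - sigma2 / 2, -Inf)
  list(meanlog = mu, sdlog = sqrt(sigma2))
}

# Map a matrix of standard-normal draws z (one row per stratum) to draws from
# the configured intra-population variability family, row-wise matched to
# (mean, sd). Lognormal is the default (positive, right-skewed); the
# truncated-normal alternative reuses the same z through the inverse CDF so
# common random numbers are preserved across scenarios.
draw_variability <- function(mean, sd, z, family = c("lognormal", "truncnorm")) {
  family <- match.arg(family)
  if (family == "lognormal") {
    p <- lnorm_params(mean, sd)
    out <- exp(p$meanlog + p$sdlog * z)
  } else {
    out <- matrix(0, nrow(z), ncol(z))
    plo <- pnorm(ifelse(sd > 0, -mean / sd, -Inf))
    u <- pnorm(z)
    for (i in seq_len(nrow(z))) {
      if (sd[i] > 0) {
        out[i, ] <- mean[i] + sd[i] * qnorm(plo[i] + u[i, ] * (1 - plo[i]))
      } else {
        out[i, ] <- mean[i]
      }
    }
  }
  out
}

# Triangular(min, mode, max) sampler via inverse CDF; degenerate when min==max.
rtri <- function(n, min, mode, max) {
  stopifnot(min <= mode, mode <= max)
  if (min == max) return(rep(min, n))
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

# Multiplicative uncertainty draws: Normal(1, cv) censored at 0. With the CVs
# used here P(<0) is negligible (< 1e-6), so censoring does not shift the mean.
runc_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  pmax(0, rnorm(n, mean = 1, sd = cv))
}

# 95% uncertainty interval: 2.5th and 97.5th percentile, linear interpolation
# between order statistics (quantile type 7), so UIs are bit-reproducible.
ui_quantiles <- function(x) {
  quantile(x, probs = c(0.025, 0.975), names = FALSE, type = 7)
}

summarise_draws <- function(x) {
  q <- ui_quantiles(x)
  c(mean = mean(x), ui_low = q[1], ui_high = q[2])
}

check_range <- function(x, name, lo = -Inf, hi = Inf,
                        lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.finite(x) |
    (if (lo_open) x <= lo else x < lo) |
    (if (hi_open) x >= hi else x > hi)
  if (any(bad)) {
    stop(sprintf("`%s` must lie in %s%s, %s%s (got %s)", name,
                 if (lo_open) "(" else "[", format(lo),
                 format(hi), if (hi_open) ")" else "]",
                 paste(format(x[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
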