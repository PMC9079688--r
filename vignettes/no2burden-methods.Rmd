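---
title: "Attributing pediatric asthma burden to source-specific NO2 exposure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing pediatric asthma burden to source-specific NO2 exposure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(no2burden)
```

## The problem

Nitrogen dioxide is the air pollutant with the most consistent
epidemiological link to new-onset asthma in children. In dense urban
settings it comes from three places that matter for policy: outdoor air
(mostly traffic), gas combustion during cooking, and tobacco combustion in
smoking households. `no2burden` implements a comparative-risk-assessment
pipeline that takes stratum-level exposure concentrations from each source
(per city, age band, sex, and smoking/non-smoking household), attributes
new asthma cases and their cost of illness to each source, and projects how
much of that burden specific restrictions would remove: a smoking ban (SB),
switching gas stoves to electric (EC), and bringing outdoor air down to the
WHO interim targets or the 2021 air quality guideline (IT1/IT2/IT3 = 40/30/20,
AQG = 10 µg/m³ annual NO2).

## Exposure model

For a stratum $g$ and household type, total exposure is the sum of
source-specific exposure concentrations,

$$C_{exp} = C_{cooking} + C_{ambient} \; (+\, C_{SHS} \text{ in smoking households}),$$

where the second-hand-smoke component is derived by subtraction from the
smoking households' total indoor-source exposure,
$C_{SHS} = C_{indoor,smoking} - C_{cooking}$. Negative differences, which
can arise from measurement noise in real tables, are physically meaningless
and are clamped to zero with a warning.

Source contribution proportions share one denominator that mixes household
types through $P_{SHS}$, the proportion of the population exposed to
second-hand smoke:

$$PS_{ambient} = \frac{\bar C_{ambient}}{\bar C_{cooking} + \bar C_{ambient} + P_{SHS}\bar C_{SHS}},$$

and analogously for cooking and SHS, so the three shares always sum to 1.

The exposure factor $f_{exp} \in (0, 1]$ (per province) converts between
ambient concentration and the exposure it produces, absorbing building
ventilation, indoor surface removal, time-activity and respiration
differences. The outdoor scenarios condition on the 2019 *outdoor*
concentration, recovered from the stored outdoor-source *exposure* as
$C_{ambient}/f_{exp}$; where it exceeds the target, the ambient exposure
becomes $\mathrm{Target} \times f_{exp}$. Exposure SDs are scaled by the
same ratio (constant coefficient of variation) — the choice is ours; scaling
preserves relative within-population variability, and keeping the SD fixed
instead would let a scenario *increase* relative spread while cutting the
mean. The smoking ban is represented as a context override ($P_{SHS} = 0$)
rather than a concentration edit, matching how $P_{SHS}$ parameterizes the
mixture; $P_{SHS}$ is stored per province and applied uniformly to all
strata within it (a per-group override hook exists in the input schema by
supplying group-level values).

## Concentration-response and burden

Risk follows a piecewise log-linear concentration-response function with a
low-concentration threshold $LC$ below which no excess risk is assumed:

$$RR = \begin{cases} 1 & C \le LC \\ RR_0^{(C - LC)/\Delta C_0} & C > LC \end{cases}$$

with central $RR_0 = 1.26$ (95% UI 1.10–1.37) per $\Delta C_0 = 10$ ppb and
$LC = 2$ ppb (range 0–5). Because the meta-analytic risk function is
defined on the ambient scale, total exposure is first converted to the
equivalent ambient concentration $C_{exp}/f_{exp}$ and then to ppb with
1 µg/m³ = 0.487 ppb (the standard NO2 volume-mixing conversion; the factor
is a `cr_function()` parameter). The threshold comparison is made on this
equivalent ambient ppb scale, where $LC$ is defined. Exponentiation is done
in log space, $\exp(k \ln RR_0)$.

Average risks per household type are mixed by $P_{SHS}$,

$$\overline{RR}_g = (1 - P_{SHS})\,\overline{RR}_{g,ns} + P_{SHS}\,\overline{RR}_{g,s},$$

and converted to the population attributable fraction
$PAF_g = (\overline{RR}_g - 1)/\overline{RR}_g$ and, for a counterfactual
scenario, the potential impact fraction
$PIF_g = (\overline{RR}_g - \overline{RR}'_g)/\overline{RR}_g$. Attributable
cases by source and avoided cases by scenario aggregate over strata as

$$AN_s = \sum_g PS_{s,g}\, PAF_g\, IR_g\, N_g, \qquad
  RAN = \sum_g PIF_g\, IR_g\, N_g,$$

with $IR_g$ the incidence (per person-year) and $N_g$ the child population.
Since the risk function never returns $RR < 1$, a sub-unit average risk can
only come from a user-supplied risk table; `paf()` therefore rejects it by
default and floors it only behind an explicit flag. Costs use the
cost-of-illness model $(Cost_d + GDP_p \times T) \times \text{cases}$,
evaluated at stratum level so age/sex-specific direct costs and city-level
daily GDP bind before aggregation (the aggregate form is ambiguous about
level; stratum-level evaluation is the only order in which both keys can
bind). Values are nominal 2019 RMB with no discounting.

## Two-stage Monte Carlo

Uncertainty is quantified by a nested simulation that separates two very
different things: *variability* — real differences in exposure between
individuals within a stratum — and *uncertainty* — our ignorance about
parameters. Per uncertainty draw (default 1000) of
$(RR_0, LC, IR\text{-multiplier}, Cost_d\text{-multiplier}, T\text{-multiplier})$,
the inner stage averages $RR$ over exposure draws (default 2000) per stratum
and household type to give $\overline{RR}$; everything downstream of
$\overline{RR}$ is deterministic within the draw. Means and 95% uncertainty
intervals (2.5th–97.5th percentile, linear interpolation between order
statistics, `quantile` type 7) are reported across uncertainty draws.

Distribution choices, all configurable:

* **Exposure variability** — lognormal matched to each (mean, SD) pair:
  concentrations are positive and right-skewed, and moment-matching needs no
  rejection step. The family of the original tables is not stated anywhere
  we could follow, so this is a documented assumption; a truncated-normal
  alternative is a configuration switch.
* **$RR_0$** — lognormal with location $\ln 1.26$ and scale
  $(\ln 1.37 - \ln 1.10)/(2 \times 1.96)$: respects positivity and the
  asymmetric published interval.
* **$LC$** — triangular(0, 2, 5) ppb: keeps the stated central value as the
  mode inside the stated range. A uniform(0, 5) option exists but its mean
  (2.5) differs from the central 2 ppb, so it is not the default.
* **Incidence, direct cost, treatment days** — independent multiplicative
  Normal(1, cv) factors censored at zero (defaults cv = 0.1, 0.2, 0.2; with
  these CVs the censoring mass is negligible). The LC draw is made once per
  uncertainty iteration and held fixed across the variability average.

Two implementation decisions matter for both speed and statistics. First,
variability draws are generated **once per run** (per stratum, household
type and source) and reused across uncertainty iterations; the outer stage
only re-draws parameters. Second, the same underlying standard-normal draws
are used for the baseline and every scenario (common random numbers), so a
scenario contrast like $PIF$ compares the same simulated individuals under
two exposures instead of two independent noisy estimates. This is also what
makes per-draw scenario monotonicity (IT1 ≤ IT2 ≤ IT3 ≤ AQG) hold exactly
rather than only in expectation. The inner average is computed by a small
compiled kernel that streams over strata; memory stays proportional to
strata × max(draw counts), never strata × variability × uncertainty.

The robustness check repeats the full two-stage simulation (default 250
times) with distinct sub-seeds and reports the maximum relative deviation of
the headline estimate from the grand mean; the "error" metric of a repeated
simulation check is not standardized, so the spread (SD of the relative
deviations) is reported alongside the maximum.

## The synthetic-data generator

The real exposure, population, incidence, exposure-factor and cost tables
of the motivating study are not redistributable, so the package ships a
seeded generator that emulates their *schema and statistical structure*:
330 cities in 31 provinces; city-level outdoor-source exposure means
uniform on 10–40 µg/m³; a cooking share of cooking+ambient exposure of
about 0.25 on average, increasing with a latitude covariate (the
north-high indoor-share gradient driven by colder-climate ventilation
behaviour); a strictly positive second-hand-smoke increment (0.5–2.5
µg/m³) added to the cooking mean of smoking households; within-stratum
CV of 0.4 on all concentrations; heavy-tailed (lognormal) city sizes
normalized to 170 million urban children, so a few municipalities dominate
the burden as they do in reality; incidence highest in the youngest band
and declining with age, higher in boys (17 down to 5 per 1000 person-years
in boys, 78% of that in girls); provincial exposure factors uniform on
0.55–0.85 and second-hand-smoke exposure proportions on 0.30–0.60; direct
costs 900–1500 RMB, treatment 2–6 days, daily per-capita GDP 120–550 RMB.
These values were fixed once, as plausible urban-China-2019 magnitudes,
before any downstream result was inspected, and they are deliberately *not*
calibrated to reproduce published national totals — the package's tests
check structure (shares, gradients, monotonicity, conservation), not
headline numbers.

What the generator does **not** emulate: spatial correlation between
neighbouring cities, correlation between city size and GDP or between
ambient levels and latitude, age/sex-specific variation in $P_{SHS}$, and
any real geography. Tests passing on synthetic bundles therefore validate
the pipeline's arithmetic and invariances, not the realism of any specific
city's estimate.

## Numerical choices and degenerate inputs

* Lognormal moment matching: $\sigma^2 = \log(1 + (sd/m)^2)$,
  $\mu = \log m - \sigma^2/2$; a zero mean is a point mass at zero and a
  zero SD a point mass at the mean, so zero-variance fixtures collapse the
  whole Monte Carlo onto the closed form (used by the oracle tests).
* All draws happen in one seeded block in a fixed documented order, so
  results are bit-reproducible for a given seed and independent of when the
  caller last touched the RNG.
* The derived SHS standard deviation inherits the coefficient of variation
  of the smoking-household indoor concentration; the SD of a difference is
  not identifiable from the published (mean, SD) pairs alone.
* Source proportions use the non-smoking household's cooking and ambient
  means as the population means entering the shared denominator.
* An all-zero exposure row is a degenerate input for the source proportions
  (zero denominator) and raises an error rather than returning NaN.
* Scenario uncertainty intervals are reported as computed; they are not
  truncated at zero even when a lower bound is slightly negative under
  sampling noise of the outer stage.

## Problem sizes

Default draw counts are 2000 (variability) × 1000 (uncertainty) with 250
robustness repeats. The package's reference robustness computation — also
what `scripts/acceptance.R` runs — uses a 50-city fixture at 500 × 500
draws and the full 250 repeats. At these sizes the Monte Carlo standard
error of one run's headline estimate is about 1%, so the repeated-run
maximum deviation is expected to sit well below the 5% robustness bound
while a full repeat set stays a desk-scale computation.
The examples and unit tests use 3–6-city bundles and tens of draws, which
is enough for every structural property they assert.

## Known limitations

* The concentration-response function is log-linear with a hard threshold;
  no spline or sublinear alternatives are provided.
* Applying an ambient-derived risk coefficient to indoor-source exposure
  assumes equal per-ppb toxicity of NO2 regardless of source.
* Wall-mounted gas boilers and other minor indoor NO2 sources are outside
  the exposure schema.
* `P_SHS` defaults to province-level; age/sex-specific smoking exposure
  requires user-supplied group-level values.
* The generator's independence assumptions (see above) make national
  synthetic totals smoother than real data would be.
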