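# Input bundle data dictionary

All tables are plain CSV with a header row. Concentrations are annual means
in µg/m³; the (mean, SD) pairs describe the intra-population variability
distribution of exposure within a stratum.

## exposure.csv — one row per city × age group × sex × household type

| column | type | description |
|---|---|---|
| city | string | unique city label |
| province | string | province the city belongs to |
| latitude | numeric | latitude-like covariate (degrees) |
| age_group | string | one of 0-0.5, 0.5-1, 1-2, 3-6, 7-11, 12-17 (years) |
| sex | string | boy / girl |
| household | string | smoking / non-smoking |
| cooking_mean, cooking_sd | numeric | NO2 exposure from gas cooking |
| ambient_mean, ambient_sd | numeric | NO2 exposure from outdoor sources |
| indoor_smoking_mean, indoor_smoking_sd | numeric | total indoor-source exposure of smoking households; NA for non-smoking rows. The second-hand-smoke concentration is derived as indoor_smoking_mean − cooking_mean. |

## population_incidence.csv — one row per city × age group × sex

| column | type | description |
|---|---|---|
| city, province, age_group, sex | string | stratum key |
| N | integer | number of children in the stratum |
| IR | numeric | asthma incidence, per person-year |
| gdp_daily | numeric | daily per-capita GDP of the city, RMB/day (city-level, repeated across the city's rows) |

## context_province.csv — one row per province

| column | type | description |
|---|---|---|
| province | string | province label |
| f_exp | numeric | exposure factor linking ambient concentration to population exposure, in (0, 1] |
| p_shs | numeric | proportion of the population exposed to second-hand smoke, in [0, 1] |

## context_cost.csv — one row per age group × sex

| column | type | description |
|---|---|---|
| age_group, sex | string | key |
| cost_direct | numeric | direct treatment cost per case, RMB |
| treatment_days | numeric | treatment and hospitalization days per case |

## synthetic_config.json

Sidecar written by `simulate_inputs()`: the full generator configuration,
including the RNG seed, so any bundle can be regenerated exactly.
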