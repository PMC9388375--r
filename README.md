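# cvdproj

Population-level projection of cardiovascular disease (CVD) under blood
pressure intervention scenarios.

Raised systolic blood pressure (SBP) is the leading modifiable risk factor
for death worldwide. `cvdproj` is for epidemiologists and health-policy
modellers who want to ask: *if a country scaled up hypertension treatment
toward an 80-80-80 target (80% of hypertensives aware × 80% of those
treated × 80% of those controlled ⇒ 51% effective coverage) and/or reduced
dietary sodium, how many CVD deaths and cases would be averted by 2050, and
how would life expectancy and premature CVD mortality change?* The package
ships a synthetic country-data generator with the statistical structure of
the real demographic and epidemiological sources, so the entire pipeline
runs and is tested without any external download.

## The model

Four independent four-state Markov models — one per cause: ischemic heart
disease (IHD), hypertensive heart disease (HHD), ischemic stroke,
hemorrhagic stroke — track `well`, `sick`, `dead (cause)` and `dead (other)`
occupancy per sex and 5-year age group (20–24 … 95+). For each annual step

```
sick_t = sick_{t-1} (1 - (CF + BG)) + well_{t-1} IR
dead_t = sick_{t-1} CF
```

with incidence `IR`, case fatality `CF` and background mortality `BG`.
Cause models are reconciled against the all-cause death envelope
(`all-cause deaths = Σ cause deaths + pop × BG`), and the population itself
advances through a cohort-component (Leslie matrix) projection
`P_{t+1} = L (P_t + 0.5 I_t) + 0.5 I_t` with zero net migration and
pandemic-era excess deaths removed post hoc in 2021–2022.

Blood pressure enters through comparative risk weighting. Each sex–age
cell's SBP distribution is normal, with spread recovered from the
CVD-free 5th percentile. With `p_i` the baseline mass in 10-mmHg SBP
category `i` and `RR_i` the category relative risk:

```
α  = Σ p_i RR_i          (standardized risk parameter)
y_i = RR_i / α × y       (category-specific incidence)
y*  = Σ p*_i y_i         (incidence after the distribution shifts to p*)
```

Interventions shift the distribution: sodium reduction moves mass above the
140 mmHg threshold down by 1.12 mmHg per gram of reduced daily intake
(0.58 mmHg below the threshold), applied before the treatment shift, which
relocates the newly controlled fraction of above-threshold mass to the goal
category. Treatment scale-up also lowers case fatality among prevalent
cases (secondary prevention: 20–26% for IHD depending on heart-failure
status, 36%/76% for ischemic/hemorrhagic stroke, 20% for HHD). Scenarios —
business as usual (historical-trend polynomial scale-up), progress (peak
3%/yr, 53% ceiling; 15% sodium cut by 2030) and aspirational (peak 4%/yr,
75% ceiling; 30% sodium cut by 2027, never below 2 g/day) — drive coverage
and sodium trajectories from 2023. Reported summary measures include life
expectancy, the probability of dying of CVD between ages 30 and 80
(`50q30`, from `5qx = 5·5Mx / (1 + 2.5·5Mx)`), target-achievement years,
and a decomposition of case growth into population growth, aging, and
age-specific rate change.

## Worked example

```r
library(cvdproj)

cfg     <- generator_config(seed = 42, n_countries = 1)
country <- generate_country(cfg, 0)
country
#> <country_inputs> SYN000 (LIC): 1.1M adults, sodium 4.2 g/day, control 19% (2019)

bau  <- run_projection(country, "bau")
prog <- run_projection(country, "progress")
glance(prog)
#> # A tibble: 1 × 8
#>   country_id scenario interventions total_cvd_deaths total_new_cases le_20_final cvd_50q30_final target_year
#>   SYN000     progress both                    70227.         104175.        60.9           0.139        2039

sum(bau$annual$cvd_deaths) - sum(prog$annual$cvd_deaths)
#> [1] 10214
```

Read: this synthetic low-income country of 1.1M adults starts at 19%
hypertension control. Under the progress scenario it reaches the 80-80-80
target (51.2% effective coverage) in 2039, and about 10,200 CVD deaths are
averted over 2020–2050 relative to business as usual; CVD-specific 50q30
falls from 0.167 to 0.139 by 2050 and remaining life expectancy at 20 gains
about 0.9 years. `tidy()` returns the annual series,
`autoplot()`/`plot_cohort_health()`/`plot_decomposition()` draw the standard
views, and `run_world()` + `export_tables()` handle multi-country,
multi-scenario runs with income-group aggregation.

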