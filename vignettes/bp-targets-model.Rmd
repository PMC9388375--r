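---
title: "Methods: projecting cardiovascular disease under blood pressure scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting cardiovascular disease under blood pressure scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdproj)
```

`cvdproj` couples four-state Markov disease models for the four
blood-pressure-linked cardiovascular causes (IHD, HHD, ischemic and
hemorrhagic stroke) to a cohort-component demographic projection, and
converts shifts of the population systolic-blood-pressure (SBP)
distribution — from dietary sodium reduction and hypertension-treatment
scale-up — into changes in disease incidence and case fatality. This
vignette records the model's assumptions, its tunable parameters, the
design decisions we made where the design was genuinely open, and what the
synthetic data generator does and does not emulate.

## State-transition disease models

Each cause is modelled independently per sex and 5-year age group with
states *well*, *sick*, *dead (cause)* and *dead (other)*. One annual step
updates the sick pool as
`sick_t = sick_{t-1}(1 - (CF + BG)) + well_{t-1} IR` and cause deaths as
`sick_{t-1} CF`. Competing risks are additive within a step, which is
adequate for annual probabilities well below 1 but is a literal modelling
choice, not an exponential-hazards approximation.

Two readings of "background" mortality coexist in this model family and we
implement both deliberately:

- inside each cause model, the sick and well pools face death from **every
  non-c cause**, so `bg_c = all-cause rate − cause-c rate`;
- in the envelope reconciliation, all-cause deaths are
  `Σ cause deaths + pop × BG` with `BG` excluding **all four** modelled
  causes, so modelled cause deaths are never double-counted in the
  envelope.

Using the all-but-four rate inside the cause models instead makes each
cohort's denominator shrink faster than its sick pool and inflates old-age
prevalence without bound; the two-reading scheme keeps the single-cause
dynamics and the envelope mutually consistent.

Transition probabilities are estimated by algebraically inverting the state
equations against an observed window (at least six years) of
cause-specific prevalence and mortality: `CF_t = mortality_t /
prevalence_{t-1}`, with its trend taken as the mean annual log rate of
change; incidence is solved per year from consecutive prevalences and held
constant thereafter, with all future incidence change flowing exclusively
through the blood-pressure mechanism. Case fatality and background
mortality continue their historical log-linear trends over the projection,
clipped to `[0, 1]`.

Calibration multiplies incidence and case fatality by per-cause factors
chosen to minimise `w · RMSE(mortality) + (1 − w) · RMSE(prevalence)` over
the observed window. The weight defaults to `w = 0.75`: mortality data are
generally more reliable than prevalence data, so they carry more weight;
the exact value is exposed as a parameter (`weight_mort`, constrained to
(0.5, 1)). The optimizer is Nelder–Mead on the log factors (relative
tolerance 1e-6, at most 500 iterations) — a derivative-free simplex is
plenty for a smooth 2-parameter problem and avoids gradient plumbing.

## Demography

The population advances through a Leslie matrix,
`P_{t+1} = L(P_t + 0.5 I_t) + 0.5 I_t`, with net migration `I_t` fixed at
zero. Age resolution is 5-year groups with a 1-year time step: each year a
fifth of a group's survivors moves up one group
(`build_leslie(..., aging_fraction = 0.2)`), the open 95+ interval
accumulates, and survival is the endogenous `1 − all-cause deaths / pop` of
the disease-plus-envelope step. All reported outputs are 5-year-grouped, so
finer internal age resolution would change nothing reported while tripling
the state space; a shape-preserving monotone cubic (`monoH.FC`) is
available in `smooth_rates()` for single-year interpolation of
quinquennial rates, reproducing knots to 1e-9 and clamping at zero.

Fertility is held constant and acts as a stylized entry process into the
youngest modelled group (20–24): new entrants cannot influence CVD outcomes
for two decades, so their exact age path is immaterial to the reported
horizon. Pandemic-era excess deaths are removed post hoc in 2021–2022,
distributed over cells proportionally to the all-cause death pattern, never
driving a cell negative (any deficit is redistributed with a warning).
Population conservation — `pop_{t+1} = pop_t − deaths + births − excess` —
holds to numerical precision and is asserted in the tests.

## Blood pressure and risk weighting

Within each sex–age cell the SBP distribution is normal with the observed
mean; its standard deviation is recovered from the 5th percentile of
CVD-free, untreated populations as `sd = (mean − p5)/qnorm(0.95)`, which is
more stable than inferring spread from a raised-BP prevalence. The density
is discretized into point masses on a 0.5-mmHg grid so that intervention
shifts are exact translations (no re-binning leakage); category masses are
then aggregated onto 10-mmHg bins from below 115 mmHg (the reference bin,
containing the 110–115 mmHg theoretical minimum-risk level) to 185+ mmHg.
The bin grid is a parameter — sources rarely print their category
definitions, so it must be configurable.

Relative risks per category follow a log-linear gradient per 10 mmHg per
cause, shipped as a versioned YAML file
(`inst/extdata/risk_parameters.yaml`). These gradients are declared
stand-ins: the trial meta-analyses behind such models are not printed as
category tables, so the defaults encode the canonical dose–response shape
(risk roughly doubling per 20 mmHg for IHD, steeper for stroke and HHD)
and are data, not code.

The identities `α = Σ p_i RR_i`, `y_i = RR_i/α · y`, `y* = Σ p*_i y_i`
guarantee that the baseline-weighted category incidence reproduces the
observed average, and that a leftward mass shift can only lower incidence.
Incidence under full control remains strictly positive — interventions
remove only the risk attributable to SBP above the distribution's lower
categories, leaving residual risk from other factors untouched.

Order of operations is fixed: within a year the sodium shift is applied
**before** the treatment shift. Distributions evolve: each year's shifts
apply to the previous year's post-shift distribution (incremental sodium
dose, newly controlled fraction of currently-uncontrolled mass), rather
than rebuilding from exogenous means — an interpretation we chose because
it keeps the distribution consistent with the coverage state already
granted to the population.

Two treatment parameters deserve note:

- **Goal placement.** Controlled individuals are relocated uniformly
  within the 10-mmHg category containing 130 mmHg (`goal = 130`,
  `[125, 135)` on the default grid). A guideline goal of "at or below
  140 mmHg" cannot be represented by relocating mass *to* 140 mmHg — that
  is the hypertension threshold itself, and mass placed in a straddling
  bin would remain partly uncontrolled. Treated-to-target patients
  typically settle near 130 mmHg, and the uniform-within-bin rule is the
  simplest mass-conserving representation of "at target".
- **Secondary prevention.** Added treatment coverage multiplies case
  fatality by `1 − Δcoverage × r_cause` with `r_IHD = 0.3×0.20 + 0.7×0.26`
  (heart-failure blend), `r = 0.36` (ischemic stroke), `0.76` (hemorrhagic
  stroke), `0.20` (HHD), where `Δcoverage` is coverage gained relative to
  the pre-intervention (2022) level.

## Scenarios

Hypertension-control scale-up follows a second-order polynomial in current
coverage, `increment(c) = a·c·(ceiling − c)`, normalized so the peak
(at half the ceiling) equals the scenario's peak rate: progress peaks at 3
percentage points/year with a 53% ceiling, aspirational at 4 points/year
with a 75% ceiling (below the ~5%/yr pace of global antiretroviral
scale-up). The aspirational increment is defined as the pointwise max of
its own polynomial and the progress polynomial: the wider aspirational
parabola alone would dip below progress at very low coverage, and a
scenario labelled stronger must dominate pointwise; the max changes neither
the printed peak nor the ceiling. Business as usual fits a nine-member
family of these polynomials (ceilings evenly spaced 25–65%, shared peak
increment 1.5 points/year — a package parameter standing in for
unpublished historical-median coefficients) to the most recent decade of a
country's control history by least squares, ties broken toward the lower
ceiling. No coverage advances during 2019–2022. At the country level a
scenario trajectory is floored at the fitted business-as-usual trajectory,
so a country whose historical path outruns the scenario ceiling keeps its
own path.

Sodium: business as usual holds intake flat; progress reduces it 15% by
2030, aspirational 30% by 2027 (both relative to 2023, linear decline
between endpoints — sources state endpoints only — and floored at
2 g/day). The 80-80-80 target is considered achieved in the first year
effective coverage reaches 0.8³ = 0.512.

## Summary measures

`5qx = 5·5Mx/(1 + 2.5·5Mx)` converts rates to probabilities (2.5 average
person-years lived by those dying in a 5-year group); the formula exceeds 1
for rates above 0.4/year and is clipped with a warning. CVD-specific 50q30
is `1 − Π(1 − 5qx)` over ages 30–79. Abridged life tables use the same
`a_x = 2.5` and `L = l/M` in the open interval. Because the synthetic
inputs cover adults only, the pipeline reports remaining life expectancy at
20 and at 40 rather than at birth. The growth/aging/rates decomposition
applies the stepwise counterfactuals (base structure and rates at projected
total population; projected structure at base rates; remainder) and is
additive to machine precision by construction.

## What the synthetic generator emulates — and what it does not

`generate_country()` draws internally consistent inputs: an exponential
adult age pyramid; Gompertz all-cause mortality with a recent 0.5–2%/yr
decline; cause-specific mortality as age-increasing shares of all-cause
mortality; prevalence derived as mortality over a plausible case-fatality
schedule (so the implied CF is exactly recoverable and bounded);
age-rising mean SBP (110–150 mmHg) and CVD-free 5th percentiles
(96–118 mmHg); sodium 2.5–5.5 g/day; a control history generated from the
same polynomial family the fitting step searches; and excess deaths at 5%
of baseline deaths in each of 2021–2022. Every draw is deterministic in
the configuration seed.

It does **not** emulate: between-country correlation, measurement error
and revision structure of real sources, non-CVD cause detail, sub-national
heterogeneity, migration, or realistic country magnitudes. Passing tests
therefore demonstrate internal correctness of the mechanics —
conservation, identities, dominance, recoverability — not predictive
validity for any real country. The generator's noise models are artifact
choices, flagged as such in the configuration defaults.

One known transient follows from this design: synthetic initial
prevalences are not at the joint demographic–epidemiological fixed point,
so age-standardized mortality drifts for roughly the first two decades of
a no-trend projection before flattening; the constancy test asserts
steadiness over the final decade.

## Numerical choices and problem sizes

Discretization uses a 0.5-mmHg SBP grid (tail probabilities accurate to a
few percent, mass conserved to 1e-9); optimizer tolerance 1e-6; envelope
and conservation assertions at 1e-6–1e-9 relative; degenerate inputs
(zero populations, flat-zero control histories, rates above 0.4/yr) are
handled by explicit guards with warnings rather than silent propagation.
The test suite and examples run worlds of 2–5 synthetic countries of
10⁶–10⁷·⁵ adults over 2019–2050 — sizes chosen because every mechanism
(aging, envelope reconciliation, distribution shifts, calibration) is
exercised identically at any scale, and larger worlds only multiply
identical per-country work.

## Limitations

Only SBP and sodium are modelled as risk factors; smoking, BMI, lipids,
diabetes and non-CVD sodium effects are out of scope. The four cause
models share no comorbidity (prevalent cases are case-episodes, so their
sum can exceed the number of distinct sick individuals). Treatment acts
through a single 140 mmHg threshold and one goal category; awareness,
treatment and control are tracked only through their product (effective
coverage). No uncertainty intervals are produced. Per-year intervention
comparisons can show late-horizon mortality displacement (people saved
early die later); cumulative comparisons are the meaningful ones and are
what the tests assert.
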