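#' Configuration for the synthetic country generator
#'
#' Controls the ranges and noise scales used by [generate_country()]. The
#' defaults aim for qualitatively realistic adult epidemiology — Gompertz
#' all-cause mortality, CVD prevalence and mean SBP rising with age — without
#' claiming country-level realism. All variance parameters are artifact
#' choices: the statistical structure, not the values, of real demographic
#' and epidemiological sources.
#'
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @param n_countries Number of countries the world holds.
#' @param pop_range Log10 range of total adult population.
#' @param mort_base_range Range of the all-cause mortality level at age 20.
#' @param gompertz_slope_range Range of the exponential age slope of
#'   mortality.
#' @param sbp_base_range Range of mean SBP at age 20 (mmHg).
#' @param sodium_range Range of population mean sodium intake (g/day).
#' @param control_noise_sd Noise s.d. of the generated control history.
#' @param excess_death_fraction Excess deaths in each of 2021 and 2022 as a
#'   fraction of baseline annual deaths.
#' @param history_years Years of epidemiological history to emit.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_countries = 5L,
                             pop_range = c(6, 7.5),
                             mort_base_range = c(4e-4, 1.2e-3),
                             gompertz_slope_range = c(0.070, 0.080),
                             sbp_base_range = c(112, 118),
                             sodium_range = c(2.5, 5.5),
                             control_noise_sd = 0.004,
                             excess_death_fraction = 0.05,
                             history_years = 2014:2019) {
  cfg <- list(seed = as.integer(seed), n_countries = as.integer(n_countries),
              pop_range = pop_range, mort_base_range = mort_base_range,
              gompertz_slope_range = gompertz_slope_range,
              sbp_base_range = sbp_base_range, sodium_range = sodium_range,
              control_noise_sd = control_noise_sd,
              excess_death_fraction = excess_death_fraction,
              history_years = history_years)
  for (nm in c("pop_range", "mort_base_range", "gompertz_slope_range",
               "sbp_base_range", "sodium_range")) {
    if (any(cfg[[nm]] < 0) || diff(cfg[[nm]]) < 0) {
      abort(sprintf("invalid `%s`: ranges must be non-negative and ordered.", nm))
    }
  }
  if (control_noise_sd < 0 || excess_death_fraction < 0) {
    abort("noise scales must be non-negative.")
  }
  if (cfg$n_countries < 1) abort("`n_countries` must be at least 1.")
  structure(cfg, class = "generator_config")
}

income_groups <- function() c("LIC", "LMIC", "UMIC", "HIC")

#' Generate one synthetic country
#'
#' Draws an internally consistent set of country inputs: an adult population
#' pyramid, constant fertility, Gompertz all-cause mortality with a recent
#' declining trend, cause-specific mortality and prevalence series for the
#' four CVD causes (prevalence constructed from mortality via plausible case
#' fatality, guaranteeing CF <= 1 and the cause-sum-below-all-cause
#' envelope), mean SBP and 5th-percentile SBP rising with age, sodium
#' intake, a hypertension-control history following the polynomial scale-up
#' pattern, and pandemic-era excess deaths.
#'
#' @param config A [generator_config()].
#' @param country_index Zero-based country index, below `n_countries`.
#' @return An object of class `country_inputs`.
#' @export
generate_country <- function(config, country_index = 0L) {
  if (!inherits(config, "generator_config")) abort("`config` must be a generator_config.")
  if (country_index < 0 || country_index >= config$n_countries) {
    abort("`country_index` must be in [0, n_countries).")
  }
  set.seed(config$seed * 1000L + as.integer(country_index))
  starts <- age_group_starts()
  mids <- age_group_midpoints()
  n_age <- length(starts)
  income <- income_groups()[(country_index %% 4L) + 1L]

  # population pyramid: exponentially declining with age, steeper in LIC
  rho <- runif(1, 0.02, 0.05) + switch(income, LIC = 0.015, LMIC = 0.008, 0)
  total <- 10^runif(1, config$pop_range[1], config$pop_range[2])
  shares <- exp(-rho * (starts - 20))
  shares <- shares / sum(shares)
  population <- tidyr::expand_grid(sex = model_sexes(),
                                   age_group = age_group_labels()) |>
    dplyr::mutate(age_start = rep(starts, times = 2),
                  count = total * rep(shares, times = 2) / 2)

  # constant fertility: annual entry rates into the adult grid, ages 20-49
  fert_total <- runif(1, 0.08, 0.12)
  fert_shape <- stats::dnorm(starts, mean = 28, sd = 6)
  fert_shape[starts >= 50] <- 0
  fertility <- tibble::tibble(
    age_group = age_group_labels(), age_start = starts,
    rate = fert_total * fert_shape / sum(fert_shape)
  )

  # all-cause mortality: Gompertz in age, male excess, recent decline
  m0 <- runif(1, config$mort_base_range[1], config$mort_base_range[2]) *
    switch(income, LIC = 1.6, LMIC = 1.3, UMIC = 1.1, HIC = 1.0)
  slope <- runif(1, config$gompertz_slope_range[1], config$gompertz_slope_range[2])
  decline <- runif(1, 0.005, 0.02)
  years <- config$history_years
  all_cause_history <- tidyr::expand_grid(year = years, sex = model_sexes(),
                                          age_group = age_group_labels()) |>
    dplyr::mutate(
      age_start = rep(rep(starts, times = 2), times = length(years)),
      rate = pmin(
        m0 * exp(slope * (rep(rep(mids, 2), length(years)) - 20)) *
          ifelse(.data$sex == "male", 1.25, 1) *
          exp(decline * (2019 - .data$year)),
        0.5
      )
    )

  # cause mortality as age-increasing shares of all-cause; prevalence via
  # plausible case fatality so CF = mort/prev stays well inside (0, 1)
  base_share <- c(ihd = 0.18, hhd = 0.035, ischemic_stroke = 0.09,
                  hemorrhagic_stroke = 0.05)
  if (income %in% c("LIC", "LMIC")) {
    base_share["hemorrhagic_stroke"] <- 0.075
    base_share["hhd"] <- 0.05
  }
  tilt <- setNames(runif(4, 0.85, 1.15), names(base_share))
  base_cf <- c(ihd = 0.05, hhd = 0.06, ischemic_stroke = 0.07,
               hemorrhagic_stroke = 0.10)
  cf_decline <- runif(1, 0.005, 0.015)
  mid_lookup <- tibble::tibble(age_group = age_group_labels(), mid = mids)
  epi_history <- tidyr::expand_grid(year = years, sex = model_sexes(),
                                    age_group = age_group_labels(),
                                    cause = cvd_causes()) |>
    dplyr::left_join(all_cause_history,
                     by = c("year", "sex", "age_group")) |>
    dplyr::left_join(mid_lookup, by = "age_group") |>
    dplyr::mutate(
      share = base_share[.data$cause] * tilt[.data$cause] *
        stats::plogis((.data$mid - 50) / 15),
      mortality = .data$share * .data$rate,
      # prevalence = mortality / case fatality keeps the implied CF exactly
      # on the generated schedule; the floor on CF caps prevalence at 30%
      cf = pmax(
        pmin(base_cf[.data$cause] *
               exp(0.028 * pmin(.data$mid - 20, 55)) *
               exp(cf_decline * (2019 - .data$year)), 0.45),
        .data$mortality / 0.3
      ),
      prevalence = .data$mortality / .data$cf
    ) |>
    dplyr::select("year", "sex", "age_group", "age_start", "cause",
                  "prevalence", "mortality")

  # mean SBP and CVD-free 5th percentile, both rising with age
  sbp_base <- runif(1, config$sbp_base_range[1], config$sbp_base_range[2])
  mean_sbp <- tidyr::expand_grid(sex = model_sexes(),
                                 age_group = age_group_labels()) |>
    dplyr::mutate(
      age_start = rep(starts, 2),
      sbp = pmin(sbp_base + 0.35 * (rep(mids, 2) - 20) +
                   ifelse(.data$sex == "male", 3, 0), 150),
      p5 = pmin(96 + 0.28 * (rep(mids, 2) - 20), 118)
    ) |>
    dplyr::mutate(p5 = pmin(.data$p5, .data$sbp - 8))

  sodium <- runif(1, config$sodium_range[1], config$sodium_range[2])

  # control history over the decade to 2019, polynomial scale-up pattern
  peak <- sample(seq(0.25, 0.65, length.out = 9), 1)
  control_history <- tibble::tibble(
    year = 2010:2019,
    control = generate_control_history(
      config, peak = peak, n_years = 10,
      start_level = runif(1, 0.03, min(0.2, peak * 0.8)),
      reseed = FALSE
    )
  )

  deaths_2019 <- population |>
    dplyr::left_join(dplyr::filter(all_cause_history, .data$year == 2019),
                     by = c("sex", "age_group", "age_start")) |>
    dplyr::summarise(d = sum(.data$count * .data$rate)) |>
    dplyr::pull("d")
  excess_deaths <- tibble::tibble(
    year = 2021:2022,
    deaths = config$excess_death_fraction * deaths_2019
  )

  out <- structure(list(
    country_id = sprintf("SYN%03d", country_index),
    income_group = income,
    population = population,
    fertility = fertility,
    all_cause_history = all_cause_history,
    epi_history = epi_history,
    mean_sbp = mean_sbp,
    sodium_intake = sodium,
    control_history = control_history,
    excess_deaths = excess_deaths,
    meta = list(seed = config$seed, country_index = as.integer(country_index),
                schema_version = 1L)
  ), class = "country_inputs")
  validate_country_inputs(out)
}

#' Generate a hypertension-control history
#'
#' Simulates an annual control series from the second-order polynomial
#' increment pattern (fastest improvement at intermediate control), plus
#' optional Gaussian noise. The series never exceeds `peak`, the ceiling of
#' the generating polynomial.
#'
#' @param config A [generator_config()]; supplies the seed and noise scale.
#' @param peak Ceiling of the generating curve, in (0, 1].
#' @param n_years Series length.
#' @param start_level Starting control level; defaults to a tenth of the
#'   peak.
#' @param noise_sd Noise s.d.; defaults to the config's.
#' @param reseed Set the RNG from the config seed (disable when called
#'   within a larger generation step).
#' @return Numeric control series of length `n_years`.
#' @export
generate_control_history <- function(config, peak, n_years = 10,
                                     start_level = NULL, noise_sd = NULL,
                                     reseed = TRUE) {
  if (!is.finite(peak) || peak <= 0 || peak > 1) {
    abort("`peak` must lie in (0, 1].")
  }
  if (reseed) set.seed(config$seed)
  noise_sd <- noise_sd %||% config$control_noise_sd
  start_level <- start_level %||% (peak / 10)
  curve <- scale_up_curve("bau", ceiling = peak)
  series <- numeric(n_years)
  series[1] <- start_level
  for (t in seq_len(n_years - 1)) {
    nxt <- series[t] + curve_increment(curve, series[t])
    if (noise_sd > 0) nxt <- nxt + stats::rnorm(1, 0, noise_sd)
    series[t + 1] <- min(max(nxt, 0), peak)
  }
  series
}

#' Generate a synthetic world
#'
#' @param config A [generator_config()].
#' @return List of [generate_country()] outputs, one per country.
#' @export
generate_world <- function(config) {
  purrr::map(seq_len(config$n_countries) - 1L,
             ~ generate_country(config, .x))
}

#' Validate country inputs
#'
#' Checks the type invariants: non-negative counts and rates, proportions in
#' `[0, 1]`, cause-specific mortality summing below all-cause mortality in
#' every sex-age-year cell, and a control history within `[0, 1]`.
#'
#' @param inputs A `country_inputs` object.
#' @return `inputs`, invisibly-checked (errors on violation).
#' @export
validate_country_inputs <- function(inputs) {
  assert_nonneg(inputs$population$count, "population")
  assert_nonneg(inputs$fertility$rate, "fertility")
  assert_nonneg(inputs$all_cause_history$rate, "all_cause_mortality")
  assert_probability(inputs$epi_history$prevalence, "cause_prevalence")
  assert_nonneg(inputs$epi_history$mortality, "cause_mortality")
  assert_probability(inputs$control_history$control, "control_history")
  assert_nonneg(inputs$excess_deaths$deaths, "excess_deaths")
  envelope <- inputs$epi_history |>
    dplyr::group_by(.data$year, .data$sex, .data$age_group) |>
    dplyr::summarise(cause_sum = sum(.data$mortality), .groups = "drop") |>
    dplyr::left_join(inputs$all_cause_history,
                     by = c("year", "sex", "age_group"))
  if (any(envelope$cause_sum > envelope$rate + 1e-12)) {
    abort("cause-specific mortality exceeds all-cause mortality in some cell.")
  }
  inputs
}

#' @export
print.country_inputs <- function(x, ...) {
  cat(sprintf("<country_inputs> %s (%s): %.1fM adults, sodium %.1f g/day, control %.0f%% (2019)\n",
              x$country_id, x$income_group,
              sum(x$population$count) / 1e6, x$sodium_intake,
              100 * tail(x$control_history$control, 1)))
  invisible(x)
}

#' Write and read country inputs
#'
#' Country inputs are persisted as a directory of headered CSV tables (one
#' per field family) plus a JSON metadata file carrying scalars and the
#' schema version.
#'
#' @param inputs A `country_inputs` object.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_country_inputs()` returns `dir` invisibly;
#'   `read_country_inputs()` returns the reconstructed `country_inputs`.
#' @export
write_country_inputs <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("population", "fertility", "all_cause_history", "epi_history",
              "mean_sbp", "control_history", "excess_deaths")
  for (tb in tables) {
    readr::write_csv(inputs[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  meta <- c(inputs$meta,
            list(country_id = inputs$country_id,
                 income_group = inputs$income_group,
                 sodium_intake = inputs$sodium_intake))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_country_inputs
#' @export
read_country_inputs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  read1 <- function(tb) {
    readr::read_csv(file.path(dir, paste0(tb, ".csv")),
                    show_col_types = FALSE)
  }
  out <- structure(list(
    country_id = meta$country_id,
    income_group = meta$income_group,
    population = read1("population"),
    fertility = read1("fertility"),
    all_cause_history = read1("all_cause_history"),
    epi_history = read1("epi_history"),
    mean_sbp = read1("mean_sbp"),
    sodium_intake = meta$sodium_intake,
    control_history = read1("control_history"),
    excess_deaths = read1("excess_deaths"),
    meta = meta[c("seed", "country_index", "schema_version")]
  ), class = "country_inputs")
  validate_country_inputs(out)
}
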