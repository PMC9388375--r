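#' Run a scenario projection for one country
#'
#' Orchestrates the full yearly cycle from the 2019 baseline to the horizon:
#' estimate (and optionally calibrate) transition probabilities from the
#' country's epidemiological history; build per-cell SBP distributions; then
#' for each year apply the sodium shift before the treatment shift, update
#' incidence through the relative-risk weighting, apply the
#' secondary-prevention case-fatality adjustment, advance the four Markov
#' disease models, reconcile against the all-cause death envelope, advance
#' the population through the cohort-component step, and remove pandemic-era
#' excess deaths in 2021-2022.
#'
#' The scenario acts only through its two intervention channels: with the
#' treatment channel off, coverage follows the business-as-usual curve fit
#' to the country's control history; with the sodium channel off, intake
#' stays at baseline. Disabling both reproduces business as usual exactly.
#'
#' @param inputs A `country_inputs` object.
#' @param scenario `"bau"`, `"progress"` or `"aspirational"`.
#' @param interventions Which channels the scenario applies: `"both"`,
#'   `"sodium"`, `"treatment"` or `"none"`.
#' @param end_year Projection horizon (inclusive).
#' @param base_year Baseline year of the input data.
#' @param intervention_start First year of scenario scale-up.
#' @param calibrate Run the composite-RMSE calibration of transition
#'   probabilities against the input history before projecting.
#' @param weight_mort Mortality weight of the calibration objective.
#' @param effects Parameter list from [default_treatment_effects()].
#' @param breaks SBP category bounds, see [sbp_default_breaks()].
#' @param goal,threshold Treatment goal and hypertension threshold (mmHg).
#' @return An object of class `cvd_projection` with elements `cells`
#'   (per year-sex-age population, deaths, combined prevalence, proportion
#'   with raised blood pressure), `causes` (per year-sex-age-cause deaths,
#'   new cases and prevalent cases), `annual` (country-year totals and
#'   summary measures), `coverage` and `sodium` trajectories, `target_year`,
#'   and a `manifest`.
#' @export
run_projection <- function(inputs,
                           scenario = c("bau", "progress", "aspirational"),
                           interventions = c("both", "sodium", "treatment", "none"),
                           end_year = 2050, base_year = 2019,
                           intervention_start = 2023,
                           calibrate = FALSE, weight_mort = 0.75,
                           effects = default_treatment_effects(),
                           breaks = sbp_default_breaks(),
                           goal = 130, threshold = 140) {
  scenario <- match.arg(scenario)
  interventions <- match.arg(interventions)
  t_start <- Sys.time()
  starts <- age_group_starts()
  n_age <- length(starts)
  causes <- cvd_causes()
  grid <- tidyr::expand_grid(sex = model_sexes(),
                             age_group = age_group_labels()) |>
    dplyr::mutate(age_start = rep(starts, 2))
  n_cell <- nrow(grid)

  # --- transitions from history -------------------------------------------
  # per-cause background mortality: each cause model's sick and well pools
  # face death from every non-c cause, so bg_c = all-cause - cause-c rate;
  # the envelope term below instead uses BG excluding all four causes
  all_cause <- dplyr::select(inputs$all_cause_history, "year", "sex",
                             "age_group", "rate")
  history <- inputs$epi_history |>
    dplyr::select("cause", "sex", "age_group", "year", "prevalence",
                  "mortality") |>
    dplyr::left_join(all_cause, by = c("year", "sex", "age_group")) |>
    dplyr::mutate(bg = pmax(.data$rate - .data$mortality, 1e-8)) |>
    dplyr::select(-"rate")
  bg_env_tbl <- inputs$epi_history |>
    dplyr::group_by(.data$year, .data$sex, .data$age_group) |>
    dplyr::summarise(cause_sum = sum(.data$mortality), .groups = "drop") |>
    dplyr::left_join(all_cause, by = c("year", "sex", "age_group")) |>
    dplyr::mutate(bg = pmax(.data$rate - .data$cause_sum, 1e-8)) |>
    dplyr::select("year", "sex", "age_group", "bg")
  transitions <- estimate_transitions(history)
  calibration <- NULL
  if (calibrate) {
    calibration <- calibrate_transitions(transitions, history,
                                         calib_by = "cause",
                                         weight_mort = weight_mort)
    transitions <- transitions |>
      dplyr::left_join(tibble::as_tibble(calibration)[c("cause", "factor_ir",
                                                        "factor_cf")],
                       by = "cause") |>
      dplyr::mutate(ir = pmin(.data$ir * .data$factor_ir, 1),
                    cf = pmin(.data$cf * .data$factor_cf, 1)) |>
      dplyr::select(-"factor_ir", -"factor_cf")
  }
  trans_of <- function(col) {
    transitions |>
      dplyr::select("cause", "sex", "age_group", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "cause", values_from = dplyr::all_of(col)) |>
      dplyr::right_join(grid, by = c("sex", "age_group")) |>
      dplyr::arrange(match(.data$sex, model_sexes()), .data$age_start)
  }
  IR <- as.matrix(trans_of("ir")[causes])
  CF0 <- as.matrix(trans_of("cf")[causes])
  CFtr <- as.matrix(trans_of("cf_trend")[causes])
  BGc0 <- as.matrix(trans_of("bg")[causes])
  BGctr <- as.matrix(trans_of("bg_trend")[causes])
  bg_env <- bg_env_tbl |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::summarise(bg0 = dplyr::last(.data$bg),
                     trend = mean(diff(log(.data$bg))), .groups = "drop") |>
    dplyr::right_join(grid, by = c("sex", "age_group")) |>
    dplyr::arrange(match(.data$sex, model_sexes()), .data$age_start)
  BG0 <- bg_env$bg0
  BGtr <- bg_env$trend

  # --- initial state -------------------------------------------------------
  pop <- inputs$population |>
    dplyr::right_join(grid, by = c("sex", "age_group", "age_start")) |>
    dplyr::arrange(match(.data$sex, model_sexes()), .data$age_start) |>
    dplyr::pull("count")
  prev0 <- inputs$epi_history |>
    dplyr::filter(.data$year == base_year) |>
    dplyr::select("cause", "sex", "age_group", "prevalence") |>
    tidyr::pivot_wider(names_from = "cause", values_from = "prevalence") |>
    dplyr::right_join(grid, by = c("sex", "age_group")) |>
    dplyr::arrange(match(.data$sex, model_sexes()), .data$age_start)
  sick <- as.matrix(prev0[causes]) * pop
  fert <- inputs$fertility |>
    dplyr::arrange(.data$age_start) |>
    dplyr::pull("rate")

  # --- blood pressure machinery -------------------------------------------
  sbp <- inputs$mean_sbp |>
    dplyr::right_join(grid, by = c("sex", "age_group", "age_start")) |>
    dplyr::arrange(match(.data$sex, model_sexes()), .data$age_start)
  dists <- purrr::map2(sbp$sbp, sbp$p5,
                       ~ build_sbp_distribution(.x, .y, breaks = breaks))
  risk <- default_risk_table(breaks, effects)
  rr_mat <- risk |>
    tidyr::pivot_wider(names_from = "cause", values_from = "rr") |>
    dplyr::arrange(.data$category)
  rr_mat <- as.matrix(rr_mat[causes]) # categories x causes
  p_base <- vapply(dists, function(d) sbp_category_mass(d)$mass,
                   numeric(nrow(rr_mat)))
  alpha_base <- crossprod(p_base, rr_mat) # cells x causes

  # --- scenario trajectories ----------------------------------------------
  treat_on <- interventions %in% c("both", "treatment")
  sodium_on <- interventions %in% c("both", "sodium")
  bau_fit <- fit_bau_curve(inputs$control_history)
  start_level <- tail(inputs$control_history$control, 1)
  coverage <- coverage_trajectory(bau_fit, start_level,
                                  start_year = base_year, end_year = end_year,
                                  intervention_start = intervention_start)
  if (scenario != "bau" && treat_on) {
    # scenario scale-up accelerates relative to the historical path: a
    # country already above the scenario curve keeps its own trajectory
    sc_traj <- coverage_trajectory(scale_up_curve(scenario), start_level,
                                   start_year = base_year,
                                   end_year = end_year,
                                   intervention_start = intervention_start)
    coverage$control <- pmax(coverage$control, sc_traj$control)
  }
  schedule <- sodium_schedule(if (sodium_on) scenario else "bau")
  sodium <- sodium_trajectory(schedule, inputs$sodium_intake,
                              start_year = base_year, end_year = end_year)
  c_ref <- coverage$control[coverage$year == intervention_start - 1]

  # --- annual loop ---------------------------------------------------------
  years <- seq(base_year + 1, end_year)
  cells_out <- vector("list", length(years))
  causes_out <- vector("list", length(years))
  annual_out <- vector("list", length(years))
  excess <- inputs$excess_deaths
  idx_f <- seq_len(n_age)
  idx_m <- n_age + seq_len(n_age)

  for (k in seq_along(years)) {
    yr <- years[k]
    c_now <- coverage$control[coverage$year == yr]
    c_prev <- coverage$control[coverage$year == yr - 1]
    na_now <- sodium$intake[sodium$year == yr]
    na_prev <- sodium$intake[sodium$year == yr - 1]
    d_sodium <- max(na_prev - na_now, 0)
    frac_new <- if (c_now > c_prev && c_prev < 1) {
      (c_now - c_prev) / (1 - c_prev)
    } else 0
    if (d_sodium > 0 || frac_new > 0) {
      dists <- purrr::map(dists, function(d) {
        if (d_sodium > 0) d <- apply_sodium_shift(d, d_sodium, effects, threshold)
        if (frac_new > 0) d <- apply_treatment_shift(d, frac_new, goal, threshold)
        d
      })
    }
    p_now <- vapply(dists, function(d) sbp_category_mass(d)$mass,
                    numeric(nrow(rr_mat)))
    ratio <- crossprod(p_now, rr_mat) / alpha_base # cells x causes
    ir_t <- pmin(IR * ratio, 1)
    elapsed <- yr - base_year
    cf_t <- pmin(CF0 * exp(CFtr * elapsed), 0.95)
    d_cov <- max(c_now - c_ref, 0)
    if (d_cov > 0) {
      for (j in seq_along(causes)) {
        cf_t[, j] <- adjust_case_fatality(cf_t[, j], d_cov, causes[j], effects)
      }
    }
    bgc_t <- pmin(BGc0 * exp(BGctr * elapsed), 0.95)
    bgc_t <- pmin(bgc_t, 1 - cf_t - 1e-9)
    bg_env_t <- pmin(BG0 * exp(BGtr * elapsed), 0.9)

    well <- pmax(pop - sick, 0) # cells x causes
    deaths_c <- sick * cf_t
    new_cases <- well * ir_t
    sick_next <- sick * (1 - (cf_t + bgc_t)) + new_cases
    all_cause <- pmin(rowSums(deaths_c) + pop * bg_env_t, pop)

    survival <- ifelse(pop > 0, 1 - all_cause / pop, 0)
    L_f <- build_leslie(fert * 0.5, survival[idx_f], aging_fraction = 0.2)
    L_m <- build_leslie(fert * 0, survival[idx_m], aging_fraction = 0.2)
    births <- sum(fert * pop[idx_f])
    pop_f <- project_population(pop[idx_f], L_f)
    pop_m <- project_population(pop[idx_m], L_m)
    pop_m[1] <- pop_m[1] + 0.5 * births
    pop_next <- c(pop_f, pop_m)

    A <- build_leslie(rep(0, n_age), rep(1, n_age), aging_fraction = 0.2)
    sick_aged <- rbind(A %*% sick_next[idx_f, , drop = FALSE],
                       A %*% sick_next[idx_m, , drop = FALSE])

    if (!is.null(excess) && yr %in% excess$year) {
      e_tot <- excess$deaths[excess$year == yr]
      pop_before <- pop_next
      pop_next <- apply_excess_deaths(pop_next, e_tot, all_cause)
      scale_cell <- ifelse(pop_before > 0, pop_next / pop_before, 0)
      sick_aged <- sick_aged * scale_cell
    } else {
      e_tot <- 0
    }
    sick_aged <- pmin(sick_aged, pop_next) # guard, inactive in normal runs

    prop_raised <- vapply(dists, sbp_prop_above, numeric(1),
                          threshold = threshold)
    cells_out[[k]] <- grid |>
      dplyr::mutate(year = yr, pop = pop_next,
                    all_cause_deaths = all_cause,
                    sick_total = rowSums(sick_aged),
                    new_cases_total = rowSums(new_cases),
                    prop_raised_bp = prop_raised)
    causes_out[[k]] <- tidyr::expand_grid(grid, cause = causes) |>
      dplyr::mutate(year = yr,
                    deaths = as.vector(t(deaths_c)),
                    new_cases = as.vector(t(new_cases)),
                    prevalent = as.vector(t(sick_aged)))

    m_age <- vapply(seq_len(n_age), function(i) {
      p <- pop[c(i, i + n_age)]
      sum(all_cause[c(i, i + n_age)]) / sum(p)
    }, numeric(1))
    le <- life_expectancy(starts, m_age)
    cvd_idx <- which(starts >= 30 & starts <= 75)
    m_cvd <- vapply(cvd_idx, function(i) {
      sum(deaths_c[c(i, i + n_age), ]) / sum(pop[c(i, i + n_age)])
    }, numeric(1))
    q_cvd <- suppressWarnings(pmin(mortality_probability(m_cvd), 1))
    annual_out[[k]] <- tibble::tibble(
      year = yr,
      population = sum(pop_next),
      births = births,
      excess_removed = e_tot,
      cvd_deaths = sum(deaths_c),
      all_cause_deaths = sum(all_cause),
      new_cases = sum(new_cases),
      prevalent_cases = sum(sick_aged),
      le_20 = le$e_first, le_40 = le$e40,
      cvd_50q30 = probability_50q30(q_cvd),
      coverage = c_now, sodium_intake = na_now
    )
    pop <- pop_next
    sick <- sick_aged
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cvdproj")),
    config_hash = rlang::hash(list(inputs$meta, scenario, interventions,
                                   end_year, calibrate)),
    country_id = inputs$country_id,
    calibration_converged = if (calibrate) all(calibration$converged) else NA,
    elapsed_secs = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  structure(list(
    country_id = inputs$country_id,
    income_group = inputs$income_group,
    scenario = scenario,
    interventions = interventions,
    cells = dplyr::bind_rows(cells_out),
    causes = dplyr::bind_rows(causes_out),
    annual = dplyr::bind_rows(annual_out),
    coverage = coverage,
    sodium = sodium,
    target_year = year_target_achieved(coverage),
    calibration = calibration,
    manifest = manifest
  ), class = "cvd_projection")
}

#' @export
print.cvd_projection <- function(x, ...) {
  cat(sprintf("<cvd_projection> %s, %s scenario (%s interventions), %d-%d\n",
              x$country_id, x$scenario, x$interventions,
              min(x$annual$year), max(x$annual$year)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cvd_projection <- function(x, ...) {
  x$annual |>
    tidyr::pivot_longer(-"year", names_to = "metric", values_to = "value") |>
    dplyr::mutate(country_id = x$country_id, scenario = x$scenario,
                  interventions = x$interventions, .before = 1)
}

#' @exportS3Method generics::glance
glance.cvd_projection <- function(x, ...) {
  window <- dplyr::filter(x$annual, .data$year >= 2020)
  tibble::tibble(
    country_id = x$country_id,
    scenario = x$scenario,
    interventions = x$interventions,
    total_cvd_deaths = sum(window$cvd_deaths),
    total_new_cases = sum(window$new_cases),
    le_20_final = tail(window$le_20, 1),
    cvd_50q30_final = tail(window$cvd_50q30, 1),
    target_year = x$target_year
  )
}

#' Demographic decomposition of a projection
#'
#' Builds the inputs of [decompose_change()] from a projection's recorded
#' states: new CVD cases and age-specific incidence rates in the base and
#' horizon years, and the corresponding population structures.
#'
#' @param projection A `cvd_projection`.
#' @param base_year,proj_year Comparison years (present in the projection).
#' @return Tibble of decomposition components (percent of base-year cases).
#' @export
decompose_projection <- function(projection, base_year = 2020,
                                 proj_year = 2050) {
  snap <- function(yr) {
    projection$cells |>
      dplyr::filter(.data$year == yr) |>
      dplyr::mutate(rate = ifelse(.data$pop > 0,
                                  .data$new_cases_total / .data$pop, 0))
  }
  s0 <- snap(base_year); s1 <- snap(proj_year)
  decompose_change(
    cases_base = sum(s0$new_cases_total),
    rates_base = s0$rate,
    structure_base = s0$pop / sum(s0$pop),
    pop_total_proj = sum(s1$pop),
    structure_proj = s1$pop / sum(s1$pop),
    rates_proj = s1$rate,
    cases_proj = sum(s1$new_cases_total)
  )
}

#' Run a world of countries across scenarios
#'
#' @param world List of `country_inputs` (e.g. from [generate_world()]).
#' @param scenarios Scenarios to run.
#' @param interventions Intervention channels for non-bau scenarios (bau
#'   always runs with both channels at business-as-usual levels).
#' @param ... Passed to [run_projection()].
#' @return An object of class `cvd_resultset`: combined `annual` tibble,
#'   `target_years`, the list of projections, and a run `manifest`.
#' @export
run_world <- function(world, scenarios = c("bau", "progress", "aspirational"),
                      interventions = "both", ...) {
  t_start <- Sys.time()
  runs <- purrr::map(world, function(ci) {
    purrr::map(scenarios, function(sc) {
      ints <- if (sc == "bau") "both" else interventions
      purrr::map(ints, function(iv) {
        run_projection(ci, scenario = sc, interventions = iv, ...)
      })
    }) |> purrr::list_flatten()
  }) |> purrr::list_flatten()
  annual <- purrr::map_dfr(runs, function(pr) {
    pr$annual |>
      dplyr::mutate(country_id = pr$country_id,
                    income_group = pr$income_group,
                    scenario = pr$scenario,
                    interventions = pr$interventions, .before = 1)
  })
  target_years <- purrr::map_dfr(runs, function(pr) {
    tibble::tibble(country_id = pr$country_id, scenario = pr$scenario,
                   interventions = pr$interventions,
                   target_year = pr$target_year)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("cvdproj")),
    id = rlang::hash(list(purrr::map(world, "meta"), scenarios, interventions)),
    n_countries = length(world),
    scenarios = scenarios,
    calibration_converged = purrr::map_lgl(
      runs, ~ isTRUE(.x$manifest$calibration_converged) ||
        is.na(.x$manifest$calibration_converged)),
    elapsed_secs = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  structure(list(annual = annual, target_years = target_years,
                 projections = runs, manifest = manifest),
            class = "cvd_resultset")
}

#' @export
print.cvd_resultset <- function(x, ...) {
  cat(sprintf("<cvd_resultset> %d countries x {%s}, %d projection runs\n",
              x$manifest$n_countries,
              paste(unique(x$annual$scenario), collapse = ", "),
              length(x$projections)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cvd_resultset <- function(x, ...) x$annual

#' @exportS3Method generics::glance
glance.cvd_resultset <- function(x, ...) {
  x$annual |>
    dplyr::filter(.data$year >= 2020) |>
    dplyr::group_by(.data$scenario, .data$interventions) |>
    dplyr::summarise(total_cvd_deaths = sum(.data$cvd_deaths),
                     total_new_cases = sum(.data$new_cases),
                     .groups = "drop")
}

#' Aggregate a resultset by income group
#'
#' Counts are summed over constituent countries; rates, probabilities and
#' life expectancies are population-weighted means. Aggregation is
#' permutation-invariant over countries.
#'
#' @param resultset A `cvd_resultset`.
#' @return Tibble keyed by (income_group, scenario, interventions, year).
#' @export
aggregate_resultset <- function(resultset) {
  resultset$annual |>
    dplyr::group_by(.data$income_group, .data$scenario, .data$interventions,
                    .data$year) |>
    dplyr::summarise(
      population = sum(.data$population),
      cvd_deaths = sum(.data$cvd_deaths),
      all_cause_deaths = sum(.data$all_cause_deaths),
      new_cases = sum(.data$new_cases),
      prevalent_cases = sum(.data$prevalent_cases),
      le_20 = sum(.data$le_20 * .data$population) / sum(.data$population),
      le_40 = sum(.data$le_40 * .data$population) / sum(.data$population),
      cvd_50q30 = sum(.data$cvd_50q30 * .data$population) / sum(.data$population),
      .groups = "drop"
    )
}

#' Export result tables
#'
#' Writes tidy CSVs (per-country annual results, target years, a JSON run
#' manifest) plus a wide summary in the style of a scenario-comparison
#' table: horizon-year totals per scenario with relative differences versus
#' business as usual, `(scenario - bau) / bau`.
#'
#' @param resultset A `cvd_resultset`.
#' @param outdir Output directory (created if needed).
#' @param horizon_year Year summarized in the wide table.
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(resultset, outdir, horizon_year = 2050) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  annual <- dplyr::mutate(resultset$annual, run_id = resultset$manifest$id)
  paths <- c(
    results = file.path(outdir, "results_annual.csv"),
    targets = file.path(outdir, "target_years.csv"),
    summary = file.path(outdir, "summary_table.csv"),
    manifest = file.path(outdir, "manifest.json")
  )
  readr::write_csv(annual, paths["results"])
  readr::write_csv(dplyr::mutate(resultset$target_years,
                                 run_id = resultset$manifest$id),
                   paths["targets"])
  wide <- resultset$annual |>
    dplyr::filter(.data$year == horizon_year) |>
    dplyr::group_by(.data$scenario, .data$interventions) |>
    dplyr::summarise(
      cvd_deaths = sum(.data$cvd_deaths),
      all_cause_deaths = sum(.data$all_cause_deaths),
      new_cases = sum(.data$new_cases),
      prevalent_cases = sum(.data$prevalent_cases),
      le_20 = sum(.data$le_20 * .data$population) / sum(.data$population),
      cvd_50q30 = sum(.data$cvd_50q30 * .data$population) / sum(.data$population),
      .groups = "drop"
    )
  bau <- dplyr::filter(wide, .data$scenario == "bau")
  metrics <- c("cvd_deaths", "all_cause_deaths", "new_cases",
               "prevalent_cases", "le_20", "cvd_50q30")
  for (mtr in metrics) {
    wide[[paste0("rel_diff_", mtr)]] <-
      (wide[[mtr]] - bau[[mtr]]) / bau[[mtr]]
  }
  wide$run_id <- resultset$manifest$id
  readr::write_csv(wide, paths["summary"])
  jsonlite::write_json(resultset$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
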