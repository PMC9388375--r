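#' One-year update of the sick state
#'
#' Four-state Markov update for the diseased ("sick") state of one cause:
#' `sick_t = sick_{t-1} * (1 - (CF + BG)) + well_{t-1} * IR`. Case fatality
#' and background mortality compete additively within the annual step.
#' Vectorized over strata.
#'
#' @param sick,well State occupancies at the previous step (counts >= 0).
#' @param ir Incidence: well-to-sick transition probability.
#' @param cf Case fatality: sick-to-cause-death transition probability.
#' @param bg Background mortality: sick-to-other-death transition
#'   probability.
#' @return Updated sick counts.
#' @export
step_sick <- function(sick, well, ir, cf, bg) {
  assert_nonneg(sick, "sick"); assert_nonneg(well, "well")
  assert_probability(ir, "ir"); assert_probability(cf, "cf")
  assert_probability(bg, "bg")
  if (any(cf + bg > 1 + 1e-12)) abort("`cf + bg` must not exceed 1.")
  sick * (1 - (cf + bg)) + well * ir
}

#' Cause-specific deaths over one step
#'
#' `dead_t = sick_{t-1} * CF`. Vectorized over strata.
#'
#' @inheritParams step_sick
#' @return Cause-specific death counts.
#' @export
step_deaths <- function(sick, cf) {
  assert_nonneg(sick, "sick"); assert_probability(cf, "cf")
  sick * cf
}

#' Reconcile cause models against the all-cause death envelope
#'
#' Aggregates the four cause models against the population: all-cause deaths
#' are the summed cause-specific deaths plus background mortality applied to
#' the whole population; the population is then reduced by all-cause deaths;
#' and the well state of each cause model is recovered as the residual
#' `well = pop - all_cause_deaths - sick`.
#'
#' @param pop Population counts per cell (vector).
#' @param cause_deaths Matrix of cause-specific deaths, cells x causes (a
#'   vector is treated as a single cause).
#' @param bg Background mortality rate per cell (all causes other than the
#'   modelled ones).
#' @param sick Matrix of current sick counts, cells x causes.
#' @return List with `pop_next`, `all_cause_deaths` (per cell), and `well`
#'   (cells x causes matrix).
#' @export
reconcile_envelope <- function(pop, cause_deaths, bg, sick) {
  cause_deaths <- as.matrix(cause_deaths)
  sick <- as.matrix(sick)
  if (nrow(cause_deaths) != length(pop) || nrow(sick) != length(pop)) {
    abort("dimension mismatch between `pop` and state matrices.")
  }
  all_cause <- rowSums(cause_deaths) + pop * bg
  pop_next <- pop - all_cause
  well <- sweep(-sick, 1, pop - all_cause, "+")
  if (any(well < -1e-6)) {
    abort("residual well state is negative: inconsistent inputs.")
  }
  well[well < 0] <- 0
  list(pop_next = pop_next, all_cause_deaths = all_cause, well = well)
}

#' Forward-simulate a single-cause disease model
#'
#' Runs the four-state model forward for one cause, vectorized over strata
#' (all inputs may be equal-length vectors). Case fatality and background
#' mortality may drift at constant annualized log rates of change.
#'
#' Conventions: `prevalence` is sick over current population; `mortality` is
#' deaths during the year per person alive at the start of the year.
#'
#' @param pop0,sick0 Initial population and sick counts per stratum.
#' @param ir,cf,bg Transition probabilities per stratum (year-1 values).
#' @param n_years Number of annual steps.
#' @param cf_trend,bg_trend Annual log rate of change applied to `cf`/`bg`.
#' @return Tibble with one row per stratum-year: `stratum`, `year_index`,
#'   `pop`, `sick`, `well`, `deaths`, `new_cases`, `prevalence`,
#'   `mortality`.
#' @export
sim_disease <- function(pop0, sick0, ir, cf, bg, n_years,
                        cf_trend = 0, bg_trend = 0) {
  n <- length(pop0)
  sick <- sick0
  pop <- pop0
  well <- pop - sick
  out <- vector("list", n_years)
  for (t in seq_len(n_years)) {
    cf_t <- pmin(cf * exp(cf_trend * (t - 1)), 1)
    bg_t <- pmin(bg * exp(bg_trend * (t - 1)), 1 - cf_t)
    deaths <- step_deaths(sick, cf_t)
    new_cases <- well * ir
    sick_next <- step_sick(sick, well, ir, cf_t, bg_t)
    all_cause <- deaths + pop * bg_t
    pop_next <- pop - all_cause
    well_next <- pmax(pop_next - sick_next, 0)
    prev_t <- ifelse(pop_next > 0, sick_next / pop_next, 0)
    mort_t <- ifelse(pop > 0, deaths / pop, 0)
    out[[t]] <- tibble::tibble(
      stratum = seq_len(n), year_index = t,
      pop = pop_next, sick = sick_next, well = well_next,
      deaths = deaths, new_cases = new_cases,
      prevalence = prev_t, mortality = mort_t
    )
    sick <- sick_next; well <- well_next; pop <- pop_next
  }
  dplyr::bind_rows(out)
}

#' Estimate transition probabilities from observed series
#'
#' Inverts the four-state model algebraically against an observed window of
#' disease-specific prevalence and mortality: case fatality in year t is
#' deaths over the sick pool at the start of the year
#' (`CF_t = mortality_t / prevalence_{t-1}`), its trend is the mean annual
#' log rate of change, and incidence is recovered from consecutive
#' prevalences. Incidence is returned as a single (time-constant) value, the
#' mean of the per-year solutions.
#'
#' @param history Data frame with columns `year`, `prevalence` (proportion of
#'   the current population), `mortality` (cause deaths per person at the
#'   start of the year), `bg` (background mortality rate), plus any grouping
#'   columns (e.g. `cause`, `sex`, `age_group`); estimation is performed per
#'   group. At least 6 years per group, all series strictly positive.
#' @return Tibble with one row per group: `ir`, `cf`, `bg` (latest-year
#'   values), `cf_trend` and `bg_trend` (annual log rates of change).
#' @export
estimate_transitions <- function(history) {
  needed <- c("year", "prevalence", "mortality", "bg")
  if (!all(needed %in% names(history))) {
    abort("`history` needs columns year, prevalence, mortality, bg.")
  }
  keys <- setdiff(names(history), needed)
  history |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::group_modify(~ estimate_transitions_one(.x)) |>
    dplyr::ungroup()
}

estimate_transitions_one <- function(df) {
  p <- df$prevalence; m <- df$mortality; bg <- df$bg
  if (length(p) < 6) abort("need at least 6 years of history.")
  if (any(p <= 0) || any(m <= 0) || any(bg < 0)) {
    abort("history series must be strictly positive.")
  }
  T_ <- length(p)
  pop <- numeric(T_); sick <- numeric(T_)
  pop[1] <- 1; sick[1] <- p[1]
  cf_t <- numeric(T_ - 1); ir_t <- numeric(T_ - 1)
  for (t in 2:T_) {
    deaths <- m[t] * pop[t - 1]
    cf_t[t - 1] <- deaths / sick[t - 1]
    all_cause <- deaths + pop[t - 1] * bg[t]
    pop[t] <- pop[t - 1] - all_cause
    sick[t] <- p[t] * pop[t]
    well_prev <- pop[t - 1] - sick[t - 1]
    ir_t[t - 1] <- (sick[t] - sick[t - 1] * (1 - cf_t[t - 1] - bg[t])) / well_prev
  }
  cf_t <- pmin(pmax(cf_t, 1e-10), 1)
  bg_trend <- if (all(bg[-1] > 0)) mean(diff(log(bg[-1]))) else 0
  tibble::tibble(
    ir = max(mean(ir_t), 0),
    cf = cf_t[length(cf_t)],
    bg = bg[length(bg)],
    cf_trend = mean(diff(log(cf_t))),
    bg_trend = bg_trend
  )
}

#' Project case fatality forward
#'
#' Extrapolates an observed case-fatality series at its constant annualized
#' log rate of change; projected values are clipped to `[0, 1]`.
#'
#' @param cf_series Observed annual case-fatality values (positive).
#' @param horizon Number of future years to project.
#' @return Numeric vector of length `horizon`.
#' @export
project_cf_trend <- function(cf_series, horizon) {
  if (any(cf_series <= 0)) abort("`cf_series` must be positive.")
  rate <- if (length(cf_series) > 1) mean(diff(log(cf_series))) else 0
  pmin(pmax(cf_series[length(cf_series)] * exp(rate * seq_len(horizon)), 0), 1)
}

#' Calibrate transition probabilities to target series
#'
#' Finds multiplicative adjustment factors for incidence and case fatality,
#' per group (typically country-cause pair), minimizing a composite
#' root-mean-squared-error objective over the observed window:
#' `weight_mort * RMSE(mortality) + (1 - weight_mort) * RMSE(prevalence)`,
#' with mortality weighted more heavily because death data are generally
#' more reliable than prevalence data. Optimization is derivative-free
#' Nelder-Mead on the log factors.
#'
#' @param transitions Tibble from [estimate_transitions()] (one row per
#'   stratum) with any grouping columns; calibration is per `calib_by`
#'   group, pooling that group's strata.
#' @param history Target series as in [estimate_transitions()], with the
#'   same grouping columns.
#' @param calib_by Columns defining a calibration group (default `"cause"`).
#' @param weight_mort Weight on the mortality RMSE, in (0.5, 1).
#' @param maxit,reltol Optimizer control.
#' @return An object of class `cvd_calibration`: tibble with the group keys,
#'   `factor_ir`, `factor_cf`, `objective`, `objective_unadjusted` (at
#'   factors of 1) and `converged`.
#' @export
calibrate_transitions <- function(transitions, history, calib_by = "cause",
                                  weight_mort = 0.75,
                                  maxit = 500, reltol = 1e-6) {
  if (weight_mort <= 0.5 || weight_mort >= 1) {
    abort("`weight_mort` must lie in (0.5, 1): mortality is weighted more.")
  }
  stratum_keys <- setdiff(names(transitions),
                          c("ir", "cf", "bg", "cf_trend", "bg_trend"))
  res <- transitions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(calib_by))) |>
    dplyr::group_modify(function(tr, key) {
      hist_g <- dplyr::semi_join(history, key, by = calib_by)
      calibrate_group(tr, hist_g, setdiff(stratum_keys, calib_by),
                      weight_mort, maxit, reltol)
    }) |>
    dplyr::ungroup()
  structure(res, class = c("cvd_calibration", class(res)))
}

calibrate_group <- function(tr, hist_g, within_keys, weight_mort,
                            maxit, reltol) {
  years <- sort(unique(hist_g$year))
  n_years <- length(years) - 1L
  tr <- dplyr::arrange(tr, dplyr::across(dplyr::all_of(within_keys)))
  hist_w <- hist_g |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(within_keys),
                       names_from = "year",
                       values_from = c("prevalence", "mortality")) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(within_keys)))
  if (nrow(hist_w) != nrow(tr)) {
    abort("`history` strata do not match `transitions` strata.")
  }
  p0 <- hist_w[[paste0("prevalence_", years[1])]]
  target_prev <- as.matrix(hist_w[paste0("prevalence_", years[-1])])
  target_mort <- as.matrix(hist_w[paste0("mortality_", years[-1])])

  # transitions carry latest-year CF/BG; rewind them to the window start so
  # the trended forward run ends on the estimated values
  cf_start <- tr$cf * exp(-tr$cf_trend * (n_years - 1))
  bg_start <- tr$bg * exp(-tr$bg_trend * (n_years - 1))
  objective <- function(lf) {
    f_ir <- exp(lf[1]); f_cf <- exp(lf[2])
    sim <- sim_disease(pop0 = rep(1, nrow(tr)), sick0 = p0,
                       ir = pmin(tr$ir * f_ir, 1),
                       cf = pmin(cf_start * f_cf, 1),
                       bg = bg_start, n_years = n_years,
                       cf_trend = tr$cf_trend, bg_trend = tr$bg_trend)
    prev_hat <- matrix(sim$prevalence, nrow = nrow(tr))
    mort_hat <- matrix(sim$mortality, nrow = nrow(tr))
    weight_mort * sqrt(mean((mort_hat - target_mort)^2)) +
      (1 - weight_mort) * sqrt(mean((prev_hat - target_prev)^2))
  }
  obj1 <- objective(c(0, 0))
  fit <- optim(c(0, 0), objective, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  best <- if (fit$value <= obj1) exp(fit$par) else c(1, 1)
  tibble::tibble(factor_ir = best[1], factor_cf = best[2],
                 objective = min(fit$value, obj1),
                 objective_unadjusted = obj1,
                 converged = fit$convergence == 0)
}

#' @exportS3Method generics::tidy
tidy.cvd_calibration <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("factor_ir", "factor_cf"),
                        names_to = "parameter", names_prefix = "factor_",
                        values_to = "estimate")
}

#' @exportS3Method generics::glance
glance.cvd_calibration <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x),
    objective = mean(x$objective),
    objective_unadjusted = mean(x$objective_unadjusted),
    all_converged = all(x$converged)
  )
}
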