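#' Effective coverage of hypertension care
#'
#' The product of the three care-cascade stages: the proportion of
#' hypertensives aware of their diagnosis, the proportion of those aware who
#' are treated, and the proportion of those treated whose blood pressure is
#' controlled. An 80-80-80 target implies effective coverage of
#' 0.8^3 = 0.512.
#'
#' @param aware,treated,controlled Cascade-stage proportions in `[0, 1]`.
#' @return Effective coverage (proportion of all hypertensives controlled).
#' @export
effective_coverage <- function(aware = 0.8, treated = 0.8, controlled = 0.8) {
  assert_probability(aware, "aware")
  assert_probability(treated, "treated")
  assert_probability(controlled, "controlled")
  aware * treated * controlled
}

#' Hypertension-control scale-up curves
#'
#' The annual increment in the controlled proportion is modelled as a
#' second-order polynomial in the current control level,
#' `increment(c) = a * c * (ceiling - c)`, scaled so its maximum (attained at
#' half the ceiling) equals `peak_increment`: scale-up is fastest at
#' intermediate coverage and stalls at the ceiling.
#'
#' The `progress` scenario caps the increment at 3 percentage points/year
#' with a ceiling of 53% control (matching the best-performing countries);
#' `aspirational` peaks at 4 points/year with a 75% ceiling (faster than any
#' observed national programme but slower than global antiretroviral
#' scale-up); `bau` members have package-default peaks used by the
#' historical-trend family, see [bau_curve_family()].
#'
#' @param family One of `"progress"`, `"aspirational"`, `"bau"`.
#' @param ceiling Control level at which the increment reaches zero.
#' @param peak_increment Maximum annual increment (proportion/year).
#' @return An object of class `scale_up_curve`.
#' @export
scale_up_curve <- function(family = c("progress", "aspirational", "bau"),
                           ceiling = NULL, peak_increment = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    progress = list(ceiling = 0.53, peak = 0.03),
    aspirational = list(ceiling = 0.75, peak = 0.04),
    bau = list(ceiling = 0.45, peak = 0.015)
  )
  ceiling <- ceiling %||% defaults$ceiling
  peak_increment <- peak_increment %||% defaults$peak
  assert_probability(ceiling, "ceiling")
  assert_nonneg(peak_increment, "peak_increment")
  # the aspirational curve is defined to dominate progress pointwise: its
  # increment is the max of its own polynomial and the progress polynomial
  # (the wider aspirational parabola alone would dip below progress at very
  # low coverage); ceiling and peak rate are unchanged by this floor
  floor_curve <- if (family == "aspirational" && ceiling > 0.53) {
    list(ceiling = 0.53, peak_increment = 0.03)
  }
  structure(list(family = family, ceiling = ceiling,
                 peak_increment = peak_increment, floor_curve = floor_curve),
            class = "scale_up_curve")
}

#' @export
print.scale_up_curve <- function(x, ...) {
  cat(sprintf("<scale_up_curve> %s: ceiling %.0f%%, peak increment %.1f pp/yr\n",
              x$family, 100 * x$ceiling, 100 * x$peak_increment))
  invisible(x)
}

#' Annual increment of a scale-up curve
#'
#' @param curve A `scale_up_curve`.
#' @param control Current control level(s), proportion.
#' @return Annual increment(s), proportion/year; zero at and beyond the
#'   ceiling.
#' @export
curve_increment <- function(curve, control) {
  quad <- function(q, p) pmax(4 * p / q^2 * control * (q - control), 0)
  inc <- quad(curve$ceiling, curve$peak_increment)
  if (!is.null(curve$floor_curve)) {
    inc <- pmax(inc, quad(curve$floor_curve$ceiling,
                          curve$floor_curve$peak_increment))
  }
  inc
}

#' Family of business-as-usual scale-up curves
#'
#' Nine second-order polynomial increment curves whose ceilings span evenly
#' spaced peak-control quantiles from 25% to 65%, all sharing a
#' package-default peak increment reflecting median historically observed
#' scale-up. Country histories are fit against this family to pick the
#' business-as-usual trajectory.
#'
#' @param ceilings Ceilings of the family members.
#' @param peak_increment Shared peak annual increment.
#' @return List of `scale_up_curve` objects, ordered by ceiling.
#' @export
bau_curve_family <- function(ceilings = seq(0.25, 0.65, length.out = 9),
                             peak_increment = 0.015) {
  purrr::map(sort(ceilings), function(q) {
    scale_up_curve("bau", ceiling = q, peak_increment = peak_increment)
  })
}

#' Fit the business-as-usual curve to a control history
#'
#' Scores each member of the nine-curve family by simulating its trajectory
#' from the first observed control level over the most recent decade of
#' history and selects the member with the lowest squared error. Ties break
#' toward the lower-ceiling (conservative) member.
#'
#' @param history Numeric control series (proportions, annual, oldest first)
#'   or a data frame with columns `year` and `control`. At least 5 values.
#' @param family Candidate curves, see [bau_curve_family()].
#' @return The selected `scale_up_curve`, with attributes `sse` (its squared
#'   error) and `member` (its index in the family).
#' @export
fit_bau_curve <- function(history, family = bau_curve_family()) {
  if (is.data.frame(history)) {
    history <- history$control[order(history$year)]
  }
  if (length(history) < 5) abort("need at least 5 years of control history.")
  history <- tail(history, 10)
  assert_probability(history, "history")
  if (all(history == 0)) {
    warn("flat-zero control history; returning lowest-ceiling curve")
    out <- family[[1]]
    attr(out, "sse") <- 0; attr(out, "member") <- 1L
    return(out)
  }
  sse <- vapply(family, function(curve) {
    c_hat <- numeric(length(history))
    c_hat[1] <- history[1]
    for (t in seq_len(length(history) - 1)) {
      c_hat[t + 1] <- min(curve$ceiling,
                          c_hat[t] + curve_increment(curve, c_hat[t]))
    }
    sum((c_hat - history)^2)
  }, numeric(1))
  best <- which(sse <= min(sse) + 1e-15)[1] # family sorted: first = lower peak
  out <- family[[best]]
  attr(out, "sse") <- sse[best]; attr(out, "member") <- best
  out
}

#' Project a hypertension-control trajectory
#'
#' Coverage is held flat from `start_year` through the year before
#' `intervention_start` (no advancements assumed over the pandemic-affected
#' 2019-2022 period), then follows the scale-up recursion
#' `c_{t+1} = min(ceiling, c_t + increment(c_t))`.
#'
#' @param curve A `scale_up_curve`.
#' @param start_level Control level at `start_year`, proportion.
#' @param start_year,end_year Trajectory span (inclusive).
#' @param intervention_start First year the recursion applies.
#' @return Tibble with columns `year` and `control`.
#' @export
coverage_trajectory <- function(curve, start_level, start_year = 2019,
                                end_year = 2050, intervention_start = 2023) {
  assert_probability(start_level, "start_level")
  years <- seq(start_year, end_year)
  control <- numeric(length(years))
  control[1] <- start_level
  if (start_level > curve$ceiling) {
    warn("start level exceeds curve ceiling; trajectory held flat")
    return(tibble::tibble(year = years, control = start_level))
  }
  for (i in seq_len(length(years) - 1)) {
    control[i + 1] <- if (years[i + 1] < intervention_start) {
      control[i]
    } else {
      min(curve$ceiling, control[i] + curve_increment(curve, control[i]))
    }
  }
  tibble::tibble(year = years, control = control)
}

#' Sodium-reduction schedules
#'
#' Scenario definitions for population mean sodium intake: business as usual
#' holds intake at its baseline level; the progress scenario reduces intake
#' by 15% between 2023 and 2030; the aspirational scenario by 30% between
#' 2023 and 2027. Intake never falls below a 2 g/day floor.
#'
#' @param scenario One of `"bau"`, `"progress"`, `"aspirational"`.
#' @return An object of class `sodium_schedule`.
#' @export
sodium_schedule <- function(scenario = c("bau", "progress", "aspirational")) {
  scenario <- match.arg(scenario)
  spec <- switch(scenario,
    bau = list(reduction = 0, target_year = NA_integer_),
    progress = list(reduction = 0.15, target_year = 2030L),
    aspirational = list(reduction = 0.30, target_year = 2027L)
  )
  structure(list(scenario = scenario, relative_reduction = spec$reduction,
                 target_year = spec$target_year, floor = 2,
                 start_year = 2023L),
            class = "sodium_schedule")
}

#' Project a sodium-intake trajectory
#'
#' Intake is flat at baseline through the schedule's start year, declines
#' linearly to the scenario's relative reduction by its target year, then
#' stays flat; the whole series is clipped at the 2 g/day floor.
#'
#' @param schedule A `sodium_schedule`.
#' @param baseline_intake Baseline population mean intake, g/day (> 0).
#' @param start_year,end_year Series span (inclusive).
#' @return Tibble with columns `year` and `intake` (g/day).
#' @export
sodium_trajectory <- function(schedule, baseline_intake, start_year = 2019,
                              end_year = 2050) {
  if (!is.finite(baseline_intake) || baseline_intake <= 0) {
    abort("`baseline_intake` must be positive.")
  }
  years <- seq(start_year, end_year)
  if (schedule$relative_reduction == 0) {
    return(tibble::tibble(year = years, intake = baseline_intake))
  }
  target <- baseline_intake * (1 - schedule$relative_reduction)
  span <- schedule$target_year - schedule$start_year
  frac <- pmin(pmax((years - schedule$start_year) / span, 0), 1)
  intake <- baseline_intake + frac * (target - baseline_intake)
  tibble::tibble(year = years, intake = pmax(intake, schedule$floor))
}

#' First year the 80-80-80 control target is achieved
#'
#' Scans a control trajectory for the first year at or above the effective
#' coverage implied by the 80-80-80 target (0.8^3 = 0.512).
#'
#' @param trajectory Tibble with columns `year` and `control`, or a numeric
#'   control series with a `year` attribute-free interpretation disallowed.
#' @param target Effective coverage threshold (default `0.8^3`).
#' @return The first achieving year (integer), or `NA_integer_` if the
#'   target is not reached within the series.
#' @export
year_target_achieved <- function(trajectory, target = effective_coverage()) {
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0) {
    abort("`trajectory` must be a non-empty data frame with year, control.")
  }
  trajectory <- dplyr::arrange(trajectory, .data$year)
  hit <- which(trajectory$control >= target)
  if (length(hit) == 0) NA_integer_ else as.integer(trajectory$year[hit[1]])
}
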