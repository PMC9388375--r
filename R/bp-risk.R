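#' Default SBP category bounds
#'
#' 10-mmHg systolic blood pressure bins from below 115 mmHg (the reference
#' category, containing the 110-115 mmHg theoretical minimum-risk level) up
#' to 185 mmHg and above.
#'
#' @return Numeric vector of strictly increasing interior cut points (mmHg).
#' @export
sbp_default_breaks <- function() seq(115, 185, by = 10)

#' Shipped blood-pressure risk and treatment-effect parameters
#'
#' Reads the versioned YAML parameter file shipped with the package. It holds
#' the per-10-mmHg relative-risk gradients used to build the default risk
#' table, the relative case-fatality reductions attributable to
#' pharmacological treatment (secondary prevention), the heart-failure share
#' of IHD cases, and the sodium-to-SBP slopes (1.12 mmHg/g above the raised
#' blood pressure threshold, 0.58 mmHg/g below it).
#'
#' @param path Optional path to an alternative YAML parameter file.
#' @return A named list of parameters.
#' @export
default_treatment_effects <- function(path = NULL) {
  path <- path %||% system.file("extdata", "risk_parameters.yaml",
                                package = "cvdproj", mustWork = TRUE)
  params <- yaml::read_yaml(path)
  stopifnot(is.numeric(params$heart_failure_share_ihd))
  params
}

#' Relative risk of new CVD by SBP category
#'
#' Builds a risk table with one row per cause and SBP category. The lowest
#' category is the reference (RR = 1); each subsequent 10-mmHg category
#' multiplies the relative risk by the cause-specific gradient from the
#' parameter file, i.e. a log-linear dose response.
#'
#' @param breaks Interior SBP cut points, as in [sbp_default_breaks()].
#' @param effects Parameter list from [default_treatment_effects()].
#' @return Tibble with columns `cause`, `category` (integer, 1 = reference),
#'   and `rr`.
#' @export
default_risk_table <- function(breaks = sbp_default_breaks(),
                               effects = default_treatment_effects()) {
  n_cat <- length(breaks) + 1L
  purrr::map_dfr(cvd_causes(), function(cause) {
    g <- effects$rr_per_10mmHg[[cause]]
    if (is.null(g)) abort(sprintf("no RR gradient for cause '%s'", cause))
    tibble::tibble(cause = cause,
                   category = seq_len(n_cat),
                   rr = g^(seq_len(n_cat) - 1L))
  })
}

new_sbp_distribution <- function(x, mass, mean, sd, breaks) {
  structure(list(x = x, mass = mass, mean = mean, sd = sd, breaks = breaks),
            class = "sbp_distribution")
}

#' Construct a discretized SBP distribution
#'
#' The population distribution of systolic blood pressure within a sex-age
#' cell is taken to be normal with the given mean; its standard deviation is
#' recovered from the 5th percentile observed in populations free of CVD and
#' antihypertensive use, `sd = (mean - p5) / qnorm(0.95)`. The density is
#' discretized onto a fine grid of point masses so that later distribution
#' shifts (sodium, treatment) are exact translations of mass.
#'
#' @param mean Mean SBP in mmHg.
#' @param p5 5th-percentile SBP in mmHg; must be below `mean`.
#' @param breaks Interior category cut points (mmHg).
#' @param step Grid resolution in mmHg for the discretization.
#' @return An object of class `sbp_distribution`.
#' @export
build_sbp_distribution <- function(mean, p5, breaks = sbp_default_breaks(),
                                   step = 0.5) {
  if (!is.finite(mean) || !is.finite(p5) || mean <= p5) {
    abort("`mean` must exceed `p5`.")
  }
  sd <- (mean - p5) / qnorm(0.95)
  lo <- min(mean - 8 * sd, min(breaks) - 10)
  hi <- max(mean + 8 * sd, max(breaks) + 10)
  edges <- seq(lo, hi, by = step)
  mass <- diff(pnorm(edges, mean, sd))
  mass <- mass / sum(mass)
  x <- (edges[-1] + edges[-length(edges)]) / 2
  keep <- mass > 0
  new_sbp_distribution(x[keep], mass[keep], mean, sd, breaks)
}

#' @export
print.sbp_distribution <- function(x, ...) {
  cat(sprintf("<sbp_distribution> mean %.1f mmHg (current %.1f), sd %.2f, %d mass points\n",
              x$mean, sbp_mean(x), x$sd, length(x$x)))
  invisible(x)
}

#' Current mean of a (possibly shifted) SBP distribution
#'
#' @param dist An `sbp_distribution`.
#' @return Mean SBP in mmHg of the current point-mass cloud.
#' @export
sbp_mean <- function(dist) sum(dist$x * dist$mass) / sum(dist$mass)

#' Proportion of an SBP distribution at or above a threshold
#'
#' @param dist An `sbp_distribution`.
#' @param threshold mmHg cut point (default 140, the raised blood pressure
#'   threshold).
#' @return Proportion of mass with SBP >= threshold.
#' @export
sbp_prop_above <- function(dist, threshold = 140) {
  sum(dist$mass[dist$x >= threshold])
}

#' Category masses of an SBP distribution
#'
#' Aggregates the point-mass cloud into the distribution's SBP categories.
#'
#' @param dist An `sbp_distribution`.
#' @return Tibble with `category` (integer), `lower`, `upper` (mmHg, the
#'   outermost bounds being -Inf/Inf) and `mass`.
#' @export
sbp_category_mass <- function(dist) {
  edges <- c(-Inf, dist$breaks, Inf)
  idx <- findInterval(dist$x, edges, left.open = FALSE)
  mass <- vapply(seq_len(length(edges) - 1L),
                 function(k) sum(dist$mass[idx == k]), numeric(1))
  tibble::tibble(category = seq_along(mass),
                 lower = edges[-length(edges)],
                 upper = edges[-1],
                 mass = mass)
}

#' Standardized CVD risk parameter
#'
#' The population-average relative risk, `alpha = sum(p_i * RR_i)`, where
#' `p_i` is the baseline proportion of the population in SBP category i and
#' `RR_i` the category relative risk.
#'
#' @param p Category masses (must sum to 1).
#' @param rr Category relative risks, same length as `p`.
#' @return The scalar standardized risk parameter.
#' @export
standardized_alpha <- function(p, rr) {
  if (length(p) != length(rr)) abort("`p` and `rr` lengths differ.")
  if (abs(sum(p) - 1) > 1e-6) abort("`p` must sum to 1.")
  sum(p * rr)
}

#' Category-specific incidence rates
#'
#' Scales the average incidence `y` (irrespective of blood pressure) into
#' SBP-category-specific rates `y_i = RR_i / alpha * y`, so that the
#' baseline-weighted mean of the `y_i` reproduces `y`.
#'
#' @param y Average incidence rate.
#' @param rr Category relative risks.
#' @param alpha Standardized risk parameter from [standardized_alpha()].
#' @return Numeric vector of category incidence rates.
#' @export
category_incidence <- function(y, rr, alpha) {
  if (!is.finite(alpha) || alpha <= 0) abort("`alpha` must be positive.")
  y * rr / alpha
}

#' Average incidence under an intervention scenario
#'
#' Reweights the category-specific incidence rates by the post-intervention
#' category masses: `y_star = sum(p_star_i * y_i)`.
#'
#' @param p_star Post-intervention category masses (sum to 1).
#' @param y_i Category incidence rates from [category_incidence()].
#' @return Scalar intervention-scenario incidence.
#' @export
intervention_incidence <- function(p_star, y_i) {
  if (length(p_star) != length(y_i)) abort("length mismatch.")
  if (abs(sum(p_star) - 1) > 1e-6) abort("`p_star` must sum to 1.")
  sum(p_star * y_i)
}

#' Incidence ratio implied by a shifted SBP distribution
#'
#' Convenience composition of the risk-weighting identities: the ratio of
#' scenario to baseline incidence equals the ratio of the RR-weighted mass of
#' the current distribution to the baseline standardized risk parameter.
#'
#' @param dist Current (possibly shifted) `sbp_distribution`.
#' @param alpha Baseline standardized risk parameter for the same cell/cause.
#' @param rr Category relative risks.
#' @return Scalar multiplier to apply to baseline incidence.
#' @export
incidence_ratio <- function(dist, alpha, rr) {
  p_star <- sbp_category_mass(dist)$mass
  standardized_alpha(p_star / sum(p_star), rr) / alpha
}

#' Shift an SBP distribution for reduced sodium intake
#'
#' Mass at or above the raised blood pressure threshold moves down by
#' 1.12 mmHg per gram of reduced daily sodium; mass below the threshold moves
#' by 0.58 mmHg per gram. Implemented as an exact translation of the two
#' segments of the point-mass cloud (a two-component shifted mixture), so no
#' mass is created or destroyed.
#'
#' @param dist An `sbp_distribution`.
#' @param delta_sodium Reduction in sodium intake, g/day (>= 0).
#' @param effects Parameter list from [default_treatment_effects()].
#' @param threshold Raised blood pressure threshold, mmHg.
#' @return The shifted `sbp_distribution`.
#' @export
apply_sodium_shift <- function(dist, delta_sodium,
                               effects = default_treatment_effects(),
                               threshold = 140) {
  if (!is.finite(delta_sodium) || delta_sodium < 0) {
    abort("`delta_sodium` must be non-negative.")
  }
  if (delta_sodium == 0) return(dist)
  raised <- dist$x >= threshold
  shift <- ifelse(raised,
                  effects$sodium_sbp_slope$raised_bp,
                  effects$sodium_sbp_slope$normal_bp) * delta_sodium
  dist$x <- dist$x - shift
  dist
}

#' Shift an SBP distribution for increased hypertension treatment
#'
#' Of the mass at or above the threshold, the newly controlled fraction is
#' relocated uniformly across the 10-mmHg category containing the goal SBP
#' (all of it below the threshold); the remaining mass is unchanged. Total
#' mass is conserved exactly.
#'
#' @param dist An `sbp_distribution`.
#' @param controlled_fraction Fraction of above-threshold mass brought to
#'   goal, in `[0, 1]`.
#' @param goal Goal SBP in mmHg; must be strictly below `threshold`. The
#'   default 130 mmHg represents the typical achieved level under a
#'   <=140 mmHg treatment goal.
#' @param threshold Raised blood pressure threshold, mmHg.
#' @return The shifted `sbp_distribution`.
#' @export
apply_treatment_shift <- function(dist, controlled_fraction, goal = 130,
                                  threshold = 140) {
  assert_probability(controlled_fraction, "controlled_fraction")
  if (goal >= threshold) abort("`goal` must be below `threshold`.")
  if (controlled_fraction == 0) return(dist)
  raised <- dist$x >= threshold
  moved <- sum(dist$mass[raised]) * controlled_fraction
  if (moved == 0) return(dist)
  dist$mass[raised] <- dist$mass[raised] * (1 - controlled_fraction)
  edges <- c(-Inf, dist$breaks, Inf)
  k <- findInterval(goal, edges)
  lo <- edges[k]; hi <- edges[k + 1]
  target <- dist$x >= lo & dist$x < hi
  if (!any(target)) {
    # degenerate cloud with no support in the goal bin: add a point at goal
    dist$x <- c(dist$x, goal)
    dist$mass <- c(dist$mass, moved)
  } else {
    dist$mass[target] <- dist$mass[target] + moved / sum(target)
  }
  dist
}

#' Secondary-prevention adjustment of case fatality
#'
#' Applies the relative case-fatality reduction attributable to increased
#' blood pressure treatment coverage among prevalent cases:
#' `CF * (1 - delta_coverage * r_cause)`. For IHD the reduction blends the
#' with- and without-heart-failure effects using the heart-failure share; HHD
#' uses the heart-failure effect.
#'
#' @param cf Case-fatality probability (vectorized).
#' @param delta_coverage Additional treatment coverage among prevalent cases,
#'   in `[0, 1]`.
#' @param cause One of [cvd_causes()].
#' @param effects Parameter list from [default_treatment_effects()].
#' @return Adjusted case fatality, same shape as `cf`.
#' @export
adjust_case_fatality <- function(cf, delta_coverage, cause,
                                 effects = default_treatment_effects()) {
  assert_probability(delta_coverage, "delta_coverage")
  red <- effects$relative_cf_reduction
  r <- switch(cause,
    ihd = effects$heart_failure_share_ihd * red$ihd_with_heart_failure +
      (1 - effects$heart_failure_share_ihd) * red$ihd_without_heart_failure,
    ischemic_stroke = red$ischemic_stroke,
    hemorrhagic_stroke = red$hemorrhagic_stroke,
    hhd = red$hhd,
    abort(sprintf("unknown cause '%s'", cause))
  )
  cf * (1 - delta_coverage * r)
}
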