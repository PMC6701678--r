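## MVPA dynamics ---------------------------------------------------------------
##
## All movement between activity levels is driven by additive shifts in weekly
## MVPA minutes converted to moved cohort shares under a uniform-within-level
## assumption: a shift of D weekly minutes promotes (demotes) the fraction
## min(1, D / width) of a level of the given interval width to the adjacent
## level. The unbounded high level absorbs promotions and uses a bounded proxy
## width for demotions.

#' Construct an activity distribution
#'
#' @param shares Numeric vector of length 4 (inactive, low, moderate, high);
#'   non-negative, summing to 1 within 1e-9.
#' @param sex `"male"` or `"female"`.
#' @param mean_mvpa Representative mean weekly MVPA minutes per level
#'   (defaults to interval midpoints; high uses lower bound + half the proxy
#'   width). Used as running-mean bookkeeping by [secular_decline()].
#' @param high_width Proxy width for the high level.
#' @return Object of class `pa_activity`.
#' @export
new_activity_distribution <- function(shares, sex = "male",
                                      mean_mvpa = NULL, high_width = 419) {
  shares <- as.numeric(shares)
  if (length(shares) != 4L || any(shares < -1e-12))
    stop("shares must be 4 non-negative numbers", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-9)
    stop(sprintf("shares sum to %.12f, not 1", sum(shares)), call. = FALSE)
  match_arg_ci(sex, SEXES, "sex")
  widths <- c(30, 120, 271, high_width)
  if (is.null(mean_mvpa)) mean_mvpa <- c(0, 30, 150, 421) + widths / 2
  shares <- pmax(shares, 0)
  names(shares) <- ACTIVITY_LEVELS
  mean_mvpa <- as.numeric(mean_mvpa)
  names(mean_mvpa) <- ACTIVITY_LEVELS
  d <- list(sex = sex, shares = shares, mean_mvpa = mean_mvpa,
            high_width = high_width)
  class(d) <- "pa_activity"
  d
}

#' Baseline activity distribution for a sex and age
#'
#' Looks up the bundle's activity prevalence for the band containing `age`.
#'
#' @param bundle A `pa_bundle`.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @return `pa_activity`.
#' @export
baseline_activity <- function(bundle, sex, age) {
  band <- as.character(age_band_of(age))
  ap <- bundle$activity_prevalence
  rows <- ap[ap$sex == sex & ap$age_band == band, ]
  new_activity_distribution(rows$share[match(ACTIVITY_LEVELS, rows$level)],
                            sex = sex,
                            high_width = bundle$settings$high_level_width)
}

#' Categorise a weekly MVPA total into an activity level
#'
#' Half-open intervals: `[0,30)` inactive, `[30,150)` low, `[150,421)`
#' moderate, `[421,Inf)` high minutes per week.
#'
#' @param weekly_mvpa Non-negative weekly MVPA minutes (vectorised).
#' @return Character vector of level names.
#' @export
#' @examples
#' categorize_mvpa(c(0, 150, 420.5, 421))
categorize_mvpa <- function(weekly_mvpa) {
  if (any(weekly_mvpa < 0)) stop("weekly MVPA must be >= 0", call. = FALSE)
  as.character(cut(weekly_mvpa, breaks = c(0, 30, 150, 421, Inf),
                   labels = ACTIVITY_LEVELS, right = FALSE))
}

#' Residual fraction of the intervention effect
#'
#' The effect is fully sustained for `sustain_years` years, then decays
#' exponentially at rate `d` per year: multiplier
#' `(1 - d)^(years_post - sustain_years)`.
#'
#' @param years_post Year since delivery (1 = first year, vectorised).
#' @param d Annual decay rate in `[0, 1]`.
#' @param sustain_years Years of full effect (default 1).
#' @return Fraction of the initial effect remaining.
#' @export
#' @examples
#' effect_multiplier(1:4, d = 0.5)  # 1, 0.5, 0.25, 0.125
effect_multiplier <- function(years_post, d, sustain_years = 1L) {
  if (d < 0 || d > 1) stop("decay rate must be in [0,1]", call. = FALSE)
  ifelse(years_post <= sustain_years, 1,
         (1 - d)^(years_post - sustain_years))
}

#' Shift an activity distribution up by added MVPA minutes
#'
#' Adds `7 * delta_daily * multiplier` weekly minutes; under the uniform
#' within-level assumption the fraction `min(1, shift / width)` of each level
#' is promoted one level; the high level absorbs. Shares remain normalised.
#'
#' @param dist `pa_activity`.
#' @param delta_daily Added MVPA minutes per day (>= 0).
#' @param multiplier Residual effect fraction (see [effect_multiplier()]).
#' @return Shifted `pa_activity`.
#' @export
apply_uplift <- function(dist, delta_daily, multiplier = 1) {
  stopifnot(inherits(dist, "pa_activity"), delta_daily >= 0, multiplier >= 0)
  shift <- 7 * delta_daily * multiplier
  f <- pmin(1, shift / c(30, 120, 271, dist$high_width))
  f[4] <- 0  # no promotion out of high
  s <- dist$shares
  new <- s * (1 - f) + c(0, s[-4] * f[-4])
  out <- new_activity_distribution(new / sum(new), dist$sex,
                                   mean_mvpa = dist$mean_mvpa + shift,
                                   high_width = dist$high_width)
  out
}

#' Age-related decline in activity (one annual step)
#'
#' For ages 17-23 (the 7 transitions out of adolescence) the weekly MVPA mean
#' declines by 6.5 (male) or 5.5 (female) minutes per year — the 7-year total
#' of 45.5 / 38.5 weekly minutes equals the reported 6.5 / 5.5 min/day fall
#' from adolescence to adulthood. The same uniform-within-level rule converts
#' the decrement into demoted shares (high uses its proxy width; inactive
#' absorbs). At the 24, 45 and 65 year band boundaries the distribution is
#' re-targeted to the bundle's band prevalence instead.
#'
#' @param dist `pa_activity` in effect at age `age - 1`.
#' @param sex `"male"` or `"female"`.
#' @param age Age reached at this step.
#' @param bundle Bundle supplying band prevalence for re-targeting.
#' @return `pa_activity` in effect at `age`.
#' @export
secular_decline <- function(dist, sex, age, bundle) {
  stopifnot(inherits(dist, "pa_activity"))
  if (age %in% c(24, 45, 65)) {
    return(baseline_activity(bundle, sex, age))
  }
  if (age < 17 || age > 23) return(dist)
  dec <- if (sex == "male") 6.5 else 5.5
  f <- pmin(1, dec / c(30, 120, 271, dist$high_width))
  f[1] <- 0  # inactive absorbs
  s <- dist$shares
  new <- s * (1 - f) + c(s[-1] * f[-1], 0)
  # mean_mvpa tracks the cumulative shift applied to each level's running
  # mean (pure accounting; shares carry the distributional information)
  new_activity_distribution(new / sum(new), dist$sex,
                            mean_mvpa = dist$mean_mvpa - dec,
                            high_width = dist$high_width)
}

#' Per-cycle activity distributions for an arm
#'
#' Builds the control trajectory (baseline adolescent prevalence, annual
#' decline through age 23, band re-targeting at 24/45/65) and, when a
#' strategy is given, applies the decayed intervention uplift on top of the
#' control distribution for each cycle.
#'
#' @param bundle A `pa_bundle`.
#' @param sex `"male"` or `"female"`.
#' @param horizon Number of annual cycles.
#' @param strategy Intervention name, one-row spec data.frame, or `NULL` for
#'   the control arm.
#' @return List of `pa_activity`, one per cycle (in effect during that cycle).
#' @export
activity_path <- function(bundle, sex, horizon, strategy = NULL) {
  if (is.character(strategy)) strategy <- get_intervention(bundle, strategy)
  entry <- bundle$settings$entry_age
  ctrl <- vector("list", horizon)
  ctrl[[1]] <- baseline_activity(bundle, sex, entry)
  for (k in seq_len(horizon)[-1]) {
    ctrl[[k]] <- secular_decline(ctrl[[k - 1]], sex, entry + k - 1, bundle)
  }
  if (is.null(strategy)) return(ctrl)
  lapply(seq_len(horizon), function(k) {
    mult <- effect_multiplier(k, strategy$decay_rate, strategy$sustain_years)
    apply_uplift(ctrl[[k]], strategy$delta_mvpa_daily, mult)
  })
}

#' Have the intervention and control distributions converged?
#'
#' TRUE when the maximum absolute difference in any level share is below the
#' tolerance (ties included: equal distributions converge).
#'
#' @param dist_int,dist_ctrl `pa_activity` for the two arms.
#' @param tol Share tolerance (default 1e-3).
#' @return Logical.
#' @export
converged_by <- function(dist_int, dist_ctrl, tol = 1e-3) {
  stopifnot(inherits(dist_int, "pa_activity"), inherits(dist_ctrl, "pa_activity"))
  max(abs(dist_int$shares - dist_ctrl$shares)) < tol
}

#' Arm convergence at a given model year
#'
#' Convenience wrapper: builds both arms' trajectories with [activity_path()]
#' and applies [converged_by()] to the distributions in effect during `year`.
#'
#' @param bundle A `pa_bundle`.
#' @param strategy Intervention name or spec.
#' @param year Model year (cycle index, 1-based).
#' @param sex Sex to evaluate.
#' @param tol Share tolerance.
#' @return Logical.
#' @export
arms_converged_at <- function(bundle, strategy, year, sex = "male",
                              tol = bundle$settings$convergence_tol) {
  ctrl <- activity_path(bundle, sex, year)
  int <- activity_path(bundle, sex, year, strategy)
  converged_by(int[[year]], ctrl[[year]], tol)
}

#' @export
print.pa_activity <- function(x, ...) {
  cat(sprintf("<pa_activity %s> %s\n", x$sex,
              paste(sprintf("%s=%.4f", ACTIVITY_LEVELS, x$shares),
                    collapse = " ")))
  invisible(x)
}
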