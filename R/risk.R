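## Risk engine -----------------------------------------------------------------
##
## Converts population-level epidemiology into activity-level-specific annual
## transition probabilities. Population incidence is deflated to the inactive
## group by re-weighting: p_inactive = p_all / sum_L w_L RR_L, and
## re-inflated per level by its relative risk. Competing transitions out of a
## healthy state are composed on the hazard scale: each cause-specific
## probability becomes a hazard, hazards add, and the total leaving
## probability is apportioned by hazard share, keeping rows stochastic
## without truncation.

#' Convert an annual rate to an annual probability
#'
#' `p = 1 - exp(-r)` under a constant hazard over the cycle.
#'
#' @param r Non-negative annual rate (vectorised).
#' @return Annual probability.
#' @export
rate_to_prob <- function(r) {
  if (any(r < 0)) stop("rate must be >= 0", call. = FALSE)
  1 - exp(-r)
}

#' Convert an annual probability back to a rate
#'
#' Inverse of [rate_to_prob()]: `r = -log(1 - p)`.
#'
#' @param p Probability in `[0, 1)` (vectorised).
#' @return Annual rate.
#' @export
prob_to_rate <- function(p) {
  if (any(p < 0 | p >= 1)) stop("probability must be in [0,1)", call. = FALSE)
  -log(1 - p)
}

#' Annual disease probability for the inactive group
#'
#' Deflates a whole-population annual probability to the inactive reference
#' group given the population activity mix: `p_I = p_all / sum(w * rr)`.
#' Level-specific probabilities are then `p_I * rr_L`, and re-aggregation
#' `sum(w * p_I * rr)` recovers `p_all` exactly.
#'
#' @param p_all Whole-population annual probability.
#' @param shares Population share per activity level (sums to 1).
#' @param rr Relative risk per level, `rr[1]` (inactive) equal to 1.
#' @return Annual probability among the inactive.
#' @export
#' @examples
#' inactive_probability(0.01, c(0.4, 0.3, 0.2, 0.1), c(1, 0.9, 0.7, 0.5))
inactive_probability <- function(p_all, shares, rr) {
  stopifnot(length(shares) == length(rr))
  if (abs(sum(shares) - 1) > 1e-9)
    stop("shares must sum to 1", call. = FALSE)
  if (abs(rr[1] - 1) > 1e-12)
    stop("rr[1] (inactive) must equal 1", call. = FALSE)
  denom <- sum(shares * rr)
  if (denom == 0) stop("sum(shares * rr) is zero", call. = FALSE)
  p_all / denom
}

#' Other-cause mortality rate
#'
#' Background mortality net of the six modelled diseases:
#' `max(all-cause - disease-attributable, 0)`. A floored result indicates an
#' inconsistent life table and emits a data-quality warning.
#'
#' @param m_all All-cause annual mortality rate (vectorised).
#' @param m_six Annual mortality rate attributable to the six diseases.
#' @return Other-cause annual rate.
#' @export
other_cause_mortality <- function(m_all, m_six) {
  if (any(m_all < 0) || any(m_six < 0))
    stop("mortality rates must be >= 0", call. = FALSE)
  out <- m_all - m_six
  if (any(out < 0)) {
    warning("disease-attributable mortality exceeds all-cause at ",
            sum(out < 0), " age(s); floored at 0", call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Annual excess cancer death risk from 5-year net survival
#'
#' Net survival is annualised to a constant excess annual death risk
#' `1 - S5^(1/5)` applied in years 1-5 since diagnosis; cancer adds no excess
#' mortality beyond 5 years.
#'
#' @param s5 5-year net survival in `(0, 1]`.
#' @param years_since_diagnosis Integer year since diagnosis (1-based,
#'   vectorised).
#' @return Annual excess death probability.
#' @export
#' @examples
#' cancer_annual_death_risk(0.9^5, 1)  # 0.1
cancer_annual_death_risk <- function(s5, years_since_diagnosis) {
  if (s5 <= 0 || s5 > 1)
    stop("5-year net survival must be in (0,1]", call. = FALSE)
  ifelse(years_since_diagnosis <= 5, 1 - s5^(1 / 5), 0)
}

## scale a probability by a hazard multiplier: 1-(1-p)^m (or naive p*m)
scale_probability <- function(p, m, scale = "hazard") {
  out <- if (scale == "hazard") 1 - (1 - p)^m else p * m
  pmin(pmax(out, 0), 1)
}

## combine independent probabilities on the complement scale
combine_probs <- function(p1, p2) pmin(1 - (1 - p1) * (1 - p2), 1)

mort_value <- function(bundle, disease, param) {
  mo <- bundle$mortality
  v <- mo$value[mo$disease == disease & mo$param == param]
  if (!length(v)) stop("mortality table has no ", param, " for ", disease,
                       call. = FALSE)
  v
}

#' Annual death probability inside a disease state
#'
#' Post-event survival by disease, composed with the background (all-cause
#' life table) probability for the current age:
#' * CHD and stroke: first-year case fatality in year 1, then the background
#'   probability scaled by the post-event multiplier (hazard scale by
#'   default, `1 - (1 - p)^m`; switchable to naive `p * m` via
#'   `settings$multiplier_scale`).
#' * Type 2 diabetes: background scaled by the mortality hazard ratio.
#' * Heart failure: annual case-fatality schedule (last value carried
#'   forward) combined with background.
#' * Cancers: excess risk from 5-year net survival (see
#'   [cancer_annual_death_risk()]) in years 1-5, background only thereafter.
#'
#' Probabilities are capped at 1.
#'
#' @param state Disease state name.
#' @param years_since_event Integer years since the event/diagnosis
#'   (1 = first year; vectorised).
#' @param background Background annual death probability at the current age.
#' @param bundle A `pa_bundle` supplying the post-event parameters.
#' @return Annual death probability, same length as `years_since_event`.
#' @export
post_event_mortality <- function(state, years_since_event, background, bundle) {
  match_arg_ci(state, DISEASES, "state")
  t <- years_since_event
  stopifnot(all(t >= 1), background >= 0, background <= 1)
  scale <- bundle$settings$multiplier_scale
  if (state %in% c("chd", "stroke")) {
    fy <- mort_value(bundle, state, "first_year_death")
    mult <- mort_value(bundle, state, "post_multiplier")
    out <- ifelse(t <= 1, combine_probs(background, fy),
                  scale_probability(background, mult, scale))
  } else if (state == "type2_diabetes") {
    hr <- mort_value(bundle, state, "mortality_hr")
    out <- rep(scale_probability(background, hr, scale), length(t))
  } else if (state == "heart_failure") {
    sched <- bundle$hf_case_fatality$death_prob
    cf <- sched[pmin(t, length(sched))]
    out <- combine_probs(background, cf)
  } else {
    s5 <- mort_value(bundle, state, "net_survival_5yr")
    out <- combine_probs(background, cancer_annual_death_risk(s5, t))
  }
  pmin(out, 1)
}

## Precompute all cycle-level risk inputs for one bundle/horizon --------------
## Returns, per sex: p_level [6 x 4 x horizon] disease entry probabilities,
## p_oc other-cause and p_bg all-cause probabilities per cycle, fatal
## fractions, and closures over the post-event parameters.
prepare_risk <- function(bundle, horizon) {
  s <- bundle$settings
  ages <- s$entry_age + seq_len(horizon) - 1L
  bands <- as.character(age_band_of(ages))
  rrm <- sapply(ACTIVITY_LEVELS, function(L) {
    bundle$relative_risks$rr[match(paste(DISEASES, L),
                                   paste(bundle$relative_risks$disease,
                                         bundle$relative_risks$level))]
  })  # 6 x 4
  rownames(rrm) <- DISEASES
  out <- list(ages = ages, horizon = horizon)
  for (sx in SEXES) {
    ap <- bundle$activity_prevalence[bundle$activity_prevalence$sex == sx, ]
    w_by_band <- sapply(AGE_BANDS, function(b) {
      rows <- ap[ap$age_band == b, ]
      rows$share[match(ACTIVITY_LEVELS, rows$level)]
    })  # 4 x bands
    denom <- sapply(AGE_BANDS, function(b) rrm %*% w_by_band[, b])  # 6 x bands
    inc <- bundle$incidence[bundle$incidence$sex == sx, ]
    key <- paste(inc$disease, inc$age)
    idx <- match(outer(DISEASES, ages, paste), key)
    p_all <- matrix(rate_to_prob(inc$rate[idx]), nrow = length(DISEASES))
    p_inact <- p_all / denom[, match(bands, AGE_BANDS)]
    p_level <- array(0, c(length(DISEASES), 4L, horizon),
                     dimnames = list(DISEASES, ACTIVITY_LEVELS, NULL))
    for (L in seq_len(4L)) p_level[, L, ] <- pmin(p_inact * rrm[, L], 1)
    lt <- bundle$lifetable[bundle$lifetable$sex == sx, ]
    m_all <- lt$all_cause_rate[match(ages, lt$age)]
    m_six <- lt$disease_attributable_rate[match(ages, lt$age)]
    out[[sx]] <- list(
      p_level = p_level,
      p_oc = rate_to_prob(other_cause_mortality(m_all, m_six)),
      p_bg = rate_to_prob(m_all)
    )
  }
  out$fatal_fraction <- stats::setNames(
    vapply(DISEASES, function(d) {
      if (d %in% ACUTE_DISEASES) mort_value(bundle, d, "fatal_fraction") else 0
    }, numeric(1)), DISEASES)
  out
}

## hazard-scale competing-risk split of cause-specific probabilities:
## returns c(per-cause transition probabilities, stay probability)
competing_split <- function(p) {
  p <- pmin(p, 1 - 1e-15)
  h <- -log1p(-p)
  H <- sum(h)
  if (H == 0) return(c(rep(0, length(p)), 1))
  P <- -expm1(-H)
  q <- P * h / H
  c(q, 1 - P)
}

#' Assemble the per-age transition matrices
#'
#' One row-stochastic 11 x 11 matrix over the health states per age and sex.
#' Healthy rows compose the six activity-adjusted disease probabilities and
#' other-cause death on the hazard scale (see [inactive_probability()]);
#' the immediately-fatal fraction of CHD/stroke/HF events routes directly to
#' dead; the within-cycle activity re-categorisation is applied separately by
#' the cohort engine (survivors stay in their level here). Disease rows use
#' the first-year post-event death probability (the engine substitutes the
#' tenure-specific probability as the cohort ages in the state); dead is
#' absorbing.
#'
#' @param bundle A validated `pa_bundle`.
#' @param horizon Number of annual cycles (default: full lifetime).
#' @return Object of class `pa_matrices`: per sex an array
#'   `[11, 11, horizon]`, plus the fatal-event split per acute disease.
#' @export
build_matrices <- function(bundle, horizon = NULL) {
  s <- bundle$settings
  if (is.null(horizon)) horizon <- s$exit_age - s$entry_age
  rk <- prepare_risk(bundle, horizon)
  states <- health_states()
  out <- list(ages = rk$ages, fatal_fraction = rk$fatal_fraction)
  for (sx in SEXES) {
    arr <- array(0, c(11L, 11L, horizon), dimnames = list(states, states, NULL))
    r <- rk[[sx]]
    for (k in seq_len(horizon)) {
      M <- matrix(0, 11L, 11L, dimnames = list(states, states))
      for (L in seq_len(4L)) {
        q <- competing_split(c(r$p_level[, L, k], r$p_oc[k]))
        fatal <- q[seq_along(DISEASES)] * rk$fatal_fraction
        M[L, DISEASES] <- q[seq_along(DISEASES)] - fatal
        M[L, "dead"] <- q[7L] + sum(fatal)
        M[L, L] <- q[8L]
      }
      for (d in DISEASES) {
        pd <- post_event_mortality(d, 1L, r$p_bg[k], bundle)
        M[d, "dead"] <- pd
        M[d, d] <- 1 - pd
      }
      M["dead", "dead"] <- 1
      if (any(M < 0))
        stop(sprintf("negative transition entry at age %d, sex %s",
                     rk$ages[k], sx), call. = FALSE)
      arr[, , k] <- M
    }
    out[[sx]] <- arr
  }
  class(out) <- "pa_matrices"
  out
}

#' Export transition matrices as a long table
#'
#' @param mats A `pa_matrices` object from [build_matrices()].
#' @param drop_zero Drop zero-probability entries?
#' @return data.frame with columns `age`, `sex`, `from`, `to`, `probability`.
#' @export
matrices_to_table <- function(mats, drop_zero = TRUE) {
  states <- health_states()
  rows <- lapply(SEXES, function(sx) {
    arr <- mats[[sx]]
    df <- expand.grid(from = states, to = states,
                      age = mats$ages, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    df$sex <- sx
    df$probability <- as.vector(arr)
    df
  })
  out <- do.call(rbind, rows)[, c("age", "sex", "from", "to", "probability")]
  if (drop_zero) out <- out[out$probability > 0, ]
  rownames(out) <- NULL
  out
}
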