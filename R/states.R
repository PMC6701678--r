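#' @keywords internal
"_PACKAGE"

## Model vocabulary -----------------------------------------------------------
## The state space has 11 mutually exclusive health states: four healthy
## activity levels, six chronic disease states (absorbing until death, no
## between-disease transitions), and dead.

ACTIVITY_LEVELS <- c("inactive", "low", "moderate", "high")

DISEASES <- c("chd", "stroke", "heart_failure", "type2_diabetes",
              "breast_cancer", "colorectal_cancer")

## Acute diseases with an immediately-fatal event fraction
ACUTE_DISEASES <- c("chd", "stroke", "heart_failure")
CANCERS <- c("breast_cancer", "colorectal_cancer")

SEXES <- c("male", "female")

AGE_BANDS <- c("16-23", "24-44", "45-64", "65plus")

## Age groups of the baseline (healthy) utility grid
UTILITY_AGE_GROUPS <- c("16-34", "35-44", "45-54", "55-64", "65-74", "75plus")

#' Names of the 11 model health states
#'
#' Four physical-activity levels (disease-free), six chronic disease states
#' and dead, in canonical order.
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c(ACTIVITY_LEVELS, DISEASES, "dead")
}

#' Activity level definitions
#'
#' The four weekly-MVPA levels as contiguous half-open intervals
#' `[0,30)`, `[30,150)`, `[150,421)`, `[421,Inf)` minutes per week.
#' The interval *width* is used by the uniform-within-level promotion rule;
#' the unbounded high level is assigned a bounded proxy width (configurable
#' via the bundle settings, default 419, mirroring the moderate width).
#'
#' @param high_width Proxy width (weekly minutes) for the unbounded high level.
#' @return data.frame with columns `level`, `lower`, `upper`, `width`.
#' @export
activity_level_table <- function(high_width = 419) {
  stopifnot(is.numeric(high_width), high_width > 0)
  data.frame(
    level = ACTIVITY_LEVELS,
    lower = c(0, 30, 150, 421),
    upper = c(30, 150, 421, Inf),
    width = c(30, 120, 271, high_width),
    stringsAsFactors = FALSE
  )
}

## Map a single-year age to the activity prevalence band
age_band_of <- function(age) {
  cut(age, breaks = c(-Inf, 23, 44, 64, Inf), labels = AGE_BANDS)
}

## Map a single-year age to the baseline-utility age group
utility_age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 34, 44, 54, 64, 74, Inf),
      labels = UTILITY_AGE_GROUPS)
}

match_arg_ci <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices) {
    stop(sprintf("%s must be one of: %s", what,
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  x
}
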