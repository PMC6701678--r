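## Synthetic parameter fixtures ------------------------------------------------
##
## The model's full transition-parameter inputs (incidence curves, relative
## risks, life tables, case fatality, activity prevalence) come from sources
## that are not shipped as machine-readable tables. This module generates
## seeded SYNTHETIC bundles with the same schema and statistical shape
## (exponential age-incidence, Gompertz mortality, monotone RR gradients,
## activity prevalence declining with age) so every downstream module builds
## and tests offline. Magnitudes are chosen to keep lifetime incidence and
## model outputs in a broadly plausible UK range; they are NOT the source
## values, and bundles are flagged via settings$epidemiology_source.

#' Recipe for a synthetic parameter bundle
#'
#' Defines the statistical shape of the generated epidemiology. Defaults give
#' a UK-plausible cohort: Gompertz-like all-cause mortality, exponentially
#' age-increasing disease incidence, protective activity RR gradients, and
#' activity prevalence that declines from adolescence to retirement.
#'
#' @param seed RNG seed; bundles are bit-identical given the same recipe.
#' @param jitter_sd Standard deviation of the seeded per-disease log-normal
#'   perturbation applied to incidence scale (0 disables).
#' @param incidence data.frame with per-disease `rate40_male`, `rate40_female`
#'   (annual incidence at age 40, per person-year) and exponential `slope`
#'   per year of age.
#' @param rr 6 x 4 matrix of relative risks (rows = diseases, columns =
#'   activity levels), monotone non-increasing with RR(inactive) = 1.
#' @param gompertz Per-sex Gompertz parameters `a`, `b`: all-cause rate
#'   `a * exp(b * age)`.
#' @param disease_attrib_fraction Fraction of all-cause mortality attributed
#'   to the six modelled diseases (for other-cause decomposition).
#' @param prevalence data.frame of activity shares by sex and age band.
#' @param fatal_fraction,first_year_death,post_multiplier Acute-event
#'   parameters for CHD/stroke/HF.
#' @param diabetes_hr,diabetes_hr_ci Mortality hazard ratio for type 2
#'   diabetes with 95% CI (synthetic default 1.8; not published in the text).
#' @param net_survival 5-year net survival for breast / colorectal cancer.
#' @param hf_schedule Annual heart-failure case-fatality schedule, years 1-10.
#' @param rate_cap Upper cap on any generated rate.
#' @return A list of class `fixture_recipe`.
#' @export
fixture_recipe <- function(seed = 20140816,
                           jitter_sd = 0.05,
                           incidence = NULL,
                           rr = NULL,
                           gompertz = NULL,
                           disease_attrib_fraction = 0.25,
                           prevalence = NULL,
                           fatal_fraction = c(chd = 0.25, stroke = 0.20,
                                              heart_failure = 0.15),
                           first_year_death = c(chd = 0.10, stroke = 0.15),
                           post_multiplier = c(chd = 2.0, stroke = 2.0),
                           diabetes_hr = 1.8,
                           diabetes_hr_ci = c(1.5, 2.2),
                           net_survival = c(breast_cancer = 0.85,
                                            colorectal_cancer = 0.59),
                           hf_schedule = c(0.20, 0.12, 0.10, 0.09, 0.09,
                                           0.08, 0.08, 0.08, 0.08, 0.08),
                           rate_cap = 0.5) {
  if (is.null(incidence)) {
    incidence <- data.frame(
      disease = DISEASES,
      rate40_male   = c(0.0020, 0.0008, 0.0004, 0.0040, 0.00001, 0.0006),
      rate40_female = c(0.0010, 0.0007, 0.0003, 0.0030, 0.00180, 0.0005),
      slope = c(0.075, 0.085, 0.095, 0.045, 0.035, 0.070),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(rr)) {
    rr <- rbind(
      chd               = c(1, 0.85, 0.73, 0.67),
      stroke            = c(1, 0.88, 0.78, 0.73),
      heart_failure     = c(1, 0.84, 0.72, 0.65),
      type2_diabetes    = c(1, 0.80, 0.65, 0.55),
      breast_cancer     = c(1, 0.93, 0.88, 0.85),
      colorectal_cancer = c(1, 0.90, 0.80, 0.76)
    )
    colnames(rr) <- ACTIVITY_LEVELS
  }
  if (is.null(gompertz)) {
    gompertz <- data.frame(sex = SEXES,
                           a = c(4.0e-5, 2.6e-5),
                           b = c(0.092, 0.097),
                           stringsAsFactors = FALSE)
  }
  if (is.null(prevalence)) {
    # shares (inactive, low, moderate, high); activity declines with age;
    # self-reported inactivity (<30 MVPA min/week) is rare in adolescence
    prevalence <- rbind(
      expand_prev("male",
                  `16-23`  = c(0.04, 0.14, 0.42, 0.40),
                  `24-44`  = c(0.15, 0.24, 0.36, 0.25),
                  `45-64`  = c(0.25, 0.30, 0.30, 0.15),
                  `65plus` = c(0.40, 0.30, 0.22, 0.08)),
      expand_prev("female",
                  `16-23`  = c(0.04, 0.15, 0.44, 0.37),
                  `24-44`  = c(0.18, 0.26, 0.35, 0.21),
                  `45-64`  = c(0.28, 0.31, 0.28, 0.13),
                  `65plus` = c(0.44, 0.30, 0.19, 0.07))
    )
  }
  recipe <- list(seed = seed, jitter_sd = jitter_sd, incidence = incidence,
                 rr = rr, gompertz = gompertz,
                 disease_attrib_fraction = disease_attrib_fraction,
                 prevalence = prevalence, fatal_fraction = fatal_fraction,
                 first_year_death = first_year_death,
                 post_multiplier = post_multiplier,
                 diabetes_hr = diabetes_hr, diabetes_hr_ci = diabetes_hr_ci,
                 net_survival = net_survival, hf_schedule = hf_schedule,
                 rate_cap = rate_cap)
  class(recipe) <- "fixture_recipe"
  stopifnot(all(recipe$rr > 0), all(recipe$rr <= 1.5),
            all(abs(recipe$rr[, "inactive"] - 1) < 1e-12),
            all(apply(recipe$rr, 1, function(x) all(diff(x) <= 0))),
            disease_attrib_fraction >= 0, disease_attrib_fraction < 1,
            all(net_survival > 0), all(net_survival <= 1))
  recipe
}

expand_prev <- function(sex, ...) {
  bands <- list(...)
  do.call(rbind, lapply(names(bands), function(b) {
    data.frame(sex = sex, age_band = b, level = ACTIVITY_LEVELS,
               share = bands[[b]], stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic parameter bundle
#'
#' Deterministic given the recipe (including its seed): incidence increases
#' with age, disease risk weakly decreases with activity level, mortality
#' increases with age, and adolescent activity prevalence declines toward the
#' older age bands. Printed cost/utility tables and intervention specs are
#' taken from [printed_value_tables()] and [default_interventions()].
#'
#' @param recipe A [fixture_recipe()].
#' @param settings Run settings (defaults to [default_settings()]).
#' @return A validated `pa_bundle` with `epidemiology_source = "synthetic"`.
#' @export
make_bundle <- function(recipe = fixture_recipe(),
                        settings = default_settings()) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  ages <- settings$entry_age:settings$exit_age
  rng <- local({ set.seed(recipe$seed);
                 matrix(stats::rnorm(length(DISEASES) * 2, 0, recipe$jitter_sd),
                        nrow = length(DISEASES), ncol = 2,
                        dimnames = list(DISEASES, SEXES)) })

  inc <- do.call(rbind, lapply(seq_along(DISEASES), function(i) {
    d <- DISEASES[i]
    row <- recipe$incidence[recipe$incidence$disease == d, ]
    do.call(rbind, lapply(SEXES, function(sx) {
      r40 <- if (sx == "male") row$rate40_male else row$rate40_female
      scale <- r40 * exp(rng[d, sx])
      data.frame(disease = d, sex = sx, age = ages,
                 rate = pmin(recipe$rate_cap,
                             scale * exp(row$slope * (ages - 40))),
                 stringsAsFactors = FALSE)
    }))
  }))

  rr <- do.call(rbind, lapply(DISEASES, function(d) {
    v <- recipe$rr[d, ]
    data.frame(disease = d, level = ACTIVITY_LEVELS, rr = unname(v),
               ci_low = unname(v) * exp(-0.15), ci_high = unname(v) * exp(0.15),
               stringsAsFactors = FALSE)
  }))
  # inactive is the reference category: RR fixed at 1, no uncertainty
  rr$ci_low[rr$level == "inactive"] <- 1
  rr$ci_high[rr$level == "inactive"] <- 1

  lt <- do.call(rbind, lapply(SEXES, function(sx) {
    g <- recipe$gompertz[recipe$gompertz$sex == sx, ]
    m <- pmin(recipe$rate_cap, g$a * exp(g$b * ages))
    data.frame(sex = sx, age = ages, all_cause_rate = m,
               disease_attributable_rate = recipe$disease_attrib_fraction * m,
               stringsAsFactors = FALSE)
  }))

  mortality <- rbind(
    data.frame(disease = names(recipe$fatal_fraction), param = "fatal_fraction",
               value = unname(recipe$fatal_fraction), se = 0.1 * unname(recipe$fatal_fraction),
               ci_low = NA_real_, ci_high = NA_real_, stringsAsFactors = FALSE),
    data.frame(disease = names(recipe$first_year_death), param = "first_year_death",
               value = unname(recipe$first_year_death), se = 0.1 * unname(recipe$first_year_death),
               ci_low = NA_real_, ci_high = NA_real_, stringsAsFactors = FALSE),
    data.frame(disease = names(recipe$post_multiplier), param = "post_multiplier",
               value = unname(recipe$post_multiplier), se = NA_real_,
               ci_low = unname(recipe$post_multiplier) * 0.75,
               ci_high = unname(recipe$post_multiplier) * 1.35,
               stringsAsFactors = FALSE),
    data.frame(disease = "type2_diabetes", param = "mortality_hr",
               value = recipe$diabetes_hr, se = NA_real_,
               ci_low = recipe$diabetes_hr_ci[1], ci_high = recipe$diabetes_hr_ci[2],
               stringsAsFactors = FALSE),
    data.frame(disease = names(recipe$net_survival), param = "net_survival_5yr",
               value = unname(recipe$net_survival),
               se = 0.02, ci_low = NA_real_, ci_high = NA_real_,
               stringsAsFactors = FALSE)
  )

  hf <- data.frame(year = seq_along(recipe$hf_schedule),
                   death_prob = recipe$hf_schedule,
                   se = 0.1 * recipe$hf_schedule)

  printed <- printed_value_tables()
  settings$epidemiology_source <- "synthetic"
  new_bundle(c(list(
    incidence = inc,
    incidence_uncertainty = data.frame(disease = DISEASES, se_fraction = 0.10,
                                       stringsAsFactors = FALSE),
    relative_risks = rr,
    lifetable = lt,
    activity_prevalence = recipe$prevalence,
    mortality = mortality,
    hf_case_fatality = hf,
    interventions = default_interventions()
  ), printed), settings)
}

#' The analytic null bundle
#'
#' All incidence and mortality rates zero, all relative risks 1, all costs and
#' SEs zero, all utilities 1 (diseases included). Under the null bundle the
#' cohort never leaves the healthy states, every mortality- and
#' disease-related accumulator is exactly zero, and total discounted QALYs
#' reduce to a closed-form geometric series of discounted person-years —
#' the anchor used by the invariant tests.
#'
#' @param settings Run settings.
#' @return A validated `pa_bundle`.
#' @export
make_null_bundle <- function(settings = default_settings()) {
  b <- make_bundle(fixture_recipe(jitter_sd = 0), settings)
  b$incidence$rate <- 0
  b$incidence_uncertainty$se_fraction <- 0
  b$relative_risks$rr <- 1
  b$relative_risks$ci_low <- 1
  b$relative_risks$ci_high <- 1
  b$lifetable$all_cause_rate <- 0
  b$lifetable$disease_attributable_rate <- 0
  b$disease_utilities$utility <- 1
  b$disease_utilities$se <- 0
  b$baseline_utilities$utility <- 1
  b$baseline_utilities$se <- 0
  b$disease_costs$cost <- 0
  b$disease_costs$se <- 0
  b$mortality$value[b$mortality$param == "fatal_fraction"] <- 0
  b$mortality$value[b$mortality$param == "first_year_death"] <- 0
  b$mortality$value[b$mortality$param == "post_multiplier"] <- 1
  b$mortality$value[b$mortality$param == "mortality_hr"] <- 1
  b$mortality$value[b$mortality$param == "net_survival_5yr"] <- 1
  b$mortality$se <- ifelse(is.na(b$mortality$se), NA_real_, 0)
  b$mortality$ci_low <- ifelse(is.na(b$mortality$ci_low), NA_real_,
                               b$mortality$value)
  b$mortality$ci_high <- b$mortality$ci_low
  b$hf_case_fatality$death_prob <- 0
  b$hf_case_fatality$se <- 0
  b$interventions$ci_low <- b$interventions$delta_mvpa_daily
  b$interventions$ci_high <- b$interventions$delta_mvpa_daily
  b$settings$epidemiology_source <- "null"
  validate_bundle(b)
  b
}
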