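# Shared fixtures, built once per test run. All bundles are generated in code
# (synthetic epidemiology); nothing is read from disk except round-trip tests.

the_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- default_bundle()
    b
  }
})

the_null_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- make_null_bundle()
    b
  }
})

# A three-effective-state toy: one activity level occupied, a single disease
# (CHD) with constant incidence, constant background mortality, flat
# utilities. Used by the exhaustive path-enumeration oracle.
toy_bundle <- function(cohort = 1) {
  b <- make_null_bundle()
  s <- b$settings
  s$cohort_size <- cohort
  s$male_fraction <- 1
  b$settings <- s
  b$incidence$rate[b$incidence$disease == "chd"] <- 0.05
  b$lifetable$all_cause_rate <- 0.02
  b$activity_prevalence$share <-
    rep(c(1, 0, 0, 0), times = nrow(b$activity_prevalence) / 4)
  b$baseline_utilities$utility <- 0.9
  b$disease_utilities$utility[b$disease_utilities$disease == "chd"] <- 0.7
  dc <- b$disease_costs
  b$disease_costs$cost[dc$disease == "chd"] <-
    c(1000, 200, 500)[match(dc$phase[dc$disease == "chd"],
                            c("first_year", "subsequent", "fatal_event"))]
  mo <- b$mortality
  b$mortality$value[mo$disease == "chd" & mo$param == "fatal_fraction"] <- 0.2
  b$mortality$value[mo$disease == "chd" & mo$param == "first_year_death"] <- 0.12
  b$mortality$value[mo$disease == "chd" & mo$param == "post_multiplier"] <- 3
  validate_bundle(b)
  b
}

# Discounted person-years over a horizon: the closed-form QALY total of the
# null bundle (utility 1, no mortality, half-cycle correction is exact for
# constant occupancy).
discounted_person_years <- function(horizon, rate = 0.035) {
  sum((1 + rate)^-(seq_len(horizon)))
}

# Independent oracle for toy_bundle(): exhaustive expectation over every
# state path (healthy H, disease year D1..Dt, dead X) with tenure tracking,
# trapezoid (half-cycle) state rewards, discounting, and fatal-event point
# costs. Transition probabilities are recomputed here from first principles
# (hazard addition and apportioning), independent of the package internals.
toy_oracle <- function(horizon = 5, v = 1 / 1.035) {
  H <- 0.05 + 0.02                       # chd hazard + background hazard
  P <- 1 - exp(-H)
  q_chd <- P * 0.05 / H
  q_oc <- P * 0.02 / H
  stay <- 1 - P
  f <- 0.2                               # immediately fatal fraction
  p_bg <- 1 - exp(-0.02)
  d_death <- function(t) if (t <= 1) 1 - (1 - p_bg) * (1 - 0.12) else
    1 - (1 - p_bg)^3
  u <- function(s) if (s == "H") 0.9 else if (s == "X") 0 else 0.7
  cost_rate <- function(s) if (identical(s, "D1")) 1000 else
    if (startsWith(s, "D")) 200 else 0

  recurse <- function(state, k) {
    if (k > horizon) return(c(qaly = 0, cost = 0))
    step <- function(nxt, prob, event_cost = 0) {
      val <- c(qaly = (u(state) + u(nxt)) / 2 * v^k,
               cost = ((cost_rate(state) + cost_rate(nxt)) / 2 + event_cost) * v^k)
      prob * (val + recurse(nxt, k + 1))
    }
    if (state == "H") {
      step("D1", q_chd * (1 - f)) +
        step("X", q_chd * f, event_cost = 500) +
        step("X", q_oc) +
        step("H", stay)
    } else if (state == "X") {
      c(qaly = 0, cost = 0)
    } else {
      t <- as.integer(substring(state, 2))
      pd <- d_death(t)
      step("X", pd) + step(paste0("D", t + 1), 1 - pd)
    }
  }
  recurse("H", 1)
}
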