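## Markov cohort engine --------------------------------------------------------
##
## Deterministic cohort expectation over the 11 states, stratified by sex and
## by years-in-disease (tenure), run for up to 65 annual cycles. Within each
## cycle: activity dynamics first (the healthy pool is re-allocated to the
## arm's current activity distribution), then competing transitions out of
## each healthy level and tenure-specific death risks inside the disease
## states. State rewards are credited with a half-cycle correction and
## discounted; acute fatal events and the intervention cost are point
## expenditures (no half-cycle).

#' Half-cycle-corrected reward for one cycle
#'
#' Credits `reward * (start + end) / 2`, the trapezoid approximation under
#' the assumption that transitions happen halfway through the cycle.
#'
#' @param start_occupancy,end_occupancy State occupancy at the cycle
#'   boundaries (vectorised).
#' @param per_person_reward Annual reward per person-year in the state.
#' @return Reward earned during the cycle.
#' @export
half_cycle_value <- function(start_occupancy, end_occupancy, per_person_reward) {
  stopifnot(all(start_occupancy >= 0), all(end_occupancy >= 0))
  per_person_reward * (start_occupancy + end_occupancy) / 2
}

#' Discount factor for a model cycle
#'
#' `(1 + rate)^(-t)`; `t = 0` is undiscounted.
#'
#' @param t Cycle index (>= 0, vectorised).
#' @param rate Annual discount rate.
#' @return Discount multiplier.
#' @export
#' @examples
#' discount_factor(0:2, 0.035)
discount_factor <- function(t, rate) {
  stopifnot(all(t >= 0), rate >= 0)
  (1 + rate)^(-t)
}

#' Annual reward rates for a cohort state
#'
#' Undiscounted annual cost and QALY accrual rates for a given occupancy:
#' healthy members earn the age-group x activity-level baseline utility and
#' zero cost; disease members earn the disease utility and the first-year or
#' subsequent-year cost according to their years in the state; dead earns
#' nothing. Fatal-event costs are point costs handled by the engine, not
#' annual rates.
#'
#' @param bundle A `pa_bundle`.
#' @param age Age (years) at which occupancy is measured.
#' @param healthy Named occupancy per activity level (length 4).
#' @param disease 6 x T matrix of disease occupancy by tenure year
#'   (rows in `mvpasim:::DISEASES` order), or `NULL`.
#' @return List with `cost` and `qaly` annual rates.
#' @export
cycle_rewards <- function(bundle, age, healthy, disease = NULL) {
  stopifnot(length(healthy) == 4L)
  u_base <- vapply(ACTIVITY_LEVELS, function(L) baseline_utility(bundle, age, L),
                   numeric(1))
  qaly <- sum(healthy * u_base)
  cost <- 0
  if (!is.null(disease) && length(disease)) {
    disease <- matrix(disease, nrow = length(DISEASES))
    u_d <- bundle$disease_utilities$utility[
      match(DISEASES, bundle$disease_utilities$disease)]
    c_first <- vapply(DISEASES, disease_cost, numeric(1), bundle = bundle,
                      phase = "first_year")
    c_subs <- vapply(DISEASES, disease_cost, numeric(1), bundle = bundle,
                     phase = "subsequent")
    qaly <- qaly + sum(u_d * rowSums(disease))
    cost <- cost + sum(c_first * disease[, 1L])
    if (ncol(disease) > 1L)
      cost <- cost + sum(c_subs * rowSums(disease[, -1L, drop = FALSE]))
  }
  list(cost = cost, qaly = qaly)
}

## Precompute reward/death-probability lookups for the fast engine loop
prepare_rewards <- function(bundle, horizon) {
  s <- bundle$settings
  ages <- s$entry_age + 0:horizon
  grp <- as.character(utility_age_group_of(ages))
  bu <- bundle$baseline_utilities
  u_base <- t(vapply(grp, function(g) {
    bu$utility[bu$age_group == g][match(ACTIVITY_LEVELS,
                                        bu$level[bu$age_group == g])]
  }, numeric(4)))  # (horizon+1) x 4, row i = age entry+i-1
  u_d <- bundle$disease_utilities$utility[
    match(DISEASES, bundle$disease_utilities$disease)]
  dc <- bundle$disease_costs
  pick <- function(phase) dc$cost[match(paste(DISEASES, phase),
                                        paste(dc$disease, dc$phase))]
  list(u_base = u_base, u_d = u_d,
       c_first = pick("first_year"), c_subs = pick("subsequent"),
       c_fatal = pick("fatal_event"))
}

## Per-sex death-probability matrices P[[d]][k, t] for tenure t at cycle k
prepare_death_probs <- function(bundle, rk, horizon) {
  scale <- bundle$settings$multiplier_scale
  sched <- bundle$hf_case_fatality$death_prob
  pars <- list(
    chd = list(fy = mort_value(bundle, "chd", "first_year_death"),
               mult = mort_value(bundle, "chd", "post_multiplier")),
    stroke = list(fy = mort_value(bundle, "stroke", "first_year_death"),
                  mult = mort_value(bundle, "stroke", "post_multiplier")),
    hr = mort_value(bundle, "type2_diabetes", "mortality_hr"),
    s5 = c(breast_cancer = mort_value(bundle, "breast_cancer", "net_survival_5yr"),
           colorectal_cancer = mort_value(bundle, "colorectal_cancer",
                                          "net_survival_5yr"))
  )
  tv <- seq_len(horizon)
  out <- list()
  for (sx in SEXES) {
    bg <- rk[[sx]]$p_bg
    P <- list()
    for (d in c("chd", "stroke")) {
      first <- combine_probs(bg, pars[[d]]$fy)
      later <- scale_probability(bg, pars[[d]]$mult, scale)
      P[[d]] <- cbind(first, matrix(later, horizon, horizon - 1L))
    }
    P$type2_diabetes <- matrix(scale_probability(bg, pars$hr, scale),
                               horizon, horizon)
    cf <- sched[pmin(tv, length(sched))]
    P$heart_failure <- 1 - outer(1 - bg, 1 - cf)
    for (d in CANCERS) {
      ex <- cancer_annual_death_risk(pars$s5[[d]], tv)
      P[[d]] <- 1 - outer(1 - bg, 1 - ex)
    }
    out[[sx]] <- lapply(P[DISEASES], function(m) pmin(m, 1))
  }
  out
}

#' Run the cohort model
#'
#' Propagates the cohort through `horizon` annual cycles. Cycle 0 delivers
#' the intervention: its per-participant cost is charged to the whole cohort,
#' undiscounted, and the activity uplift takes effect from cycle 1 (decaying
#' per the strategy's decay rate). Each cycle re-allocates the healthy pool
#' to the arm's current activity distribution, applies competing transitions
#' (six diseases, other-cause death, immediate fatal split for acute events),
#' advances disease tenure with tenure-specific death risks, and accumulates
#' half-cycle-corrected, discounted costs and QALYs.
#'
#' @param bundle A validated `pa_bundle`.
#' @param strategy Intervention name, one-row spec, or `NULL`/`"none"` for no
#'   intervention.
#' @param horizon Number of annual cycles (default: exit - entry age, 65).
#' @return A `pa_trace`: per-cycle accumulators, start-of-cycle occupancy by
#'   sex and state, and total / per-person discounted costs and QALYs.
#' @export
run_cohort <- function(bundle, strategy = NULL, horizon = NULL) {
  s <- bundle$settings
  if (is.null(horizon)) horizon <- s$exit_age - s$entry_age
  if (horizon <= 0) stop("horizon must be >= 1 cycle", call. = FALSE)
  if (horizon > s$exit_age - s$entry_age)
    stop("horizon exceeds exit - entry age", call. = FALSE)
  if (is.character(strategy) && length(strategy) == 1L &&
      strategy %in% c("none", "no_intervention")) strategy <- NULL
  if (is.character(strategy)) strategy <- get_intervention(bundle, strategy)
  strat_name <- if (is.null(strategy)) "no_intervention" else strategy$name

  rk <- prepare_risk(bundle, horizon)
  rw <- prepare_rewards(bundle, horizon)
  dp <- prepare_death_probs(bundle, rk, horizon)
  disc <- discount_factor(seq_len(horizon) - as.integer(!s$discount_first_cycle),
                          s$discount_rate)

  n_by_sex <- c(male = s$cohort_size * s$male_fraction,
                female = s$cohort_size * (1 - s$male_fraction))
  states <- health_states()
  occupancy <- array(0, c(horizon + 1L, 11L, 2L),
                     dimnames = list(NULL, states, SEXES))
  cost_cyc <- qaly_cyc <- numeric(horizon)
  act_paths <- list()

  for (sx in SEXES) {
    N <- n_by_sex[[sx]]
    path <- activity_path(bundle, sx, horizon, strategy)
    act_paths[[sx]] <- t(vapply(path, function(d) d$shares, numeric(4)))
    healthy <- N
    D <- matrix(0, length(DISEASES), horizon + 1L,
                dimnames = list(DISEASES, NULL))
    dead <- 0
    occupancy[1L, ACTIVITY_LEVELS, sx] <- N * path[[1L]]$shares
    r <- rk[[sx]]
    Pd <- dp[[sx]]

    for (k in seq_len(horizon)) {
      hl <- healthy * path[[k]]$shares
      ## start-of-cycle annual reward rates (age = entry + k - 1)
      q_start <- sum(hl * rw$u_base[k, ]) + sum(rw$u_d * rowSums(D))
      c_start <- sum(rw$c_first * D[, 1L]) +
        sum(rw$c_subs * rowSums(D[, -1L, drop = FALSE]))

      ## competing transitions out of the healthy levels
      P <- rbind(r$p_level[, , k], oc = r$p_oc[k])  # 7 x 4
      h <- -log1p(-pmin(P, 1 - 1e-15))
      H <- colSums(h)
      Ptot <- -expm1(-H)
      q <- sweep(h, 2L, ifelse(H > 0, Ptot / H, 0), `*`)
      stay <- 1 - Ptot
      entrants <- as.vector(q[seq_along(DISEASES), , drop = FALSE] %*% hl)
      fatal <- entrants * rk$fatal_fraction
      oc_deaths <- sum(q["oc", ] * hl)
      hl_end <- hl * stay

      ## disease tenure advance with tenure-specific death risk
      Dnew <- matrix(0, length(DISEASES), horizon + 1L,
                     dimnames = dimnames(D))
      d_deaths <- 0
      if (k > 1L) {
        tv <- seq_len(k - 1L)
        for (di in seq_along(DISEASES)) {
          occ <- D[di, tv]
          pdeath <- Pd[[di]][k, tv]
          d_deaths <- d_deaths + sum(occ * pdeath)
          Dnew[di, tv + 1L] <- occ * (1 - pdeath)
        }
      }
      Dnew[, 1L] <- entrants - fatal
      dead <- dead + oc_deaths + sum(fatal) + d_deaths
      healthy <- sum(hl_end)
      D <- Dnew

      ## end-of-cycle annual reward rates (age = entry + k)
      q_end <- sum(hl_end * rw$u_base[k + 1L, ]) + sum(rw$u_d * rowSums(D))
      c_end <- sum(rw$c_first * D[, 1L]) +
        sum(rw$c_subs * rowSums(D[, -1L, drop = FALSE]))

      qaly_cyc[k] <- qaly_cyc[k] + (q_start + q_end) / 2
      cost_cyc[k] <- cost_cyc[k] + (c_start + c_end) / 2 +
        sum(fatal * rw$c_fatal)

      occupancy[k + 1L, ACTIVITY_LEVELS, sx] <- hl_end
      occupancy[k + 1L, DISEASES, sx] <- rowSums(D)
      occupancy[k + 1L, "dead", sx] <- dead
    }
  }

  intervention_cost <- if (is.null(strategy)) 0 else
    s$cohort_size * strategy$cost_per_participant

  cycles <- data.frame(
    cycle = 0:horizon,
    age = s$entry_age + 0:horizon,
    cost_undisc = c(intervention_cost, cost_cyc),
    cost_disc = c(intervention_cost, cost_cyc * disc),
    qaly_undisc = c(0, qaly_cyc),
    qaly_disc = c(0, qaly_cyc * disc)
  )
  totals <- list(
    cost = sum(cycles$cost_disc), qaly = sum(cycles$qaly_disc),
    cost_undisc = sum(cycles$cost_undisc), qaly_undisc = sum(cycles$qaly_undisc),
    cost_per_person = sum(cycles$cost_disc) / s$cohort_size,
    qaly_per_person = sum(cycles$qaly_disc) / s$cohort_size
  )
  out <- list(strategy = strat_name, horizon = horizon,
              settings = s, cycles = cycles, occupancy = occupancy,
              activity = act_paths, totals = totals)
  class(out) <- "pa_trace"
  out
}

#' Total occupancy per cycle
#'
#' Sums occupancy over all 11 states and both sexes at every cycle boundary;
#' a conserved total equal to the cohort size is the model's internal
#' validity check.
#'
#' @param trace A `pa_trace`.
#' @return Numeric vector of length `horizon + 1`.
#' @export
population_totals <- function(trace) {
  apply(trace$occupancy, 1L, sum)
}

#' Export a trace as a long per-cycle table
#'
#' @param trace A `pa_trace`.
#' @return data.frame with columns `cycle`, `age`, `sex`, `state`, `occupancy`.
#' @export
trace_to_table <- function(trace) {
  occ <- trace$occupancy
  df <- expand.grid(cycle = 0:trace$horizon, state = health_states(),
                    sex = SEXES, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$age <- trace$settings$entry_age + df$cycle
  df$occupancy <- as.vector(occ)
  df[, c("cycle", "age", "sex", "state", "occupancy")]
}

#' @export
print.pa_trace <- function(x, ...) {
  cat(sprintf("<pa_trace> strategy=%s, %d cycles\n", x$strategy, x$horizon))
  cat(sprintf("  discounted totals: cost GBP %.2f, QALYs %.3f (per person: %.2f / %.4f)\n",
              x$totals$cost, x$totals$qaly,
              x$totals$cost_per_person, x$totals$qaly_per_person))
  invisible(x)
}
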