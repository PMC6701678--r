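## Incremental economics and probabilistic sensitivity analysis ---------------

#' Per-strategy cost and QALY totals
#'
#' Extracts the discounted per-person totals from a trace (the scale on which
#' incremental results are reported).
#'
#' @param trace A `pa_trace`.
#' @return One-row data.frame: `strategy`, `cost`, `qaly` (per person),
#'   `total_cost`, `total_qaly` (whole cohort).
#' @export
strategy_result <- function(trace) {
  data.frame(strategy = trace$strategy,
             cost = trace$totals$cost_per_person,
             qaly = trace$totals$qaly_per_person,
             total_cost = trace$totals$cost,
             total_qaly = trace$totals$qaly,
             stringsAsFactors = FALSE)
}

#' Incremental cost-effectiveness ratio
#'
#' Computes the cost and QALY increments of `alt` over `base` from unrounded
#' totals and classifies the comparison: `"icer"` (ratio reported),
#' `"dominant"` (cheaper and at least as effective), `"dominated"` (costlier
#' and no more effective), or `"undefined"` (no QALY difference).
#'
#' @param base,alt Results with `cost` and `qaly` fields (e.g. from
#'   [strategy_result()]) on the same horizon and settings.
#' @param tol Differences smaller than `tol` in absolute value are treated as
#'   zero when classifying (guards against floating-point noise in totals);
#'   the reported increments themselves are never rounded.
#' @return List of class `pa_econ`: `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` unless flag is `"icer"`), `flag`, `comparison`.
#' @export
icer <- function(base, alt, tol = 1e-9) {
  dc <- alt$cost - base$cost
  dq <- alt$qaly - base$qaly
  dc_cls <- if (abs(dc) <= tol) 0 else dc
  dq_cls <- if (abs(dq) <= tol) 0 else dq
  if (dq_cls == 0) {
    flag <- "undefined"; ratio <- NA_real_
  } else if (dc_cls <= 0 && dq_cls > 0) {
    flag <- "dominant"; ratio <- NA_real_
  } else if (dc_cls >= 0 && dq_cls < 0) {
    flag <- "dominated"; ratio <- NA_real_
  } else {
    flag <- "icer"; ratio <- dc / dq
  }
  out <- list(delta_cost = dc, delta_qaly = dq, icer = ratio, flag = flag,
              comparison = paste(alt$strategy %||% "alt", "vs",
                                 base$strategy %||% "base"))
  class(out) <- "pa_econ"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pa_econ <- function(x, ...) {
  cat(sprintf("<pa_econ> %s: dC = %.2f, dQ = %.5f, %s\n", x$comparison,
              x$delta_cost, x$delta_qaly,
              if (x$flag == "icer") sprintf("ICER = %.0f", x$icer) else x$flag))
  invisible(x)
}

#' Net monetary benefit
#'
#' `lambda * QALYs - cost` at willingness-to-pay `lambda`. For incremental
#' quantities, pass increments; `NMB > 0` is equivalent to `ICER < lambda`
#' when the QALY gain is positive.
#'
#' @param result List or row with `cost` and `qaly` fields.
#' @param lambda Willingness-to-pay threshold (GBP per QALY, >= 0).
#' @return Monetary value (GBP).
#' @export
nmb <- function(result, lambda) {
  stopifnot(lambda >= 0)
  lambda * result$qaly - result$cost
}

## Method-of-moments samplers (degenerate SE returns the mean) ----------------

sample_beta <- function(m, se) {
  if (se == 0) return(m)
  if (m <= 0 || m >= 1) stop("beta mean must be in (0,1) when SE > 0",
                             call. = FALSE)
  if (se^2 >= m * (1 - m))
    stop(sprintf("beta SE %.4g incompatible with mean %.4g", se, m),
         call. = FALSE)
  ab <- m * (1 - m) / se^2 - 1
  stats::rbeta(1L, m * ab, (1 - m) * ab)
}

sample_gamma <- function(m, se) {
  if (se == 0 || m == 0) return(m)
  shape <- (m / se)^2
  stats::rgamma(1L, shape = shape, scale = m / shape)
}

sample_lognormal_ci <- function(m, lo, hi) {
  sdlog <- (log(hi) - log(lo)) / (2 * 1.96)
  if (!is.finite(sdlog) || sdlog == 0) return(m)
  stats::rlnorm(1L, meanlog = log(m), sdlog = sdlog)
}

sample_normal_ci <- function(m, lo, hi) {
  se <- (hi - lo) / (2 * 1.96)
  if (se == 0) return(m)
  stats::rnorm(1L, m, se)
}

#' Draw a perturbed parameter bundle
#'
#' One Monte-Carlo draw of every uncertain parameter from its assigned
#' family: utilities, event fractions, case-fatality and net-survival
#' probabilities and reference incidence follow beta distributions
#' (method-of-moments from mean and SE); costs follow gamma distributions
#' (shape `(m/SE)^2`, scale `m/shape`); relative risks, post-event
#' multipliers and hazard ratios follow lognormal distributions with log-SD
#' `(log hi - log lo) / (2 * 1.96)` from their 95% CI; intervention effect
#' sizes (mean differences that may be negative) are sampled normally from
#' their 95% CI. Incidence curves are scaled by the draw of their reference
#' rate (age 40). Zero-SE (or degenerate-CI) parameters stay at their means,
#' so a bundle with all SEs zero reproduces the deterministic base case.
#' Uses the current RNG stream; set a seed for reproducibility.
#'
#' @param bundle A `pa_bundle`.
#' @param seed Optional integer seed.
#' @return List: `bundle` (perturbed, validated) and `draws` (named numeric
#'   vector logging every sampled value).
#' @export
sample_parameters <- function(bundle, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- bundle
  draws <- c()
  log_draw <- function(name, value) draws[[name]] <<- value

  du <- b$disease_utilities
  for (i in seq_len(nrow(du))) {
    v <- sample_beta(du$utility[i], du$se[i])
    log_draw(paste0("utility.", du$disease[i]), v)
    b$disease_utilities$utility[i] <- v
  }
  bu <- b$baseline_utilities
  for (i in seq_len(nrow(bu))) {
    v <- sample_beta(bu$utility[i], bu$se[i])
    log_draw(paste0("base_utility.", bu$age_group[i], ".", bu$level[i]), v)
    b$baseline_utilities$utility[i] <- v
  }
  ## the utility grid must stay monotone inactive -> high within an age group
  for (g in unique(b$baseline_utilities$age_group)) {
    idx <- which(b$baseline_utilities$age_group == g)
    idx <- idx[match(ACTIVITY_LEVELS, b$baseline_utilities$level[idx])]
    b$baseline_utilities$utility[idx] <-
      sort(b$baseline_utilities$utility[idx])
  }

  dc <- b$disease_costs
  for (i in seq_len(nrow(dc))) {
    v <- sample_gamma(dc$cost[i], dc$se[i])
    log_draw(paste0("cost.", dc$disease[i], ".", dc$phase[i]), v)
    b$disease_costs$cost[i] <- v
  }

  rr <- b$relative_risks
  for (i in seq_len(nrow(rr))) {
    if (rr$level[i] == "inactive") next
    v <- sample_lognormal_ci(rr$rr[i], rr$ci_low[i], rr$ci_high[i])
    log_draw(paste0("rr.", rr$disease[i], ".", rr$level[i]), v)
    b$relative_risks$rr[i] <- v
  }

  mo <- b$mortality
  for (i in seq_len(nrow(mo))) {
    v <- switch(mo$param[i],
      fatal_fraction = ,
      first_year_death = ,
      net_survival_5yr = sample_beta(mo$value[i], mo$se[i]),
      post_multiplier = ,
      mortality_hr = sample_lognormal_ci(mo$value[i], mo$ci_low[i],
                                         mo$ci_high[i]))
    log_draw(paste0("mortality.", mo$disease[i], ".", mo$param[i]), v)
    b$mortality$value[i] <- v
  }

  hf <- b$hf_case_fatality
  for (i in seq_len(nrow(hf))) {
    v <- sample_beta(hf$death_prob[i], hf$se[i])
    log_draw(paste0("hf_case_fatality.year", hf$year[i]), v)
    b$hf_case_fatality$death_prob[i] <- v
  }

  iu <- b$incidence_uncertainty
  ref_age <- 40L
  for (d in DISEASES) for (sx in SEXES) {
    sel <- b$incidence$disease == d & b$incidence$sex == sx
    ref <- b$incidence$rate[sel & b$incidence$age == ref_age]
    sef <- iu$se_fraction[iu$disease == d]
    v <- sample_beta(ref, sef * ref)
    log_draw(paste0("incidence.", d, ".", sx), v)
    if (ref > 0) b$incidence$rate[sel] <- b$incidence$rate[sel] * (v / ref)
  }

  iv <- b$interventions
  for (i in seq_len(nrow(iv))) {
    v <- max(sample_normal_ci(iv$delta_mvpa_daily[i], iv$ci_low[i],
                              iv$ci_high[i]), 0)
    log_draw(paste0("delta_mvpa.", iv$name[i]), v)
    b$interventions$delta_mvpa_daily[i] <- v
  }

  list(bundle = b, draws = unlist(draws))
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation: each iteration draws one perturbed bundle with
#' [sample_parameters()] and runs every strategy on it (common random numbers
#' across arms — all arms see the same draw), recording per-person discounted
#' cost and QALYs.
#'
#' @param bundle A `pa_bundle`.
#' @param strategies Character vector of strategies; `"no_intervention"` (or
#'   `"none"`) is the usual comparator.
#' @param iterations Number of iterations (default from
#'   `settings$psa_iterations`, 2000).
#' @param seed RNG seed (default from settings).
#' @param horizon Cycles per run (default lifetime).
#' @return Object of class `pa_psa`: `results` (iteration x strategy long
#'   data.frame of per-person cost/QALY), `draws` (iterations x parameters
#'   matrix), `seed`, `strategies`.
#' @export
run_psa <- function(bundle, strategies = c("no_intervention", "after_school",
                                           "multicomponent"),
                    iterations = bundle$settings$psa_iterations,
                    seed = bundle$settings$seed, horizon = NULL) {
  stopifnot(iterations >= 1)
  set.seed(seed)
  res <- vector("list", iterations)
  draws <- NULL
  for (it in seq_len(iterations)) {
    sp <- sample_parameters(bundle)
    if (is.null(draws))
      draws <- matrix(NA_real_, iterations, length(sp$draws),
                      dimnames = list(NULL, names(sp$draws)))
    draws[it, ] <- sp$draws
    rows <- lapply(strategies, function(st) {
      out <- strategy_result(run_cohort(sp$bundle, st, horizon))
      out$iteration <- it
      out
    })
    res[[it]] <- do.call(rbind, rows)
  }
  out <- list(results = do.call(rbind, res), draws = draws, seed = seed,
              strategies = sub("^none$", "no_intervention", strategies),
              iterations = iterations)
  class(out) <- "pa_psa"
  out
}

#' @export
print.pa_psa <- function(x, ...) {
  cat(sprintf("<pa_psa> %d iterations x %d strategies (seed %s)\n",
              x$iterations, length(x$strategies), format(x$seed)))
  agg <- stats::aggregate(cbind(cost, qaly) ~ strategy, data = x$results, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold on the lambda grid, the fraction of PSA iterations in
#' which a strategy's net monetary benefit strictly exceeds the comparator's
#' (ties count as not cost-effective). Pairwise against the comparator by
#' default; `method = "best"` instead reports the probability that the
#' strategy has the highest NMB among all strategies in the cloud.
#'
#' @param psa A `pa_psa`.
#' @param comparator Comparator strategy name.
#' @param lambda_grid Thresholds (GBP/QALY), default 0 to 50,000 step 1,000.
#' @param method `"pairwise"` or `"best"`.
#' @return data.frame: `lambda`, `strategy`, `probability`.
#' @export
ceac <- function(psa, comparator = "no_intervention",
                 lambda_grid = seq(0, 50000, by = 1000),
                 method = c("pairwise", "best")) {
  method <- match.arg(method)
  res <- psa$results
  if (!comparator %in% res$strategy)
    stop("comparator '", comparator, "' not in PSA cloud", call. = FALSE)
  strategies <- setdiff(unique(res$strategy), comparator)
  all_st <- unique(res$strategy)
  pick <- function(col) vapply(all_st, function(st) {
    r <- res[res$strategy == st, ]
    r[[col]][order(r$iteration)]
  }, numeric(psa$iterations))
  wide_c <- matrix(pick("cost"), ncol = length(all_st),
                   dimnames = list(NULL, all_st))
  wide_q <- matrix(pick("qaly"), ncol = length(all_st),
                   dimnames = list(NULL, all_st))
  out <- lapply(lambda_grid, function(lam) {
    nb <- lam * wide_q - wide_c
    p <- if (method == "pairwise") {
      vapply(strategies, function(st) mean(nb[, st] > nb[, comparator]),
             numeric(1))
    } else {
      best <- colnames(nb)[max.col(nb, ties.method = "first")]
      vapply(strategies, function(st) mean(best == st), numeric(1))
    }
    data.frame(lambda = lam, strategy = strategies, probability = unname(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Deterministic scenario grid
#'
#' Re-runs the model over decay-rate and time-horizon scenarios and reports,
#' per scenario and strategy, the per-person total cost, total QALYs, cost
#' and QALY increments versus no intervention, and the ICER — the layout of
#' the base-case / sensitivity results table. The default grid is the base
#' case (50% decay, lifetime), decay 0%, 33% and 100%, and 10- and 20-year
#' horizons.
#'
#' @param bundle A `pa_bundle`.
#' @param strategies Intervention names to evaluate.
#' @param scenarios data.frame with columns `scenario`, `decay`
#'   (`NA` = keep the bundle's decay rates) and `horizon` (`NA` = lifetime).
#' @return data.frame of class `pa_scenarios`.
#' @export
scenario_table <- function(bundle,
                           strategies = c("after_school", "multicomponent"),
                           scenarios = NULL) {
  if (is.null(scenarios)) {
    scenarios <- data.frame(
      scenario = c("base_case", "decay_0", "decay_33", "decay_100",
                   "horizon_10", "horizon_20"),
      decay = c(0.5, 0, 0.33, 1, 0.5, 0.5),
      horizon = c(NA, NA, NA, NA, 10, 20)
    )
  }
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    b <- bundle
    if (!is.na(sc$decay)) b$interventions$decay_rate <- sc$decay
    hz <- if (is.na(sc$horizon)) NULL else sc$horizon
    base <- strategy_result(run_cohort(b, NULL, hz))
    out <- lapply(strategies, function(st) {
      alt <- strategy_result(run_cohort(b, st, hz))
      ec <- icer(base, alt)
      data.frame(scenario = sc$scenario, strategy = st,
                 cost = alt$cost, qaly = alt$qaly,
                 delta_cost = ec$delta_cost, delta_qaly = ec$delta_qaly,
                 icer = ec$icer, flag = ec$flag, stringsAsFactors = FALSE)
    })
    rbind(data.frame(scenario = sc$scenario, strategy = "no_intervention",
                     cost = base$cost, qaly = base$qaly,
                     delta_cost = NA_real_, delta_qaly = NA_real_,
                     icer = NA_real_, flag = "", stringsAsFactors = FALSE),
          do.call(rbind, out))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pa_scenarios", class(out))
  out
}

#' Cost-effectiveness plane scatter plot
#'
#' Incremental cost vs incremental QALYs of each PSA iteration relative to
#' the comparator. Requires ggplot2.
#'
#' @param psa A `pa_psa`.
#' @param comparator Comparator strategy.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, comparator = "no_intervention") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  res <- psa$results
  base <- res[res$strategy == comparator, ]
  inc <- do.call(rbind, lapply(setdiff(unique(res$strategy), comparator),
    function(st) {
      r <- res[res$strategy == st, ]
      data.frame(strategy = st,
                 delta_cost = r$cost - base$cost[match(r$iteration,
                                                       base$iteration)],
                 delta_qaly = r$qaly - base$qaly[match(r$iteration,
                                                       base$iteration)])
    }))
  ggplot2::ggplot(inc, ggplot2::aes(delta_qaly, delta_cost,
                                    colour = strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0) + ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALYs per person",
                  y = "Incremental cost per person (GBP)")
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param ceac_df Output of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(ceac_df, ggplot2::aes(lambda, probability,
                                        colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "P(cost-effective vs comparator)")
}

utils::globalVariables(c("delta_qaly", "delta_cost", "strategy",
                         "lambda", "probability"))
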