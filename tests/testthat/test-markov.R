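test_that("half-cycle correction credits the trapezoid of occupancy", {
  expect_equal(half_cycle_value(1000, 1000, 0.7), 700)
  expect_equal(half_cycle_value(1, 0, 1), 0.5)
  # linear decline over k cycles equals the trapezoid integral
  occ <- seq(100, 0, length.out = 11)
  total <- sum(half_cycle_value(occ[-11], occ[-1], 1))
  expect_equal(total, sum(diff(seq_along(occ)) * (occ[-11] + occ[-1]) / 2))
})

test_that("discount factors match the NICE 3.5% reference case", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(1, 0.035), 0.966184, tolerance = 1e-6)
  expect_equal(discount_factor(10, 0.035), 0.708919, tolerance = 1e-6)
})

test_that("a decade in the CHD state at utility 0.65 accrues 6.5 QALYs", {
  b <- the_bundle()
  disease <- matrix(0, 6, 2, dimnames = list(mvpasim:::DISEASES, NULL))
  disease["chd", 2] <- 1   # one person beyond the first disease year
  r <- cycle_rewards(b, age = 50, healthy = rep(0, 4), disease = disease)
  expect_equal(10 * r$qaly, 6.5)
  # one person-year of type 2 diabetes beyond year 1 costs 1257
  disease[] <- 0; disease["type2_diabetes", 2] <- 1
  r <- cycle_rewards(b, age = 50, healthy = rep(0, 4), disease = disease)
  expect_equal(r$cost, 1257)
  # dead-only occupancy earns nothing
  r <- cycle_rewards(b, age = 50, healthy = rep(0, 4))
  expect_equal(c(r$cost, r$qaly), c(0, 0))
})

test_that("population is conserved at every cycle in every scenario", {
  b <- the_bundle()
  N <- b$settings$cohort_size
  for (st in list(NULL, "after_school", "multicomponent")) {
    tr <- run_cohort(b, st)
    expect_true(max(abs(population_totals(tr) - N)) < 1e-6)
  }
  b$interventions$decay_rate <- 0
  tr <- run_cohort(b, "after_school", horizon = 20)
  expect_true(max(abs(population_totals(tr) - N)) < 1e-6)
})

test_that("cohort expectation equals exhaustive path enumeration on a toy
           three-state bundle", {
  b <- toy_bundle(cohort = 1)
  horizon <- 5
  expected <- toy_oracle(horizon)
  tr <- run_cohort(b, NULL, horizon = horizon)
  expect_equal(tr$totals$qaly, unname(expected["qaly"]), tolerance = 1e-10)
  expect_equal(tr$totals$cost, unname(expected["cost"]), tolerance = 1e-10)
  expect_true(max(abs(population_totals(tr) - 1)) < 1e-12)
})

test_that("zero discount rate makes discounted and undiscounted totals equal", {
  b <- the_bundle()
  b$settings$discount_rate <- 0
  tr <- run_cohort(b, "after_school", horizon = 30)
  expect_equal(tr$totals$cost, tr$totals$cost_undisc)
  expect_equal(tr$totals$qaly, tr$totals$qaly_undisc)
  # and with the default rate, discounting can only shrink totals
  tr2 <- run_cohort(the_bundle(), "after_school", horizon = 30)
  expect_lt(tr2$totals$qaly, tr2$totals$qaly_undisc)
  expect_lt(tr2$totals$cost, tr2$totals$cost_undisc)
})

test_that("QALY totals grow monotonically with the horizon", {
  b <- the_bundle()
  q <- vapply(c(10, 20, 65),
              function(h) run_cohort(b, NULL, h)$totals$qaly, numeric(1))
  expect_true(all(diff(q) > 0))
})

test_that("the cohort expectation is deterministic", {
  b <- the_bundle()
  t1 <- run_cohort(b, "multicomponent", horizon = 20)
  t2 <- run_cohort(b, "multicomponent", horizon = 20)
  expect_identical(t1, t2)
})

test_that("traces export as tidy long tables", {
  tr <- run_cohort(the_bundle(), NULL, horizon = 3)
  tab <- trace_to_table(tr)
  expect_named(tab, c("cycle", "age", "sex", "state", "occupancy"))
  expect_equal(nrow(tab), 4 * 11 * 2)
  expect_equal(sum(tab$occupancy[tab$cycle == 3]),
               tr$settings$cohort_size, tolerance = 1e-6)
})

test_that("invalid horizons are rejected", {
  b <- the_bundle()
  expect_error(run_cohort(b, NULL, horizon = 0), "horizon")
  expect_error(run_cohort(b, NULL, horizon = 66), "exceeds")
})
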