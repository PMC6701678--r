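test_that("weekly MVPA maps to the half-open level intervals", {
  expect_equal(categorize_mvpa(c(0, 29.9, 30, 149.9, 150, 420.5, 421, 1000)),
               c("inactive", "inactive", "low", "low", "moderate", "moderate",
                 "high", "high"))
  expect_error(categorize_mvpa(-1), ">= 0")
})

test_that("intervention effect is sustained then decays exponentially", {
  expect_equal(effect_multiplier(1, d = 0.5), 1)
  expect_equal(effect_multiplier(3, d = 0.5, sustain_years = 1), 0.25)
  expect_equal(effect_multiplier(2, d = 1), 0)
  expect_equal(effect_multiplier(10, d = 0), 1)
  expect_error(effect_multiplier(1, d = 1.2), "\\[0,1\\]")
})

test_that("uplift promotes the uniform-within-interval fraction", {
  dist <- new_activity_distribution(c(0.25, 0.25, 0.25, 0.25))
  # identity at zero shift
  expect_equal(apply_uplift(dist, 0)$shares, dist$shares)
  # 7.0 min/day: low level [30,150) promotes 49/120
  up <- apply_uplift(new_activity_distribution(c(0, 1, 0, 0)), 7.0, 1)
  expect_equal(unname(up$shares[["moderate"]]), 49 / 120, tolerance = 1e-12)
  # 4.84 min/day: moderate [150,421) promotes 33.88/271
  up <- apply_uplift(new_activity_distribution(c(0, 0, 1, 0)), 4.84, 1)
  expect_equal(unname(up$shares[["high"]]), 33.88 / 271, tolerance = 1e-12)
  expect_equal(sum(up$shares), 1, tolerance = 1e-12)
})

test_that("uplift is monotone: more minutes never lowers the upper tail", {
  set.seed(3)
  for (i in 1:20) {
    s <- stats::runif(4)
    dist <- new_activity_distribution(s / sum(s))
    deltas <- sort(stats::runif(2, 0, 20))
    a <- apply_uplift(dist, deltas[1])$shares
    b <- apply_uplift(dist, deltas[2])$shares
    # cumulative share at-or-above each level is non-decreasing in delta
    expect_true(all(rev(cumsum(rev(b))) - rev(cumsum(rev(a))) >= -1e-12))
  }
})

test_that("seven annual decline steps reproduce the adolescence-to-adulthood
           fall in weekly MVPA", {
  b <- the_bundle()
  for (sx in mvpasim:::SEXES) {
    d0 <- baseline_activity(b, sx, 16)
    d <- d0
    for (age in 17:23) d <- secular_decline(d, sx, age, b)
    dec <- if (sx == "male") 6.5 else 5.5
    expect_equal(unname(d0$mean_mvpa - d$mean_mvpa), rep(7 * dec, 4),
                 tolerance = 1e-12)  # 45.5 (boys) / 38.5 (girls) weekly min
    expect_equal(sum(d$shares), 1, tolerance = 1e-12)
    # decline only demotes: inactive grows, high shrinks
    expect_gt(d$shares[["inactive"]], d0$shares[["inactive"]])
    expect_lt(d$shares[["high"]], d0$shares[["high"]])
  }
})

test_that("girls decline 5.5/6.5 as fast as boys each year", {
  b <- the_bundle()
  start <- new_activity_distribution(c(0.25, 0.25, 0.25, 0.25))
  boy <- secular_decline(start, "male", 18, b)
  girl <- secular_decline(start, "female", 18, b)
  drop_boy <- start$shares - boy$shares
  drop_girl <- start$shares - girl$shares
  keep <- abs(drop_boy) > 1e-12
  expect_equal(unname(drop_girl[keep] / drop_boy[keep]),
               rep(5.5 / 6.5, sum(keep)), tolerance = 1e-12)
})

test_that("band boundaries re-target the distribution to adult prevalence", {
  b <- the_bundle()
  path <- activity_path(b, "male", 12)
  # cycle 9 starts at age 24: shares equal the 24-44 band prevalence
  ap <- b$activity_prevalence
  band <- ap[ap$sex == "male" & ap$age_band == "24-44", ]
  expect_equal(unname(path[[9]]$shares),
               band$share[match(mvpasim:::ACTIVITY_LEVELS, band$level)])
  # within the band, no further drift
  expect_equal(path[[10]]$shares, path[[9]]$shares)
})

test_that("arms converge by year 8 under base-case decay but not without decay", {
  b <- the_bundle()
  expect_true(converged_by(new_activity_distribution(c(0.1, 0.2, 0.3, 0.4)),
                           new_activity_distribution(c(0.1, 0.2, 0.3, 0.4))))
  for (sx in mvpasim:::SEXES) {
    expect_true(arms_converged_at(b, "after_school", year = 8, sex = sx))
    expect_false(arms_converged_at(b, "after_school", year = 2, sex = sx))
  }
  nodecay <- b
  nodecay$interventions$decay_rate <- 0
  expect_false(arms_converged_at(nodecay, "after_school", year = 8))
})

test_that("full decay makes the arms identical from year 2 onward", {
  b <- the_bundle()
  b$interventions$decay_rate <- 1
  ctrl <- activity_path(b, "female", 10)
  int <- activity_path(b, "female", 10, "multicomponent")
  for (k in 2:10) expect_equal(int[[k]]$shares, ctrl[[k]]$shares)
  expect_false(isTRUE(all.equal(int[[1]]$shares, ctrl[[1]]$shares)))
})

test_that("shares stay normalised and non-negative through every operation", {
  b <- the_bundle()
  for (sx in mvpasim:::SEXES) {
    for (path in list(activity_path(b, sx, 65),
                      activity_path(b, sx, 65, "multicomponent"))) {
      sums <- vapply(path, function(d) sum(d$shares), numeric(1))
      mins <- vapply(path, function(d) min(d$shares), numeric(1))
      expect_true(max(abs(sums - 1)) < 1e-9)
      expect_true(all(mins >= 0))
    }
  }
})
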