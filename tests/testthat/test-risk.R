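test_that("rate/probability conversions are exact and inverse", {
  expect_equal(rate_to_prob(0), 0)
  expect_equal(rate_to_prob(0.01), 0.0099502, tolerance = 1e-5)
  r <- c(0, 0.001, 0.05, 0.4)
  expect_equal(prob_to_rate(rate_to_prob(r)), r, tolerance = 1e-12)
  expect_error(rate_to_prob(-0.1), ">= 0")
  expect_error(prob_to_rate(1), "probability")
})

test_that("relative-risk re-weighting recovers the inactive probability", {
  # no risk gradient: population probability unchanged
  expect_equal(inactive_probability(0.01, c(0.4, 0.3, 0.2, 0.1), rep(1, 4)),
               0.01)
  # hand arithmetic: denominator 0.4 + 0.27 + 0.14 + 0.05 = 0.86
  expect_equal(inactive_probability(0.01, c(0.4, 0.3, 0.2, 0.1),
                                    c(1, 0.9, 0.7, 0.5)),
               0.01 / 0.86, tolerance = 1e-9)
  # all-inactive population
  expect_equal(inactive_probability(0.02, c(1, 0, 0, 0), c(1, 0.5, 0.4, 0.1)),
               0.02)
  expect_error(inactive_probability(0.01, c(1, 0, 0, 0), c(1, 1, 1, 0) * 0),
               "inactive")
})

test_that("re-aggregating level probabilities recovers the population value", {
  set.seed(11)
  for (i in 1:25) {
    w <- as.vector(stats::rmultinom(1, 1000, stats::runif(4))) / 1000
    rr <- c(1, sort(stats::runif(3, 0.3, 1.2), decreasing = TRUE))
    p_all <- stats::runif(1, 0, 0.2)
    p_i <- inactive_probability(p_all, w, rr)
    expect_equal(sum(w * p_i * rr), p_all, tolerance = 1e-12)
  }
})

test_that("other-cause mortality subtracts and floors with a warning", {
  expect_equal(other_cause_mortality(0.02, 0.005), 0.015)
  expect_equal(other_cause_mortality(0.3, 0), 0.3)
  expect_warning(out <- other_cause_mortality(0.004, 0.005), "floored")
  expect_equal(out, 0)
})

test_that("post-event mortality follows the disease-specific rules", {
  b <- the_bundle()
  # stroke beyond year 1: hazard-doubled background, 1 - (1 - p)^2
  mult <- mvpasim:::mort_value(b, "stroke", "post_multiplier")
  expect_equal(mult, 2)
  expect_equal(post_event_mortality("stroke", 2, 0.01, b), 0.0199)
  expect_equal(post_event_mortality("stroke", 5, 0.01, b), 0.0199)
  # stroke first year: case fatality on top of background
  fy <- mvpasim:::mort_value(b, "stroke", "first_year_death")
  expect_equal(post_event_mortality("stroke", 1, 0.01, b),
               1 - (1 - 0.01) * (1 - fy))
  # diabetes with HR = 1 leaves background unchanged
  b1 <- b
  b1$mortality$value[b1$mortality$param == "mortality_hr"] <- 1
  expect_equal(post_event_mortality("type2_diabetes", 3, 0.013, b1), 0.013)
  # naive multiplier scale can exceed 1 and is capped
  b2 <- b
  b2$settings$multiplier_scale <- "naive"
  b2$mortality$value[b2$mortality$disease == "stroke" &
                       b2$mortality$param == "post_multiplier"] <- 4
  expect_equal(post_event_mortality("stroke", 2, 0.4, b2), 1)
  expect_error(post_event_mortality("gout", 1, 0.01, b), "must be one of")
})

test_that("cancer excess risk is annualised from 5-year net survival", {
  expect_equal(cancer_annual_death_risk(1, 1), 0)
  expect_equal(cancer_annual_death_risk(0.59049, 3), 0.1, tolerance = 1e-9)
  expect_equal(cancer_annual_death_risk(0.5, 6), 0)  # no excess beyond year 5
  expect_error(cancer_annual_death_risk(0, 1), "net survival")
})

test_that("transition matrices are row-stochastic with an absorbing dead state", {
  b <- the_bundle()
  mats <- build_matrices(b)
  for (sx in mvpasim:::SEXES) {
    arr <- mats[[sx]]
    sums <- apply(arr, 3, rowSums)
    expect_true(max(abs(sums - 1)) < 1e-12, label = sx)
    expect_true(all(arr >= 0 & arr <= 1))
    expect_true(all(arr["dead", "dead", ] == 1))
    expect_true(all(arr["dead", -11L, ] == 0))
  }
})

test_that("null bundle matrices are identity apart from activity dynamics", {
  mats <- build_matrices(the_null_bundle(), horizon = 10)
  for (sx in mvpasim:::SEXES) {
    arr <- mats[[sx]]
    for (k in 1:10) expect_equal(arr[, , k], diag(11),
                                 ignore_attr = TRUE, tolerance = 1e-15)
  }
})

test_that("entering any disease is weakly less likely from higher activity", {
  b <- the_bundle()
  mats <- build_matrices(b)
  for (sx in mvpasim:::SEXES) {
    arr <- mats[[sx]]
    for (k in seq_along(mats$ages)) {
      p <- arr[mvpasim:::ACTIVITY_LEVELS, mvpasim:::DISEASES, k]
      expect_true(all(apply(p, 2, diff) <= 1e-15),
                  label = sprintf("%s age %d", sx, mats$ages[k]))
    }
  }
})

test_that("matrix export produces a tidy long audit table", {
  mats <- build_matrices(the_bundle(), horizon = 3)
  tab <- matrices_to_table(mats)
  expect_named(tab, c("age", "sex", "from", "to", "probability"))
  expect_true(all(tab$probability > 0 & tab$probability <= 1))
  # probabilities for one (age, sex, from) row still sum to 1
  one <- tab[tab$age == 17 & tab$sex == "female" & tab$from == "moderate", ]
  expect_equal(sum(one$probability), 1, tolerance = 1e-12)
})
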