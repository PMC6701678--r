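res <- function(cost, qaly, strategy = "s") {
  list(strategy = strategy, cost = cost, qaly = qaly)
}

test_that("ICER arithmetic and dominance flags", {
  ec <- icer(res(0, 0, "base"), res(100, 0.01))
  expect_equal(ec$icer, 10000)
  expect_identical(ec$flag, "icer")
  expect_identical(icer(res(10, 1), res(5, 1.01))$flag, "dominant")
  expect_identical(icer(res(10, 1), res(15, 0.99))$flag, "dominated")
  ec <- icer(res(10, 1), res(15, 1))
  expect_identical(ec$flag, "undefined")
  expect_true(is.na(ec$icer))
})

test_that("net monetary benefit and its ICER equivalence", {
  # increments of the base-case after-school comparison
  expect_equal(nmb(res(50.64, 0.004), 20000), 29.36)
  expect_equal(nmb(res(12, 0.5), 0), -12)
  set.seed(5)
  for (i in 1:20) {
    dc <- stats::runif(1, 1, 500); dq <- stats::runif(1, 1e-4, 0.5)
    lam <- stats::runif(1, 0, 5e4)
    expect_equal(nmb(res(dc, dq), lam) > 0, dc / dq < lam)
  }
})

test_that("method-of-moments samplers reproduce their families", {
  # gamma with SE = 10% of mean: shape 100, scale mean/100
  set.seed(1)
  draws <- replicate(4000, mvpasim:::sample_gamma(5562, 556.2))
  expect_equal(mean(draws), 5562, tolerance = 0.01)
  expect_equal(stats::sd(draws), 556.2, tolerance = 0.05)
  # beta mean/SE recovery
  draws <- replicate(4000, mvpasim:::sample_beta(0.65, 0.0203))
  expect_equal(mean(draws), 0.65, tolerance = 0.005)
  expect_equal(stats::sd(draws), 0.0203, tolerance = 0.05)
  # lognormal log-SD from a 95% CI
  expect_equal((log(0.82) - log(0.6)) / (2 * 1.96), 0.0797, tolerance = 1e-3)
  set.seed(2)
  draws <- replicate(4000, mvpasim:::sample_lognormal_ci(0.7, 0.6, 0.82))
  expect_equal(stats::sd(log(draws)), 0.0797, tolerance = 0.05)
  # degenerate SE collapses to a point mass
  expect_equal(replicate(5, mvpasim:::sample_beta(0.5, 0)), rep(0.5, 5))
  expect_equal(replicate(5, mvpasim:::sample_gamma(100, 0)), rep(100, 5))
  # incompatible beta SE rejected
  expect_error(mvpasim:::sample_beta(0.5, 0.6), "incompatible")
})

test_that("sampling a zero-uncertainty bundle returns it unchanged", {
  b <- the_null_bundle()
  sp <- sample_parameters(b, seed = 99)
  expect_identical(sp$bundle, b)
})

test_that("PSA is reproducible and uses common random numbers across arms", {
  b <- the_bundle()
  p1 <- run_psa(b, c("no_intervention", "after_school"), iterations = 4,
                seed = 7, horizon = 10)
  p2 <- run_psa(b, c("no_intervention", "after_school"), iterations = 4,
                seed = 7, horizon = 10)
  expect_identical(p1$results, p2$results)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$results), 8)
})

test_that("PSA with all SEs zero reproduces the deterministic run exactly", {
  b <- the_null_bundle()
  det <- strategy_result(run_cohort(b, "after_school", horizon = 10))
  cloud <- run_psa(b, "after_school", iterations = 3, seed = 1, horizon = 10)
  expect_equal(unique(cloud$results$cost), det$cost)
  expect_equal(unique(cloud$results$qaly), det$qaly)
})

test_that("CEAC probabilities follow the NMB ordering and tie rule", {
  fake <- function(results, iterations) {
    structure(list(results = results, iterations = iterations,
                   strategies = unique(results$strategy)),
              class = "pa_psa")
  }
  # strictly dominant in every iteration: probability 1 at every lambda
  r <- rbind(
    data.frame(iteration = 1:5, strategy = "no_intervention",
               cost = 100, qaly = 1.0),
    data.frame(iteration = 1:5, strategy = "better", cost = 50, qaly = 1.2)
  )
  cc <- ceac(fake(r, 5), lambda_grid = c(0, 10000, 50000))
  expect_equal(cc$probability, rep(1, 3))
  # lambda = 0 reduces to the fraction of iterations with lower cost
  r$cost[r$strategy == "better"] <- c(50, 50, 150, 150, 150)
  cc <- ceac(fake(r, 5), lambda_grid = 0)
  expect_equal(cc$probability, 2 / 5)
  # identical strategies: ties are not cost-effective
  r$cost[r$strategy == "better"] <- 100
  r$qaly[r$strategy == "better"] <- 1.0
  cc <- ceac(fake(r, 5), lambda_grid = c(0, 20000))
  expect_equal(cc$probability, c(0, 0))
  expect_error(ceac(fake(r, 5), comparator = "absent"), "comparator")
})

test_that("scenario grid reports increments and ICERs per scenario", {
  b <- the_bundle()
  tab <- scenario_table(b, strategies = "after_school",
                        scenarios = data.frame(
                          scenario = c("horizon_10", "horizon_20"),
                          decay = 0.5, horizon = c(10, 20)))
  expect_named(tab, c("scenario", "strategy", "cost", "qaly", "delta_cost",
                      "delta_qaly", "icer", "flag"))
  expect_equal(nrow(tab), 4)
  q10 <- tab$qaly[tab$scenario == "horizon_10"]
  q20 <- tab$qaly[tab$scenario == "horizon_20"]
  expect_true(all(q10 < q20))  # QALYs accumulate with the horizon
  ic <- tab$icer[tab$strategy == "after_school"]
  expect_true(all(is.finite(ic) & ic > 0))
})
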