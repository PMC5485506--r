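test_that("cohort runs are bitwise reproducible from (n, seed)", {
  p <- default_parameters()
  r1 <- run_cohort(p, strategy_catalog()[c("no screening", "59y")],
                   n = 5000, seed = 42)
  r2 <- run_cohort(p, strategy_catalog()[c("no screening", "59y")],
                   n = 5000, seed = 42)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- run_cohort(p, strategy_catalog()[c("no screening", "59y")],
                   n = 5000, seed = 43)
  expect_false(identical(r1$risk_dx, r3$risk_dx))
})

test_that("no screening means no tests and no screen detection", {
  ctx <- cohort_context(default_parameters(), 2e4, 31)
  pp <- simulate_strategy(ctx, strategy_spec("no screening"))
  expect_true(all(pp$psa_tests == 0))
  expect_true(all(pp$fp_tests == 0))
  expect_false(any(pp$mode_screen))
})

test_that("zero-sensitivity screening equals no screening exactly under CRN", {
  p <- default_parameters()
  p$detection$screen_sens[] <- 0
  p$detection$psa_specificity <- 1
  ctx <- cohort_context(p, 2e4, 7)
  a <- simulate_strategy(ctx, strategy_spec("no screening"))
  b <- simulate_strategy(ctx, strategy_spec("annual", 55:69))
  expect_identical(a$qald, b$qald)
  expect_identical(a$death_age, b$death_age)
  expect_identical(a$dx_age, b$dx_age)
  expect_identical(a$cause, b$cause)
  expect_true(all(b$psa_tests > 0 | ctx$death_oc <= 55 | a$dx_age <= 55))
})

test_that("diagnosis risk is monotone in the screening-age set person by person", {
  ctx <- cohort_context(default_parameters(), 3e4, 15)
  nested <- list(strategy_spec("one", 55L),
                 strategy_spec("quad", c(55L, 59L, 63L, 67L)),
                 strategy_spec("bien", seq(55L, 69L, 2L)),
                 strategy_spec("annual", 55:69))
  # the quadrennial/biennial/annual sets are nested; detection draws are
  # keyed by age, so diagnosis can only be added, never removed
  pp <- lapply(nested, function(s) simulate_strategy(ctx, s))
  expect_true(all(pp[[1]]$diagnosed <= pp[[4]]$diagnosed))
  expect_true(all(pp[[2]]$diagnosed <= pp[[3]]$diagnosed))
  expect_true(all(pp[[3]]$diagnosed <= pp[[4]]$diagnosed))
})

test_that("a screening strategy does not increase cancer mortality", {
  res <- run_cohort(default_parameters(),
                    strategy_catalog()[c("no screening", "55-69, 1y")],
                    n = 1e5, seed = 3)
  se <- sqrt(res$se_risk_pca_death[1]^2 + res$se_risk_pca_death[2]^2)
  expect_lt(res$risk_pca_death[2], res$risk_pca_death[1] + 3 * se)
})

test_that("microsimulated no-screening risks match the deterministic cohort oracle", {
  p <- default_parameters()
  n <- 15e4
  oracle <- cohort_oracle(p)
  ctx <- cohort_context(p, n, 27)
  pp <- simulate_strategy(ctx, strategy_spec("no screening"))
  dx <- 100 * mean(pp$diagnosed)
  se_dx <- 100 * sqrt(mean(pp$diagnosed) * (1 - mean(pp$diagnosed)) / n)
  expect_lt(abs(dx - oracle$dx_risk), 3 * se_dx)
  pca <- 100 * mean(pp$cause == "pca")
  se_pca <- 100 * sqrt(mean(pp$cause == "pca") * (1 - mean(pp$cause == "pca")) / n)
  expect_lt(abs(pca - oracle$pca_death_risk), 3 * se_pca)
})

test_that("overdiagnosis and overtreatment accounting identities hold exactly", {
  res <- run_cohort(default_parameters(),
                    strategy_catalog()[c("no screening", "64y", "55-64, 2y")],
                    n = 3e4, seed = 10)
  for (i in 2:3) {
    expect_equal(res$risk_overdx[i], res$risk_dx[i] - res$risk_dx[1],
                 tolerance = 1e-12)
    expect_equal(res$overdx_frac[i] * res$risk_screen_dx[i] / 100,
                 res$risk_overdx[i], tolerance = 1e-12)
    expect_equal(res$risk_overtx[i],
                 res$risk_curative[i] - res$risk_curative[1],
                 tolerance = 1e-12)
  }
  # the reference arm compared with itself is all zeros
  expect_equal(res$risk_overdx[1], 0)
  expect_equal(res$qald_gained[1], 0)
  expect_equal(res$life_days_gained[1], 0)
})

test_that("event-order and cycle-convention switches change levels, not contracts", {
  p <- default_parameters()
  res_pf <- run_cohort(p, strategy_catalog()["no screening"], n = 1e4,
                       seed = 5, progression_first = TRUE)
  expect_true(res_pf$risk_dx > 0)
  p$natural_history$cycle_method <- "discrete"
  res_d <- run_cohort(p, strategy_catalog()["no screening"], n = 1e4, seed = 5)
  expect_gt(res_d$risk_dx, 0)
})

test_that("simulate_person traces a single reproducible life", {
  p <- default_parameters()
  a <- simulate_person(p, strategy_spec("annual", 55:69), seed = 77)
  b <- simulate_person(p, strategy_spec("annual", 55:69), seed = 77)
  expect_identical(a, b)
  expect_length(a$death_age, 1)
  expect_true(a$qald <= a$life_days)
})

test_that("index-age conditioning restricts the analysis population", {
  res <- run_cohort(default_parameters(),
                    strategy_catalog()[c("no screening", "64y")],
                    n = 2e4, seed = 8, condition_age = 60)
  expect_lt(attr(res, "n_subset"), 2e4)
  expect_gt(attr(res, "n_subset"), 0.7 * 2e4)
  expect_equal(res$qald_gained[1], 0)
})
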