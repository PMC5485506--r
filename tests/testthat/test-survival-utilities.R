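test_that("life tables load, validate and extend beyond their last age", {
  f <- tempfile(fileext = ".csv")
  write.csv(synthetic_life_table(max_age = 100), f, row.names = FALSE)
  lt <- read_life_table(f)
  expect_lt(lt$q[lt$age == 0], lt$q[lt$age == 80])
  q <- prostasim:::.lt_q_vector(lt)
  expect_equal(q[116], lt$q[nrow(lt)])   # q(115) = last tabulated q
  bad <- synthetic_life_table(max_age = 100)
  bad$q[31] <- 1.7
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_life_table(f), "row 31")
  gap <- synthetic_life_table(max_age = 100)[-5, ]
  write.csv(gap, f, row.names = FALSE)
  expect_error(read_life_table(f), "contiguous")
})

test_that("other-cause death sampling inverts the life-table survival curve", {
  lt <- synthetic_life_table()
  S <- cumprod(1 - prostasim:::.lt_q_vector(lt))
  d <- prostasim:::sample_other_cause_death(2e5, 77, lt)
  # death at age a means cycles 0..a-1 lived: P(d > a) = P(surviving
  # cycles 0..a) = S[a + 1]
  for (a in c(40, 55, 70, 85, 100)) {
    got <- mean(d > a)
    se <- sqrt(S[a + 1] * (1 - S[a + 1]) / 2e5)
    expect_lt(abs(got - S[a + 1]), 3 * se)
  }
  expect_true(all(d >= 0 & d <= 120))
})

test_that("annual utility composes baseline, state, chronic and one-time weights", {
  p <- default_parameters()
  b62 <- prostasim:::baseline_utility(p, 62)
  expect_equal(annual_utility(62, p), b62)
  # surgery year with a diagnostic biopsy: both one-time weights apply once
  expect_equal(annual_utility(62, p, one_time_events = c("RP", "biopsy")),
               b62 * 0.753 * 0.994)
  # chronic adverse events multiply as 1 - m (1 - u)
  expect_equal(annual_utility(62, p, active_aes = c("RP:ED", "RP:UI")),
               b62 * 0.89 * 0.90)
  # the preference multiplier removes (m = 0) or doubles (m = 2) impairment
  p0 <- p; p0$utilities$disutility_multiplier <- 0
  expect_equal(annual_utility(62, p0, active_aes = c("RP:ED", "RT:BD")), b62)
  p2 <- p; p2$utilities$disutility_multiplier <- 2
  expect_equal(annual_utility(62, p2, active_aes = "RP:ED"),
               b62 * (1 - 2 * (1 - 0.89)))
  # distant-state utility replaces the baseline
  expect_equal(annual_utility(62, p, clinical_distant = TRUE,
                              one_time_events = "terminal"), 0.6 * 0.7)
  expect_error(annual_utility(62, p, active_aes = "RP:XX"), "unknown")
  expect_error(annual_utility(62, p, one_time_events = "surgery"), "unknown")
})

test_that("an immortal healthy cohort accrues exactly 120 years of life", {
  p <- default_parameters()
  p$natural_history$exit$no_cancer <- c(p = 0, scale = 80, shape = 8)
  lt <- synthetic_life_table(A = 0, B = 0)
  ctx <- cohort_context(p, 50, 2, life_table = lt)
  pp <- simulate_strategy(ctx, strategy_spec("no screening"))
  expect_true(all(pp$life_days == 120 * 365.25))
  expect_true(all(pp$cause == "horizon"))
  expect_equal(pp$qald, rep(sum(prostasim:::baseline_utility(p, 0:119)) * 365.25, 50))
  # with flat utility of one, QALDs equal life days exactly
  p1 <- apply_scenario(p, scenario_spec(baseline_utility_one = TRUE))
  ctx1 <- cohort_context(p1, 50, 2, life_table = lt)
  pp1 <- simulate_strategy(ctx1, strategy_spec("no screening"))
  expect_equal(pp1$qald, pp1$life_days)
})

test_that("certain death at birth yields zero life days", {
  lt <- synthetic_life_table()
  lt$q[1] <- 1
  ctx <- cohort_context(default_parameters(), 20, 3, life_table = lt)
  pp <- simulate_strategy(ctx, strategy_spec("no screening"))
  expect_true(all(pp$life_days == 0))
  expect_true(all(pp$qald == 0))
})

test_that("a forced distant-diagnosis path accrues the exact QALD ledger", {
  # onset at 1, regional at 2, distant at 3 (splits forced), symptomatic at 3,
  # palliative treatment, certain cancer death at 4: cycles 0-2 at baseline 1,
  # cycle 3 at distant utility 0.6 times the terminal weight 0.7
  p <- default_parameters()
  p$natural_history$exit$no_cancer <- c(p = 1, scale = 0.1, shape = 1)
  for (k in c("localized_Glt7", "regional_Glt7"))
    p$natural_history$exit[[k]] <- c(p = 1, scale = 0.1, shape = 1)
  p$natural_history$stage_split <- c(localized_Glt7 = 1, localized_Geq7 = 0.388,
                                     regional_Glt7 = 1, regional_Geq7 = 0.144)
  p$detection$clinical_detect[] <- 0
  p$detection$clinical_detect[["distant_Glt7"]] <- 1
  p <- apply_scenario(p, scenario_spec(baseline_utility_one = TRUE))
  lt <- synthetic_life_table(A = 0, B = 0)
  rates <- synthetic_postdx_rates()
  rates[] <- 1
  ctx <- cohort_context(p, 25, 8, life_table = lt)
  pp <- simulate_strategy(ctx, strategy_spec("no screening"), postdx = rates)
  expect_true(all(pp$dx_age == 3))
  expect_true(all(pp$dx_state == 7L))
  expect_true(all(pp$proc == 3L))      # ADT
  expect_false(any(pp$cured))
  expect_true(all(pp$death_age == 4))
  expect_true(all(pp$cause == "pca"))
  expect_equal(pp$life_days, rep(4 * 365.25, 25))
  expect_equal(pp$qald, rep((3 + 0.6 * 0.7) * 365.25, 25))
})

test_that("a null post-diagnosis survival model produces no cancer deaths", {
  rates <- synthetic_postdx_rates()
  rates[] <- 0
  ctx <- cohort_context(default_parameters(), 2e4, 13)
  pp <- simulate_strategy(ctx, strategy_spec("no screening"), postdx = rates)
  expect_false(any(pp$cause == "pca"))
  expect_equal(postdx_death_prob(5L, cured = TRUE), 0)
  expect_equal(postdx_death_prob(9L, postdx = rates), 0)
})

test_that("quality-adjusted days never exceed life days", {
  p <- default_parameters(familial = TRUE)
  p$surveillance$enabled <- TRUE
  ctx <- cohort_context(p, 2e4, 19)
  pp <- simulate_strategy(ctx, strategy_spec("55-69 2y AS", seq(55, 69, 2),
                                             surveillance = TRUE))
  expect_true(all(pp$qald <= pp$life_days + 1e-9))
  expect_true(all(pp$qald >= 0))
})
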