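test_that("bundled defaults carry the published base-case values", {
  p <- default_parameters()
  expect_equal(unname(p$natural_history$exit$no_cancer),
               c(0.838, 80.427, 8.448))
  expect_equal(unname(p$natural_history$exit$distant_Geq7),
               c(0.945, 0.806, 4.564))
  expect_equal(unname(p$natural_history$stage_split),
               c(0.158, 0.388, 0.005, 0.144))
  expect_equal(unname(p$detection$clinical_detect),
               c(0.006, 0.110, 0.604, 0.067, 0.108, 0.407,
                 0.233, 0.897, 1.000))
  expect_equal(unname(p$detection$screen_sens),
               c(0.550, 0.370, 0.677, 0.456))
  expect_equal(p$detection$psa_specificity, 0.85)
  expect_equal(p$detection$biopsy_sensitivity, 0.90)
  expect_equal(unname(p$treatment$cure_by_grade), c(0.51, 0.30, 0.11))
  expect_equal(p$treatment$rp_periop_mortality, 0.0015)
  expect_equal(unname(p$treatment$ae_risk$RP), c(0.28, 0.22, 0))
  expect_equal(unname(p$treatment$ae_risk$RT), c(0.15, 0.031, 0.028))
  expect_equal(p$treatment$ae_duration, 5)
  expect_equal(p$utilities$distant_clinical, 0.6)
  expect_equal(unname(p$utilities$ae_utility$RP), c(0.89, 0.90, 0.93))
  expect_equal(unname(p$utilities$ae_utility$RT), c(0.95, 0.93, 0.93))
  expect_equal(unname(p$utilities$one_time), c(0.994, 0.753, 0.772, 0.7))
  expect_false(default_parameters(familial = TRUE)$natural_history$fr != 1.423)
})

test_that("defaults match the bundled YAML and round-trip through it", {
  path <- system.file("extdata", "defaults.yaml", package = "prostasim")
  skip_if(path == "", "bundled defaults.yaml not installed")
  p1 <- default_parameters()
  p2 <- load_parameters(path)
  expect_equal(p1$natural_history[c("exit", "stage_split", "fr")],
               p2$natural_history[c("exit", "stage_split", "fr")])
  expect_equal(p1$utilities$one_time, p2$utilities$one_time)
  tmp <- tempfile(fileext = ".yaml")
  write_parameters(p1, tmp)
  p3 <- load_parameters(tmp)
  for (block in c("natural_history", "detection", "treatment", "surveillance"))
    expect_equal(p1[[block]], p3[[block]])
  expect_equal(p1$utilities$baseline$utility, p3$utilities$baseline$utility)
})

test_that("config overrides merge over defaults and are recorded", {
  p <- load_parameters(list(natural_history = list(fr = 1.423)))
  expect_equal(p$natural_history$fr, 1.423)
  expect_equal(p$natural_history$exit, default_parameters()$natural_history$exit)
  expect_true("natural_history.fr" %in% p$provenance$overridden)
  expect_error(load_parameters(list(natural_history = list(frr = 2))),
               "unknown parameter key")
})

test_that("validation rejects out-of-range and incomplete inputs", {
  expect_error(
    load_parameters(list(natural_history = list(
      exit = list(no_cancer = c(1.2, 80, 8))))),
    "no_cancer")
  expect_error(
    load_parameters(list(detection = list(psa_specificity = 1.5))),
    "\\[0,1\\]")
  p <- default_parameters()
  p$natural_history$exit$distant_Ggt7 <- NULL
  expect_error(validate_parameters(p), "distant_Ggt7")
})

test_that("scenario toggles modify a copy as specified and are idempotent", {
  base <- default_parameters()
  p <- apply_scenario(base, scenario_spec(no_rp_mortality = TRUE))
  expect_equal(p$treatment$rp_periop_mortality, 0)
  expect_equal(base$treatment$rp_periop_mortality, 0.0015)
  p <- apply_scenario(base, scenario_spec(ae_duration_1y = TRUE))
  expect_equal(p$treatment$ae_duration, 1)
  p <- apply_scenario(base, scenario_spec(halve_one_time_disutility = TRUE))
  expect_equal(unname(p$utilities$one_time[["RP"]]), 1 - (1 - 0.753) / 2)
  expect_equal(unname(p$utilities$one_time[["RP"]]), 0.8765)
  expect_equal(unname(p$utilities$one_time[["terminal"]]), 0.7)
  p <- apply_scenario(base, scenario_spec(baseline_utility_one = TRUE))
  expect_true(all(p$utilities$baseline$utility == 1))
  p <- apply_scenario(base, scenario_spec(familial_onset_only = TRUE))
  expect_true(p$natural_history$fr_on_onset)
  expect_false(p$natural_history$fr_on_progression)
  # identity and idempotence
  expect_equal(apply_scenario(base, scenario_spec()), base)
  s <- scenario_spec(halve_one_time_disutility = TRUE)
  expect_equal(apply_scenario(apply_scenario(base, scenario_spec(no_rp_mortality = TRUE)),
                              scenario_spec(no_rp_mortality = TRUE))$treatment$rp_periop_mortality,
               0)
  expect_error(scenario_spec(familial_onset_only = TRUE,
                             familial_progression_only = TRUE),
               "mutually exclusive")
})

test_that("audit CSV export is written and re-readable", {
  tmp <- tempfile(fileext = ".csv")
  flat <- export_parameters_csv(default_parameters(), tmp)
  expect_true(file.exists(tmp))
  back <- read.csv(tmp)
  expect_true(all(c("key", "value", "source") %in% names(back)))
  expect_true(any(grepl("utilities.baseline", back$key, fixed = TRUE) &
                    grepl("synthetic", back$source)))
  expect_equal(
    as.numeric(back$value[back$key == "treatment.rp_periop_mortality"]),
    0.0015)
})
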