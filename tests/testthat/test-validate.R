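test_that("single unverified outpatient records are rejected", {
  pan <- mini_panel(mini_person("a"),
                    mini_dx("a", 2006, 3, "F03", status = "unverified"))
  expect_equal(nrow(validate_diagnoses(pan)), 0L)
})

test_that("two admissible records validate, dated to the first quarter", {
  pan <- mini_panel(mini_person("a"),
                    rbind(mini_dx("a", 2016 - 10, 3, "G30"),
                          mini_dx("a", 2016 - 10, 3, "G30")))
  v <- validate_diagnoses(pan)
  expect_equal(v$first_valid_dx_ym, 12L * 2006 + 7L)  # mid-month of Q3
  # two records in different quarters: valid, dated to the earlier one
  pan2 <- mini_panel(mini_person("b"),
                     rbind(mini_dx("b", 2006, 2, "F03"),
                           mini_dx("b", 2007, 1, "F03",
                                   setting = "inpatient_discharge",
                                   status = "unverified")))
  v2 <- validate_diagnoses(pan2)
  expect_equal(v2$first_valid_dx_ym, 12L * 2006 + 4L)  # May 2006
})

test_that("a single record in the death quarter validates", {
  dead <- mini_person("a", death_ym = 12L * 2007 + 7L)  # Aug 2007, Q3
  pan <- mini_panel(dead, mini_dx("a", 2007, 3, "F01"))
  v <- validate_diagnoses(pan)
  # clamped to the death month so the person dies in the dementia state
  expect_equal(v$first_valid_dx_ym, 12L * 2007 + 7L)
  # same single record while alive through the quarter: rejected
  pan2 <- mini_panel(mini_person("a"), mini_dx("a", 2007, 3, "F01"))
  expect_equal(nrow(validate_diagnoses(pan2)), 0L)
})

test_that("code matching strips dots and respects prefixes", {
  pan <- mini_panel(mini_person("a"),
                    rbind(mini_dx("a", 2006, 2, "F051"),
                          mini_dx("a", 2006, 2, "F05.1")))
  expect_equal(nrow(validate_diagnoses(pan)), 1L)
  # F05.0 must not match the F05.1 prefix; I10 is not dementia
  pan2 <- mini_panel(mini_person("a"),
                     rbind(mini_dx("a", 2006, 2, "F050"),
                           mini_dx("a", 2006, 2, "F05.0"),
                           mini_dx("a", 2006, 3, "I10"),
                           mini_dx("a", 2006, 4, "I10")))
  expect_equal(nrow(validate_diagnoses(pan2)), 0L)
})

test_that("inpatient discharge/secondary records are admissible regardless of status", {
  pan <- mini_panel(mini_person("a"),
                    rbind(mini_dx("a", 2006, 2, setting = "inpatient_discharge",
                                  status = "unverified"),
                          mini_dx("a", 2006, 4, setting = "inpatient_secondary",
                                  status = "unverified")))
  expect_equal(nrow(validate_diagnoses(pan)), 1L)
  expect_error(
    validate_diagnoses(mini_panel(mini_person("a"),
                                  mini_dx("a", 2006, 2, setting = "er"))),
    "unknown setting")
})

test_that("episode construction applies age floor, wash-out and censoring", {
  base <- 12L * 2006
  pans <- mini_panel(rbind(
    mini_person("young", age = 64),
    mini_person("washout_case"),
    mini_person("survivor"),
    mini_person("switcher", coverage_end_ym = base + 17L),
    mini_person("late_entry")),
    rbind(mini_dx("washout_case", 2005, 2), mini_dx("washout_case", 2005, 3)))
  pans$persons$coverage_start_ym[pans$persons$person_id == "late_entry"] <-
    base - 6L  # entered mid-wash-out: not continuously covered
  ep <- build_episodes(pans)
  expect_setequal(ep$person_id, c("survivor", "switcher"))
  s <- ep[ep$person_id == "survivor", ]
  expect_equal(s$censor_ym, base + 36L)
  expect_equal(s$censor_reason, "study_end")
  sw <- ep[ep$person_id == "switcher", ]
  expect_equal(sw$censor_ym, base + 18L)
  expect_equal(sw$censor_reason, "coverage_end")
})

test_that("a wider code set never detects fewer cases; a longer wash-out never enlarges the cohort", {
  pan <- simulate_cohort(quick_sim_config(false_pos_rate = 0.01), "P1")
  narrow <- case_definition(code_set = c("G30", "F00"))
  wide <- case_definition()
  expect_lte(nrow(validate_diagnoses(pan, narrow)),
             nrow(validate_diagnoses(pan, wide)))
  ep2 <- build_episodes(pan, case_definition(washout_years = 2))
  ep0 <- build_episodes(pan, case_definition(washout_years = 0))
  expect_lte(nrow(ep2), nrow(ep0))
})

test_that("isolated unverified false positives are all rejected; paired verified ones leak", {
  cfg <- clean_sim_config(n = 8000, false_pos_rate = 0.01)
  pan <- simulate_cohort(cfg, "P1")
  v <- validate_diagnoses(pan)
  never <- pan$truth$person_id[is.na(pan$truth$onset_ym)]
  # no never-demented person acquires a valid diagnosis...
  expect_length(intersect(v$person_id, never), 0L)
  # ...unless false positives arrive as same-quarter verified pairs
  cfg2 <- clean_sim_config(n = 8000, false_pos_rate = 0.01,
                           paired_false_positives = TRUE)
  pan2 <- simulate_cohort(cfg2, "P1")
  v2 <- validate_diagnoses(pan2)
  never2 <- pan2$truth$person_id[is.na(pan2$truth$onset_ym)]
  expect_gt(length(intersect(v2$person_id, never2)), 0L)
})

test_that("with full recording the detected onset quarter matches the truth", {
  cfg <- clean_sim_config(n = 20000)
  pan <- simulate_cohort(cfg, "P1")
  ep <- build_episodes(pan)
  base <- 12L * pan$baseline_year
  onset <- pan$truth$onset_ym[match(ep$person_id, pan$truth$person_id)]
  cov_end <- pan$persons$coverage_end_ym[match(ep$person_id,
                                               pan$persons$person_id)]
  # onsets during follow-up with at least one later covered quarter
  detectable <- !is.na(onset) & onset >= base &
    (cov_end %/% 3L) > (onset %/% 3L)
  det_rate <- mean(!is.na(ep$first_valid_dx_ym[detectable]))
  expect_gte(det_rate, 0.99)
  hit <- detectable & !is.na(ep$first_valid_dx_ym)
  same_q <- mean(ep$first_valid_dx_ym[hit] %/% 3L == onset[hit] %/% 3L)
  expect_gte(same_q, 0.99)
})
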