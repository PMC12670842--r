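test_that("identical configuration and seed reproduce the panel exactly", {
  cfg <- quick_sim_config()
  p1 <- simulate_cohort(cfg, "P1")
  p2 <- simulate_cohort(cfg, "P1")
  expect_identical(p1, p2)
  # the two period cohorts use independent substreams
  q <- simulate_cohort(cfg, "P2")
  expect_false(identical(p1$truth$onset_ym, q$truth$onset_ym))
})

test_that("zero incidence hazard produces no true onsets", {
  cfg <- quick_sim_config(
    incidence_params = list(men = c(a = 0, b = 0.1),
                            women = c(a = 0, b = 0.1), rr = 1),
    false_pos_rate = 0.01)
  pan <- simulate_cohort(cfg, "P1")
  expect_true(all(is.na(pan$truth$onset_ym)))
  # every dementia-coded record is then a false positive: unverified
  dem <- pan$diagnoses[startsWith(pan$diagnoses$code, "F") |
                         startsWith(pan$diagnoses$code, "G"), ]
  dem <- dem[dem$code != "I10", ]
  expect_true(all(dem$status == "unverified"))
})

test_that("panel satisfies its structural invariants", {
  pan <- simulate_cohort(quick_sim_config(false_pos_rate = 0.005), "P1")
  p <- pan$persons
  expect_false(any(duplicated(p$person_id)))
  expect_true(all(p$coverage_start_ym <= p$coverage_end_ym))
  d <- p$death_ym[!is.na(p$death_ym)]
  expect_true(all(d == p$coverage_end_ym[!is.na(p$death_ym)]))
  # every diagnosis falls inside the person's coverage
  dg <- pan$diagnoses
  j <- match(dg$person_id, p$person_id)
  dg_q <- dg$year * 4L + dg$quarter - 1L
  expect_true(all(dg_q >= p$coverage_start_ym[j] %/% 3L))
  expect_true(all(dg_q <= p$coverage_end_ym[j] %/% 3L))
  # no verifiable dementia record precedes the true onset
  tr <- pan$truth
  onset_q <- tr$onset_ym[match(dg$person_id, tr$person_id)] %/% 3L
  adm <- dg$code != "I10" & dg$status == "verified"
  expect_true(all(dg_q[adm] >= onset_q[adm], na.rm = TRUE))
})

test_that("configured Gompertz hazards are returned exactly", {
  cfg <- quick_sim_config(
    nondem_mortality_params = list(men = c(a = 0.01, b = 0.10),
                                   women = c(a = 0.01, b = 0.10), rr = 1))
  tr <- true_rates(cfg, "P1")
  expect_equal(tr$nondm[tr$sex == "men" & tr$age == 75],
               0.01 * exp(0.10 * 10))
  cfg0 <- quick_sim_config(
    incidence_params = list(men = c(a = 0, b = 0.1),
                            women = c(a = 0, b = 0.1), rr = 1))
  expect_true(all(true_rates(cfg0, "P1")$di == 0))
})

test_that("period rate ratios act multiplicatively on every age", {
  cfg <- quick_sim_config(
    incidence_params = list(men = c(a = 0.005, b = 0.11),
                            women = c(a = 0.004, b = 0.12), rr = 0.9))
  r1 <- true_rates(cfg, "P1")
  r2 <- true_rates(cfg, "P2")
  expect_equal(r2$di / r1$di, rep(0.9, nrow(r1)))
  expect_equal(r2$dm[r1$sex == "men"] / r1$dm[r1$sex == "men"],
               rep(cfg$dem_mortality_params$rr[["men"]], 36))
})

test_that("empirical truth-level incidence matches the hazard-implied rate", {
  cfg <- clean_sim_config(n = 50000, seed = 1, switch_rate = 0)
  pan <- simulate_cohort(cfg, "P1")
  base <- 12L * pan$baseline_year
  fu_end <- base + 36L
  p <- pan$persons
  onset <- pan$truth$onset_ym
  # persons dementia-free and alive at baseline (all are covered from entry)
  at_risk <- (is.na(onset) | onset >= base) &
    (is.na(p$death_ym) | p$death_ym >= base)
  end_nd <- pmin(ifelse(is.na(onset), fu_end, onset),
                 p$coverage_end_ym + 1L, fu_end)
  py <- sum(pmax(end_nd[at_risk] - base, 0)) / 12
  events <- sum(at_risk & !is.na(onset) & onset >= base & onset < fu_end &
                  onset <= p$coverage_end_ym)
  emp_rate <- events / py
  expected <- analytic_di_rate(cfg, "P1")
  se <- sqrt(events) / py
  expect_lt(abs(emp_rate - expected), 3 * se)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_per_cohort = 0), "n_per_cohort")
  expect_error(sim_config(record_prob = 1.5), "record_prob")
  expect_error(sim_config(
    incidence_params = list(men = c(a = -1, b = 0.1),
                            women = c(a = 0.005, b = 0.1), rr = 1)),
    "incidence_params")
  expect_error(sim_config(
    incidence_params = list(men = c(0.005, 0.1),
                            women = c(a = 0.005, b = 0.1), rr = 1)),
    "incidence_params")
})
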