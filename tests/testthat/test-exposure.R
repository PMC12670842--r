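mk_episode <- function(id = "a", sex = "men", age = 70, dx_months = NA,
                       censor_months = 36, reason = "study_end",
                       baseline_year = 2006) {
  base <- 12L * baseline_year
  data.frame(person_id = id, sex = sex, birth_ym = base - 12L * age,
             entry_age = age, baseline_ym = base,
             first_valid_dx_ym = if (is.na(dx_months)) NA_integer_ else
               base + as.integer(dx_months),
             death_ym = if (reason == "death") base + as.integer(censor_months)
             else NA_integer_,
             censor_ym = base + as.integer(censor_months),
             censor_reason = reason, stringsAsFactors = FALSE)
}

test_that("an uneventful three-year episode yields exactly 3 person-years", {
  tabs <- person_time_slices(mk_episode(), "P1")
  expect_equal(sum(tabs$di$person_years), 3)
  expect_equal(tabs$di$person_years, tabs$nondm$person_years)
  expect_equal(sum(tabs$di$events), 0L)
  expect_equal(sum(tabs$dm$person_years), 0)
  # spread over the traversed ages 70, 71, 72
  expect_equal(tabs$di$person_years[tabs$di$sex == "men" &
                                      tabs$di$age %in% 70:72], rep(1, 3))
})

test_that("the diagnosis splits exposure between the states exactly", {
  # diagnosed 18 months in, dies 30 months in
  ep <- mk_episode(dx_months = 18, censor_months = 30, reason = "death")
  tabs <- person_time_slices(ep, "P1")
  expect_equal(sum(tabs$di$person_years), 1.5)
  expect_equal(sum(tabs$di$events), 1L)
  expect_equal(sum(tabs$dm$person_years), 1.0)
  expect_equal(sum(tabs$dm$events), 1L)
  expect_equal(sum(tabs$nondm$events), 0L)
  # diagnosis event lands at the age in completed years at diagnosis
  expect_equal(tabs$di$events[tabs$di$sex == "men" & tabs$di$age == 71], 1L)
  # death without diagnosis is a non-dementia death instead
  tabs2 <- person_time_slices(mk_episode(censor_months = 30,
                                         reason = "death"), "P1")
  expect_equal(sum(tabs2$nondm$events), 1L)
  expect_equal(sum(tabs2$dm$events), 0L)
})

test_that("diagnosis and death in the same month put the death in the dementia state", {
  ep <- mk_episode(dx_months = 12, censor_months = 12, reason = "death")
  tabs <- person_time_slices(ep, "P1")
  expect_equal(sum(tabs$di$events), 1L)
  expect_equal(sum(tabs$dm$events), 1L)
  expect_equal(sum(tabs$nondm$events), 0L)
  expect_equal(sum(tabs$dm$person_years), 0)
})

test_that("person-years are conserved and invariant to record order", {
  pan <- simulate_cohort(quick_sim_config(), "P1")
  ep <- build_episodes(pan)
  tabs <- suppressMessages(person_time_slices(ep, "P1"))
  total_followup <- sum(ep$censor_ym - ep$baseline_ym) / 12
  expect_equal(sum(tabs$di$person_years) + sum(tabs$dm$person_years),
               total_followup, tolerance = 1e-10)
  # shuffling rows (relabelling order) changes nothing
  ep_shuf <- ep[sample(nrow(ep)), ]
  attr(ep_shuf, "period") <- "P1"
  tabs_shuf <- suppressMessages(person_time_slices(ep_shuf, "P1"))
  expect_equal(tabs, tabs_shuf)
})

test_that("crude rates reproduce hand-checkable arithmetic", {
  r <- aggregate_rate(5, 250)
  expect_equal(r$rate_per_1000, 20)
  z <- aggregate_rate(0, 1000)
  expect_equal(c(z$rate_per_1000, z$ci_low, z$ci_high), c(0, 0, 0))
  expect_error(aggregate_rate(3, 0), "person_years")
})

test_that("a constant configured hazard is recovered by the pooled rate", {
  # episodes built directly from an exponential onset model, rate 0.03
  set.seed(31)
  n <- 40000
  onset <- stats::rexp(n, 0.03)
  months <- pmin(as.integer(floor(onset * 12)), 36L)
  has_dx <- months < 36L
  base <- 12L * 2006
  ep <- data.frame(person_id = sprintf("p%05d", seq_len(n)), sex = "men",
                   birth_ym = base - 12L * 70L, entry_age = 70L,
                   baseline_ym = base,
                   first_valid_dx_ym = ifelse(has_dx, base + months,
                                              NA_integer_),
                   death_ym = NA_integer_,
                   censor_ym = base + ifelse(has_dx, months, 36L),
                   censor_reason = ifelse(has_dx, "study_end", "study_end"),
                   stringsAsFactors = FALSE)
  ep$first_valid_dx_ym <- as.integer(ep$first_valid_dx_ym)
  tabs <- person_time_slices(ep, "P1")
  pooled <- sum(tabs$di$events) / sum(tabs$di$person_years)
  se <- sqrt(sum(tabs$di$events)) / sum(tabs$di$person_years)
  # month-floored event times shift the continuous rate by < 0.5 SE here
  expect_lt(abs(pooled - 0.03), 3 * se + 0.03 / 24)
})

test_that("age-specific rates flag zero-exposure cells as missing", {
  tb <- data.frame(transition = "DI", sex = "men", period = "P1",
                   age = 65:100, events = 0L, person_years = 0)
  tb$person_years[tb$age == 70] <- 250
  tb$events[tb$age == 70] <- 5L
  r <- age_specific_rates(tb)
  expect_equal(r$rate[r$age == 70], 0.02)
  expect_true(all(is.na(r$rate[r$age != 70])))
  tb$events[tb$age == 71] <- 1L
  expect_error(age_specific_rates(tb), "zero person-years")
})

test_that("pooled summary cells equal the sums of their margins", {
  pan <- simulate_cohort(quick_sim_config(), "P1")
  tabs <- suppressMessages(person_time_slices(build_episodes(pan), "P1"))
  rs <- rate_summary(tabs)
  di <- rs[rs$transition == "DI", ]
  tot <- di[di$sex == "total", ]
  expect_equal(tot$events, sum(di$events[di$sex != "total"]))
  expect_equal(tot$person_years, sum(di$person_years[di$sex != "total"]))
  expect_equal(tot$rate_per_1000, 1000 * tot$events / tot$person_years)
})
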