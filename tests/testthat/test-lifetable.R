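test_that("constant dementia mortality reproduces the closed-form expectancy", {
  m <- 0.25
  rates <- transition_rates(rep(0.02, 36), rep(m, 36), rep(0.03, 36))
  e <- state_expectancies(rates)$e_dem
  expect_equal(e, (1 - exp(-m * (100 - 65:100))) / m, tolerance = 1e-12)
  # zero mortality: the full truncated span remains
  r0 <- transition_rates(rep(0.02, 36), rep(0, 36), rep(0.03, 36))
  expect_equal(state_expectancies(r0)$e_dem, pmax(100 - 65:100, 0),
               tolerance = 1e-12)
})

test_that("zero incidence collapses the table to a single decrement", {
  rates <- transition_rates(rep(0, 36), rep(0.2, 36), rep(0.05, 36))
  lt <- build_lifetable(rates)
  expect_true(all(lt$d[1:35] == 0))
  expect_true(all(lt$l_d == 0))
  expect_error(average_life_expectancy(state_expectancies(rates), lt),
               "no decrements")
  # no hazards at all: nobody leaves, 35 person-years accrue
  r0 <- transition_rates(rep(0, 36), rep(0, 36), rep(0, 36))
  lt0 <- build_lifetable(r0)
  expect_true(all(lt0$l_nd == 1))
  expect_equal(sum(lt0$L_nd[1:35]), 35)
})

test_that("the accounting identity holds exactly at every age", {
  for (sd in c(11, 22, 33, 44)) {
    lt <- build_lifetable(random_rate_grid(sd))
    # exact up to the rounding of the final additions (about one ulp)
    expect_lt(max(abs(lt$l_nd[1:35] -
                        (lt$l_nd[2:36] + lt$d[1:35] + lt$deaths_nd[1:35]))),
              1e-15)
    expect_true(all(diff(lt$l_nd) <= 0))
    expect_true(all(lt$d[1:35] >= 0 & lt$deaths_nd[1:35] >= 0 &
                      lt$deaths_d[1:35] >= 0))
  }
})

test_that("expectancies fall when their governing hazards rise", {
  for (sd in c(5, 6, 7)) {
    set.seed(sd)
    rates <- random_rate_grid(sd)
    bump <- stats::runif(36, 0, 0.05)
    up_dm <- rates; up_dm$dm <- rates$dm + bump
    up_nm <- rates; up_nm$nondm <- rates$nondm + bump
    e0 <- state_expectancies(rates)
    expect_true(all(state_expectancies(up_dm)$e_dem <= e0$e_dem + 1e-12))
    expect_true(all(state_expectancies(up_dm)$e_nondem <= e0$e_nondem + 1e-12))
    expect_true(all(state_expectancies(up_nm)$e_nondem <= e0$e_nondem + 1e-12))
  }
})

test_that("degenerate onset weights reduce the ALE to a single age", {
  di <- rep(0, 36); di[6] <- 0.04           # onset mass only at age 70
  rates <- transition_rates(di, rep(0.22, 36), rep(0.04, 36))
  lt <- build_lifetable(rates)
  exps <- state_expectancies(rates)
  ale <- average_life_expectancy(exps, lt)
  expect_equal(ale$ale_dem, exps$e_dem[exps$age == 70])
  expect_equal(ale$ale_nondem, exps$e_nondem[exps$age == 70])
  expect_equal(sum(ale$weights$w), 1)
})

test_that("the ALE identities hold exactly", {
  ale <- average_life_expectancy(
    state_expectancies(random_rate_grid(77)),
    build_lifetable(random_rate_grid(77)))
  expect_identical(ale$ale_total, ale$ale_dem + ale$ale_nondem)
  expect_identical(ale$lyl, ale$ale_nondem - ale$ale_dem)
  expect_identical(ale$ratio, ale$ale_dem / ale$ale_total)
})

test_that("backward recursion matches a forward microsimulation", {
  for (sd in c(301, 302)) {
    rates <- random_rate_grid(sd)
    ale <- average_life_expectancy(state_expectancies(rates),
                                   build_lifetable(rates))
    mo <- micro_ale(rates, n_agents = 2e5, seed = sd)
    expect_lt(abs(ale$ale_dem - mo$ale_dem), 3 * mo$se_dem)
    expect_lt(abs(ale$ale_nondem - mo$ale_nondem), 3 * mo$se_nondem)
  }
})

test_that("the hazard-only reading of the dementia-free expectancy is available", {
  rates <- random_rate_grid(12)
  rates$dm <- rates$nondm + 0.1   # dementia mortality dominates everywhere
  e3 <- state_expectancies(rates, nondem_mode = "threestate")
  eh <- state_expectancies(rates, nondem_mode = "nondem_hazard_only")
  m <- rates$nondm
  # hazard-only reading is plain survival under non-DM
  manual <- numeric(36)
  for (i in 35:1) {
    manual[i] <- (1 - exp(-m[i])) / max(m[i], 1e-300) +
      exp(-m[i]) * manual[i + 1]
  }
  expect_equal(eh$e_nondem, manual, tolerance = 1e-12)
  # the three-state reading can only lower the expectancy when dementia
  # mortality exceeds non-dementia mortality everywhere
  expect_true(all(e3$e_nondem <= eh$e_nondem + 1e-12))
})

test_that("invalid rate grids are rejected", {
  rates <- random_rate_grid(2)
  bad <- rates; bad$di[3] <- -0.1
  expect_error(build_lifetable(bad), "non-negative")
  short <- rates[-1, ]
  expect_error(build_lifetable(short), "complete")
})
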