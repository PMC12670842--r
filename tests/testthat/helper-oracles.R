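# Independent oracles and fixture builders used across the test suite.
# These deliberately re-derive quantities by brute force (forward Monte
# Carlo, fine-grid numerical integration) rather than calling the code
# paths they check.

# --- small simulation configs ------------------------------------------

quick_sim_config <- function(...) {
  sim_config(n_per_cohort = 4000, seed = 99, ...)
}

# noise-free recording: every true case is recorded, no false positives
clean_sim_config <- function(n = 20000, seed = 11, record_prob = 1,
                             false_pos_rate = 0, filler_rate = 0, ...) {
  sim_config(n_per_cohort = n, record_prob = record_prob,
             false_pos_rate = false_pos_rate, filler_rate = filler_rate,
             seed = seed, ...)
}

# --- forward Monte Carlo oracle for the three-state model ---------------

# Years alive from exact age `start` under piecewise-constant mortality
# `haz` (vector indexed by age 65..100, constant within single years),
# truncated at 100.  `start` may be fractional (e.g. mid-interval entry).
micro_years_under <- function(n, start, haz) {
  yrs <- numeric(n)
  alive <- rep(TRUE, n)
  cur <- rep(start, n)
  while (any(alive)) {
    i <- which(alive)
    x <- floor(cur[i] + 1e-9)
    w <- pmin(x + 1 - cur[i], 100 - cur[i])
    r <- haz[x - 64]
    te <- ifelse(r > 0, stats::rexp(length(i)) / pmax(r, 1e-300), Inf)
    died <- te < w
    yrs[i] <- yrs[i] + ifelse(died, te, w)
    cur[i] <- cur[i] + w
    alive[i] <- !died & cur[i] < 100 - 1e-9
  }
  yrs
}

# Onset intervals and within-interval onset times for agents starting
# dementia-free at 65 under competing hazards di / nondm.
micro_onsets <- function(n, di, nondm) {
  onset_x <- rep(NA_integer_, n)
  onset_t <- rep(NA_real_, n)
  alive_nd <- rep(TRUE, n)
  for (x in 65:99) {
    i <- which(alive_nd)
    if (!length(i)) break
    h <- di[x - 64] + nondm[x - 64]
    if (h <= 0) next
    te <- stats::rexp(length(i)) / h
    exit <- te < 1
    if (any(exit)) {
      ie <- i[exit]
      is_onset <- stats::runif(length(ie)) < di[x - 64] / h
      onset_x[ie[is_onset]] <- x
      onset_t[ie[is_onset]] <- te[exit][is_onset]
      alive_nd[ie] <- FALSE
    }
  }
  list(x = onset_x, t = onset_t)
}

# Brute-force estimates of ale_dem / ale_nondem: forward-simulate the
# onset-age distribution, then for each onset age simulate (a) dementia
# survival from the exact integer onset age and (b) a same-aged
# dementia-free person through the full three-state model (years of a
# later dementia spell accrue from mid-interval, the model's occupancy
# convention).  Returns estimates with Monte Carlo standard errors.
micro_ale <- function(rates, n_agents = 1e6, seed = 1) {
  set.seed(seed)
  di <- rates$di; dm <- rates$dm; nm <- rates$nondm
  on <- micro_onsets(n_agents, di, nm)
  keep <- which(!is.na(on$x))
  x0 <- on$x[keep]
  m <- length(x0)

  # (a) years alive after onset at exact integer age x0, hazard DM
  y_dem <- numeric(m)
  for (x in sort(unique(x0))) {
    sel <- which(x0 == x)
    y_dem[sel] <- micro_years_under(length(sel), x, dm)
  }

  # (b) total years of a dementia-free person at exact age x0
  y_nd <- numeric(m)
  for (x in sort(unique(x0))) {
    sel <- which(x0 == x)
    k <- length(sel)
    cur <- rep(x, k)
    yrs <- numeric(k)
    state_nd <- rep(TRUE, k)
    done <- rep(FALSE, k)
    while (any(!done)) {
      i <- which(!done & state_nd)
      if (length(i)) {
        a <- floor(cur[i] + 1e-9)
        h <- di[a - 64] + nm[a - 64]
        te <- ifelse(h > 0, stats::rexp(length(i)) / pmax(h, 1e-300), Inf)
        exit <- te < 1
        ie <- i[exit]
        a_ie <- a[exit]
        yrs[i] <- yrs[i] + ifelse(exit, te, 1)
        cur[i] <- cur[i] + 1
        if (length(ie)) {
          p_on <- di[a_ie - 64] / (di[a_ie - 64] + nm[a_ie - 64])
          is_onset <- stats::runif(length(ie)) < p_on
          onset_agents <- ie[is_onset]
          if (length(onset_agents)) {
            # dementia clock starts at mid-interval of the onset interval
            start_dem <- a_ie[is_onset] + 0.5
            for (sa in unique(start_dem)) {
              g <- onset_agents[start_dem == sa]
              yrs[g] <- yrs[g] + micro_years_under(length(g), sa, dm)
            }
          }
          done[ie] <- TRUE
        }
        done[i[!exit & cur[i] >= 100 - 1e-9]] <- TRUE
      } else break
    }
    y_nd[sel] <- yrs
  }

  list(ale_dem = mean(y_dem), se_dem = stats::sd(y_dem) / sqrt(m),
       ale_nondem = mean(y_nd), se_nondem = stats::sd(y_nd) / sqrt(m),
       n_onsets = m)
}

# --- random rate grids --------------------------------------------------

# A plausible transition-rate grid: Gompertz-like below 80, continuing
# smoothly above.  Used for life-table property tests.
random_rate_grid <- function(seed) {
  set.seed(seed)
  ages <- 65:100
  g <- function(a0, b) a0 * exp(b * (ages - 65))
  di <- g(stats::runif(1, 0.003, 0.01), stats::runif(1, 0.08, 0.13))
  nm <- g(stats::runif(1, 0.006, 0.02), stats::runif(1, 0.07, 0.11))
  dm <- g(stats::runif(1, 0.08, 0.25), stats::runif(1, 0.02, 0.06))
  transition_rates(pmin(di, 0.9), pmin(dm, 0.95), pmin(nm, 0.9), age = ages)
}

# Truth grid whose 80+ part is exactly Kannisto (correctly specified for
# the smoother): Gompertz below 80, logistic continuation matched at 80.
kannisto_truth_grid <- function(a65, b, ages = 65:100) {
  r80 <- a65 * exp(b * 15)
  a_k <- r80 / (1 - min(r80, 0.99))
  ifelse(ages < 80, a65 * exp(b * (ages - 65)),
         kannisto_hazard(ages, a_k, b))
}

# --- analytic cohort rate (fine-grid integration) -----------------------

# Expected truth-level dementia incidence rate of one simulated cohort:
# person-years-weighted mean hazard over the entry-age distribution,
# conditioning on surviving the wash-out dementia-free, switch_rate = 0.
analytic_di_rate <- function(config, period_label = "P1",
                             da = 0.05, dt = 0.01) {
  ead <- config$entry_age_dist
  num <- 0; den <- 0
  for (s in c("men", "women")) {
    gomp <- function(p) {
      rr <- if (period_label == "P2") p$rr[[s]] else 1
      a0 <- p[[s]][["a"]] * rr
      b0 <- p[[s]][["b"]]
      # piecewise-constant on single-year intervals, extrapolated below 65
      function(x) a0 * exp(b0 * (pmin(floor(x), 100) - 65))
    }
    g_di <- gomp(config$incidence_params)
    g_nm <- gomp(config$nondem_mortality_params)
    hz_di <- function(a) g_di(a)
    hz_nd <- function(a) g_di(a) + g_nm(a)
    w_sex <- if (s == "women") config$prop_female else 1 - config$prop_female
    sh2 <- if (s == "women") ead$shape2_women else ead$shape2_men
    a_grid <- seq(65 + da / 2, 100 - da / 2, by = da)
    f_a <- stats::dbeta((a_grid - 65) / 35, ead$shape1, sh2) / 35
    for (j in seq_along(a_grid)) {
      a <- a_grid[j]
      # survive wash-out [a-2, a) dementia-free
      tw <- seq(dt / 2, 2, by = dt)
      S_w <- exp(-sum(hz_nd(a - 2 + tw)) * dt)
      # follow-up [a, a+3)
      tf <- seq(dt / 2, 3, by = dt)
      cumh <- cumsum(hz_nd(a + tf)) * dt
      S_f <- exp(-(cumh - hz_nd(a + tf) * dt / 2))
      w <- w_sex * f_a[j] * da * S_w
      num <- num + w * sum(S_f * hz_di(a + tf)) * dt
      den <- den + w * sum(S_f) * dt
    }
  }
  num / den
}
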