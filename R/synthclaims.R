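#' Configuration for the synthetic claims generator
#'
#' Defines the ground-truth transition hazards and recording mechanisms of a
#' synthetic quarterly claims panel.  Two period cohorts are generated (P1
#' and P2, baseline years `baseline_years`); each spans a two-year wash-out
#' plus three follow-up years.  All three transition hazards are Gompertz,
#' `a * exp(b * (age - 65))`, piecewise-constant on single-year age
#' intervals, with a multiplicative period rate ratio applied to the second
#' cohort.
#'
#' @param n_per_cohort Number of insured persons per period cohort.
#' @param prop_female Proportion of women in the cohort.
#' @param entry_age_dist Parameters of the age-at-baseline distribution:
#'   ages are drawn as `65 + 35 * Beta(shape1, shape2_sex)`, a decreasing
#'   density over \[65, 100) whose defaults put the mean entry age near the
#'   mean ages of exposed claims populations (about 74 for men, 76 for
#'   women).
#' @param incidence_params Dementia incidence hazard: list with per-sex
#'   Gompertz parameters `men = c(a=, b=)`, `women = c(a=, b=)` (level `a`
#'   at age 65, slope `b` per year of age) and `rr`, the period-2/period-1
#'   rate ratio.  `rr` may be a scalar (applied to both sexes) or a named
#'   vector `c(men=, women=)`.
#' @param nondem_mortality_params Mortality hazard without dementia, same
#'   structure.
#' @param dem_mortality_params Mortality hazard with dementia, same
#'   structure.
#' @param record_prob Per-quarter probability that a person with true
#'   dementia generates an admissible (verifiable) diagnosis claim, from the
#'   onset quarter onward.  Values below 1 emulate under-recording.
#' @param false_pos_rate Per person-quarter rate at which persons who never
#'   develop dementia emit a spurious dementia diagnosis.  Each event is a
#'   single unverified outpatient record, which the two-records validation
#'   rule must reject.
#' @param paired_false_positives If `TRUE`, each false-positive event emits
#'   two verified outpatient records in the same quarter instead, which the
#'   validation rule cannot reject -- its designed failure mode, exposed for
#'   testing.
#' @param filler_rate Per person-quarter rate of a generic non-dementia
#'   diagnosis (ICD-10 I10), exercising the code-set filter.
#' @param switch_rate Annual probability of leaving the insurer.
#' @param baseline_years Named vector mapping period labels to baseline
#'   calendar years.
#' @param seed Integer RNG seed; each period cohort uses its own stream
#'   derived from `seed` and the period label.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()], [true_rates()]
#' @export
sim_config <- function(n_per_cohort = 50000L,
                       prop_female = 0.58,
                       entry_age_dist = list(shape1 = 1.0,
                                             shape2_men = 3.0,
                                             shape2_women = 2.3),
                       incidence_params = list(
                         men = c(a = 0.007, b = 0.105),
                         women = c(a = 0.006, b = 0.120),
                         rr = c(men = 0.927, women = 0.903)),
                       nondem_mortality_params = list(
                         men = c(a = 0.013, b = 0.090),
                         women = c(a = 0.008, b = 0.100),
                         rr = c(men = 0.931, women = 0.937)),
                       dem_mortality_params = list(
                         men = c(a = 0.17, b = 0.035),
                         women = c(a = 0.11, b = 0.045),
                         rr = c(men = 0.880, women = 1.062)),
                       record_prob = 0.85,
                       false_pos_rate = 0.002,
                       paired_false_positives = FALSE,
                       filler_rate = 0.03,
                       switch_rate = 0.005,
                       baseline_years = c(P1 = 2006L, P2 = 2016L),
                       seed = 1L) {
  cfg <- list(n_per_cohort = as.integer(n_per_cohort),
              prop_female = prop_female,
              entry_age_dist = entry_age_dist,
              incidence_params = normalize_hazard_params(incidence_params,
                                                         "incidence_params"),
              nondem_mortality_params =
                normalize_hazard_params(nondem_mortality_params,
                                        "nondem_mortality_params"),
              dem_mortality_params =
                normalize_hazard_params(dem_mortality_params,
                                        "dem_mortality_params"),
              record_prob = record_prob,
              false_pos_rate = false_pos_rate,
              paired_false_positives = isTRUE(paired_false_positives),
              filler_rate = filler_rate,
              switch_rate = switch_rate,
              baseline_years = baseline_years,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# Recycle a scalar rr to both sexes and check hazard parameter shape.
normalize_hazard_params <- function(p, field) {
  for (s in c("men", "women")) {
    if (is.null(p[[s]]) || !all(c("a", "b") %in% names(p[[s]]))) {
      stop("invalid configuration: ", field, "$", s,
           " must be a named vector with elements 'a' and 'b'")
    }
  }
  rr <- p$rr %||% 1
  if (length(rr) == 1L) rr <- c(men = unname(rr), women = unname(rr))
  if (!all(c("men", "women") %in% names(rr))) {
    stop("invalid configuration: ", field,
         "$rr must be a scalar or named c(men=, women=)")
  }
  p$rr <- rr[c("men", "women")]
  p
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, why) {
    stop("invalid configuration: field '", field, "' ", why, call. = FALSE)
  }
  if (is.na(cfg$n_per_cohort) || cfg$n_per_cohort < 1L) {
    stop_field("n_per_cohort", "must be >= 1")
  }
  for (f in c("prop_female", "record_prob", "false_pos_rate",
              "filler_rate", "switch_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_field(f, "must be a probability in [0, 1]")
    }
  }
  for (f in c("incidence_params", "nondem_mortality_params",
              "dem_mortality_params")) {
    p <- cfg[[f]]
    for (s in c("men", "women")) {
      if (any(!is.finite(p[[s]])) || p[[s]]["a"] < 0) {
        stop_field(f, paste0("$", s, " must have finite a >= 0 and finite b"))
      }
      # hazards must stay finite over the simulated age span
      if (!is.finite(p[[s]]["a"] * exp(p[[s]]["b"] * 40))) {
        stop_field(f, paste0("$", s, " hazard overflows on [65, 105)"))
      }
    }
    if (any(!is.finite(p$rr)) || any(p$rr < 0)) stop_field(f, "$rr must be >= 0")
  }
  ead <- cfg$entry_age_dist
  if (!all(c("shape1", "shape2_men", "shape2_women") %in% names(ead)) ||
      any(unlist(ead[c("shape1", "shape2_men", "shape2_women")]) <= 0)) {
    stop_field("entry_age_dist", "must give positive Beta shapes")
  }
  if (!all(c("P1", "P2") %in% names(cfg$baseline_years))) {
    stop_field("baseline_years", "must name P1 and P2")
  }
  if (is.na(cfg$seed)) stop_field("seed", "must be an integer")
  invisible(cfg)
}

# Gompertz hazard anchored at 65, evaluated per person at integer age x.
hazard_at <- function(x, a, b, rr = 1) a * exp(b * (x - 65)) * rr

per_sex <- function(params, sex, what) {
  ifelse(sex == "men", params$men[what], params$women[what])
}

#' Ground-truth transition rates of a simulation configuration
#'
#' Returns the exact configured hazards DI(x), DM(x) and non-DM(x) on
#' integer ages 65--100 for one period cohort, including the period rate
#' ratio for P2.  These are the values the simulator samples from and serve
#' as the oracle in parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @param period_label `"P1"` or `"P2"`.
#' @return Data frame with columns `sex`, `age`, `di`, `dm`, `nondm`.
#' @export
true_rates <- function(config, period_label = c("P1", "P2")) {
  period_label <- match.arg(period_label)
  validate_sim_config(config)
  grid <- expand.grid(sex = c("men", "women"), age = 65:100,
                      stringsAsFactors = FALSE)
  rrf <- function(p) if (period_label == "P2") p$rr else c(men = 1, women = 1)
  hz <- function(p) {
    unname(hazard_at(grid$age,
                     per_sex(p, grid$sex, "a"),
                     per_sex(p, grid$sex, "b"),
                     ifelse(grid$sex == "men", rrf(p)["men"], rrf(p)["women"])))
  }
  out <- data.frame(sex = grid$sex, age = grid$age,
                    di = hz(config$incidence_params),
                    dm = hz(config$dem_mortality_params),
                    nondm = hz(config$nondem_mortality_params))
  out[order(out$sex, out$age), , drop = FALSE]
}

# Sample exit times from a piecewise-constant (single-year-of-age) hazard by
# inversion, one age interval at a time, for all active persons at once.
# `hfuns` is a list of per-person hazard evaluators (age-vector -> rate).
# Returns exit age (NA if censored at `horizon`) and cause index.
sample_piecewise_exit <- function(start_age, horizon, hfuns) {
  n <- length(start_age)
  exit_age <- rep(NA_real_, n)
  cause <- rep(NA_integer_, n)
  cur <- start_age
  active <- cur < horizon - 1e-12
  while (any(active)) {
    i <- which(active)
    k <- floor(cur[i] + 1e-9)
    dt <- pmin(k + 1 - cur[i], horizon[i] - cur[i])
    hz <- vapply(hfuns, function(f) f(k, i), numeric(length(i)))
    if (length(i) == 1L) hz <- matrix(hz, nrow = 1L)
    H <- rowSums(hz)
    te <- stats::rexp(length(i)) / pmax(H, 1e-300)
    hit <- H > 0 & te < dt
    if (any(hit)) {
      ih <- i[hit]
      exit_age[ih] <- cur[ih] + te[hit]
      u <- stats::runif(length(ih)) * H[hit]
      cum <- hz[hit, , drop = FALSE]
      cs <- t(apply(cum, 1L, cumsum))
      if (length(ih) == 1L) cs <- matrix(cs, nrow = 1L)
      cs[, ncol(cs)] <- Inf  # guard against cumsum rounding below u
      cause[ih] <- max.col(u <= cs, ties.method = "first")
    }
    cur[i] <- ifelse(hit, horizon[i], cur[i] + dt)
    active[i] <- cur[i] < horizon[i] - 1e-12
  }
  list(age = exit_age, cause = cause)
}

#' Simulate one synthetic claims cohort
#'
#' Generates a quarterly claims panel for one period cohort: persons enter
#' coverage two years before the baseline year (the wash-out window) and are
#' followed for three years after baseline.  Dementia onset, death and
#' insurance exit are drawn by competing-risks sampling from the configured
#' piecewise-constant hazards; persons with true onset emit admissible
#' diagnosis records per quarter with probability `record_prob` from onset
#' onward, and never-demented persons emit isolated unverified false
#' positives at `false_pos_rate`.  Death months are recorded exactly; the
#' true onset month of every person is carried in the `truth` component for
#' recovery testing.
#'
#' @param config A [sim_config()].
#' @param period_label `"P1"` or `"P2"`; selects the baseline year and which
#'   period rate ratios apply.
#' @return A `claims_panel`: list with data frames `persons` (person_id,
#'   sex, birth_ym, death_ym, coverage_start_ym, coverage_end_ym; `*_ym`
#'   columns are integer months, see [write_claims_panel()] for the CSV
#'   form), `diagnoses` (person_id, year, quarter, code, setting, status)
#'   and `truth` (person_id, onset_ym), plus the period label, baseline year
#'   and panel window.
#' @export
simulate_cohort <- function(config, period_label = c("P1", "P2")) {
  period_label <- match.arg(period_label)
  validate_sim_config(config)
  baseline_year <- unname(config$baseline_years[period_label])
  seed <- derive_seed(config$seed, if (period_label == "P1") 0L else 1000003L)

  with_seed(seed, {
    n <- config$n_per_cohort
    base_ym <- ym(baseline_year, 1L)
    start_ym <- base_ym - 24L        # wash-out entry
    end_ym <- base_ym + 36L          # exclusive end of follow-up

    sex <- ifelse(stats::runif(n) < config$prop_female, "women", "men")
    ead <- config$entry_age_dist
    age0 <- 65 + 35 * stats::rbeta(n, ead$shape1,
                                   ifelse(sex == "men",
                                          ead$shape2_men, ead$shape2_women))
    birth_ym <- base_ym - as.integer(floor(age0 * 12 + 1e-9))
    a_start <- (start_ym - birth_ym) / 12
    horizon <- (end_ym - birth_ym) / 12

    rr1 <- if (period_label == "P2") config$incidence_params$rr else c(men = 1, women = 1)
    rr2 <- if (period_label == "P2") config$nondem_mortality_params$rr else c(men = 1, women = 1)
    rr3 <- if (period_label == "P2") config$dem_mortality_params$rr else c(men = 1, women = 1)
    sexnum <- as.integer(sex == "women") + 1L  # 1 men, 2 women
    par_vec <- function(p, rr) {
      list(a = ifelse(sexnum == 1L, p$men["a"], p$women["a"]) *
             ifelse(sexnum == 1L, rr["men"], rr["women"]),
           b = ifelse(sexnum == 1L, p$men["b"], p$women["b"]))
    }
    pdi <- par_vec(config$incidence_params, rr1)
    pnm <- par_vec(config$nondem_mortality_params, rr2)
    pdm <- par_vec(config$dem_mortality_params, rr3)
    hsw <- -log(1 - config$switch_rate)   # constant annual exit hazard

    # stage 1: non-dementia state, competing risks onset / death / exit
    st1 <- sample_piecewise_exit(
      a_start, horizon,
      list(function(k, i) pdi$a[i] * exp(pdi$b[i] * (k - 65)),
           function(k, i) pnm$a[i] * exp(pnm$b[i] * (k - 65)),
           function(k, i) rep(hsw, length(i))))

    onset_age <- ifelse(!is.na(st1$cause) & st1$cause == 1L, st1$age, NA_real_)
    death_age <- ifelse(!is.na(st1$cause) & st1$cause == 2L, st1$age, NA_real_)
    switch_age <- ifelse(!is.na(st1$cause) & st1$cause == 3L, st1$age, NA_real_)

    # stage 2: dementia state, death / exit from the onset age
    don <- which(!is.na(onset_age))
    if (length(don)) {
      st2 <- sample_piecewise_exit(
        onset_age[don], horizon[don],
        list(function(k, i) pdm$a[don][i] * exp(pdm$b[don][i] * (k - 65)),
             function(k, i) rep(hsw, length(i))))
      death_age[don[!is.na(st2$cause) & st2$cause == 1L]] <-
        st2$age[!is.na(st2$cause) & st2$cause == 1L]
      switch_age[don[!is.na(st2$cause) & st2$cause == 2L]] <-
        st2$age[!is.na(st2$cause) & st2$cause == 2L]
    }

    to_ym <- function(age) {
      ifelse(is.na(age), NA_integer_,
             birth_ym + as.integer(floor(age * 12 + 1e-9)))
    }
    onset_ym <- to_ym(onset_age)
    death_ym <- to_ym(death_age)
    switch_ym <- to_ym(switch_age)

    coverage_end <- pmin(end_ym - 1L,
                         ifelse(is.na(death_ym), .Machine$integer.max, death_ym),
                         ifelse(is.na(switch_ym), .Machine$integer.max, switch_ym))

    person_id <- sprintf("%s-%06d", period_label, seq_len(n))
    persons <- data.frame(person_id = person_id, sex = sex,
                          birth_ym = birth_ym, death_ym = death_ym,
                          coverage_start_ym = rep(start_ym, n),
                          coverage_end_ym = as.integer(coverage_end),
                          stringsAsFactors = FALSE)

    dx_parts <- list()

    # true-case diagnosis stream: one admissible record per quarter with
    # probability record_prob, from the onset quarter to the end of coverage
    rec <- which(!is.na(onset_ym) & onset_ym <= coverage_end)
    if (length(rec)) {
      q0 <- onset_ym[rec] %/% 3L
      q1 <- coverage_end[rec] %/% 3L
      nq <- q1 - q0 + 1L
      pid <- rep(rec, nq)
      qs <- rep(q0, nq) + sequence(nq) - 1L
      hit <- stats::runif(length(qs)) < config$record_prob
      pid <- pid[hit]; qs <- qs[hit]
      if (length(pid)) {
        m <- length(pid)
        draw <- stats::runif(m)
        setting <- ifelse(draw < 0.80, "outpatient",
                          ifelse(draw < 0.95, "inpatient_discharge",
                                 "inpatient_secondary"))
        status <- ifelse(setting == "outpatient", "verified",
                         ifelse(stats::runif(m) < 0.5, "verified", "unverified"))
        code <- sample(c("F03", "G30", "F01", "F00", "F02", "F05.1"), m,
                       replace = TRUE,
                       prob = c(0.55, 0.25, 0.08, 0.05, 0.04, 0.03))
        dx_parts$true <- data.frame(person_id = person_id[pid],
                                    year = yq_year(qs), quarter = yq_quarter(qs),
                                    code = code, setting = setting,
                                    status = status, stringsAsFactors = FALSE)
      }
    }

    # false positives among the never-demented: isolated records, one per
    # event (or a same-quarter verified pair under the failure-mode flag)
    if (config$false_pos_rate > 0) {
      fpp <- which(is.na(onset_ym))
      if (length(fpp)) {
        q0 <- start_ym %/% 3L
        nq <- coverage_end[fpp] %/% 3L - q0 + 1L
        k <- stats::rbinom(length(fpp), nq, config$false_pos_rate)
        has <- k > 0L
        if (any(has)) {
          pid <- rep(fpp[has], k[has])
          nq_rep <- rep(nq[has], k[has])
          qs <- q0 + as.integer(floor(stats::runif(length(pid)) * nq_rep))
          code <- sample(c("F03", "G30", "F01"), length(pid), replace = TRUE,
                         prob = c(0.7, 0.2, 0.1))
          if (config$paired_false_positives) {
            fp <- data.frame(person_id = rep(person_id[pid], 2L),
                             year = rep(yq_year(qs), 2L),
                             quarter = rep(yq_quarter(qs), 2L),
                             code = rep(code, 2L),
                             setting = "outpatient", status = "verified",
                             stringsAsFactors = FALSE)
          } else {
            fp <- data.frame(person_id = person_id[pid],
                             year = yq_year(qs), quarter = yq_quarter(qs),
                             code = code,
                             setting = "outpatient", status = "unverified",
                             stringsAsFactors = FALSE)
          }
          dx_parts$fp <- fp
        }
      }
    }

    # generic filler diagnoses (non-dementia code), all persons
    if (config$filler_rate > 0) {
      q0 <- start_ym %/% 3L
      nq <- coverage_end %/% 3L - q0 + 1L
      k <- stats::rbinom(n, nq, config$filler_rate)
      has <- k > 0L
      if (any(has)) {
        pid <- rep(which(has), k[has])
        nq_rep <- rep(nq[has], k[has])
        qs <- q0 + as.integer(floor(stats::runif(length(pid)) * nq_rep))
        dx_parts$filler <- data.frame(person_id = person_id[pid],
                                      year = yq_year(qs),
                                      quarter = yq_quarter(qs),
                                      code = "I10", setting = "outpatient",
                                      status = "verified",
                                      stringsAsFactors = FALSE)
      }
    }

    diagnoses <- if (length(dx_parts)) {
      d <- do.call(rbind, unname(dx_parts))
      d[order(d$person_id, d$year, d$quarter, d$code), , drop = FALSE]
    } else {
      data.frame(person_id = character(), year = integer(),
                 quarter = integer(), code = character(),
                 setting = character(), status = character(),
                 stringsAsFactors = FALSE)
    }
    rownames(diagnoses) <- NULL

    truth <- data.frame(person_id = person_id, onset_ym = onset_ym,
                        stringsAsFactors = FALSE)

    structure(list(persons = persons, diagnoses = diagnoses, truth = truth,
                   period = period_label, baseline_year = baseline_year,
                   window = c(start = start_ym, end = end_ym)),
              class = "claims_panel")
  })
}

#' @export
print.claims_panel <- function(x, ...) {
  cat("Synthetic claims panel (", x$period, ", baseline ",
      x$baseline_year, ")\n", sep = "")
  cat("  persons:   ", nrow(x$persons), " (",
      sum(x$persons$sex == "women"), " women)\n", sep = "")
  cat("  diagnoses: ", nrow(x$diagnoses), " records\n", sep = "")
  cat("  true onsets: ", sum(!is.na(x$truth$onset_ym)), "\n", sep = "")
  cat("  window: ", format_ym(x$window[["start"]]), " .. ",
      format_ym(x$window[["end"]] - 1L), "\n", sep = "")
  invisible(x)
}
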