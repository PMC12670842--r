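# Three-state (illness-death) Markov life table and decrement-weighted
# average life expectancy.
#
# States: non-dementia -> dementia -> dead, plus non-dementia -> dead,
# governed by age-specific hazards DI(x), DM(x), non-DM(x) that are
# constant within single-year age intervals.  Everything is truncated at
# age 100: all expectancies are temporary expectancies between age x and
# 100, with no open-ended interval.

rate_mat <- function(rates) {
  stopifnot(inherits(rates, "data.frame"),
            all(c("age", "di", "dm", "nondm") %in% names(rates)))
  r <- rates[order(rates$age), , drop = FALSE]
  if (!identical(as.integer(r$age), 65:100)) {
    stop("rates must cover the complete integer age grid 65-100")
  }
  vals <- as.matrix(r[, c("di", "dm", "nondm")])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rates must be finite and non-negative")
  }
  vals
}

# Expected time to exit within a unit interval under constant hazard h,
# i.e. (1 - e^{-h})/h, continuous at h = 0.
interval_time <- function(h, width = 1) {
  ifelse(h > 0, (1 - exp(-h * width)) / h, width)
}

#' Build the three-state health-disease life table
#'
#' Constructs the multi-state life table on ages 65--100 with radix
#' `l_nd(65) = 1`.  Within each single-year interval the hazards are
#' constant, so the non-dementia survivors update as
#' `l_nd(x+1) = l_nd(x) e^{-h(x)}` with total exit hazard
#' `h(x) = DI(x) + nonDM(x)`, and the interval's exits split
#' proportionally to cause-specific hazards: the decrement to dementia is
#' `d(x) = l_nd(x)(1 - e^{-h(x)}) DI(x)/h(x)` and non-dementia deaths take
#' the rest, making the accounting identity
#' `l_nd(x) = l_nd(x+1) + d(x) + deaths_nd(x)` exact.  New dementia cases
#' enter the dementia state at mid-interval; dementia occupancy then
#' evolves under DM(x).  Person-years lived in each state (`L_nd`, `L_d`)
#' use the constant-hazard expected sojourn times.  The table is truncated
#' at 100: no exposure accrues beyond that age.
#'
#' @param rates A [transition_rates()] grid (or any data frame with
#'   columns `age` = 65:100, `di`, `dm`, `nondm`).
#' @return Data frame of class `dementia_lifetable` with one row per age:
#'   `l_nd`, `l_d`, `d`, `deaths_nd`, `deaths_d`, `L_nd`, `L_d` (interval
#'   columns are `NA` on the terminal row).
#' @export
build_lifetable <- function(rates) {
  m <- rate_mat(rates)
  n <- 35L
  l_nd <- l_d <- numeric(n + 1L)
  d <- deaths_nd <- deaths_d <- L_nd <- L_d <- numeric(n)
  l_nd[1L] <- 1

  for (i in seq_len(n)) {
    di <- m[i, "di"]; dm <- m[i, "dm"]; nm <- m[i, "nondm"]
    h <- di + nm
    surv <- exp(-h)
    l_nd[i + 1L] <- l_nd[i] * surv
    exits <- l_nd[i] - l_nd[i + 1L]       # exact complement
    d[i] <- if (h > 0) exits * (di / h) else 0
    deaths_nd[i] <- exits - d[i]          # keeps the accounting identity exact

    s_dm <- exp(-dm)
    s_half <- exp(-dm / 2)
    deaths_d[i] <- l_d[i] * (1 - s_dm) + d[i] * (1 - s_half)
    l_d[i + 1L] <- l_d[i] * s_dm + d[i] * s_half

    L_nd[i] <- l_nd[i] * interval_time(h)
    L_d[i] <- l_d[i] * interval_time(dm) +
      d[i] * interval_time(dm, width = 0.5)  # mid-interval entrants
  }

  out <- data.frame(age = 65:100,
                    l_nd = l_nd, l_d = l_d,
                    d = c(d, NA), deaths_nd = c(deaths_nd, NA),
                    deaths_d = c(deaths_d, NA),
                    L_nd = c(L_nd, NA), L_d = c(L_d, NA))
  class(out) <- c("dementia_lifetable", "data.frame")
  out
}

#' State-specific remaining life expectancies
#'
#' Temporary (truncated at 100) remaining life expectancies at each exact
#' integer age: `e_dem(x)` is the expected years lived between x and 100 by
#' a person in the dementia state at exact age x, i.e. survival under the
#' dementia mortality hazard DM alone; `e_nondem(x)` is the expected years
#' lived (in either state) by a person dementia-free at exact age x.  By
#' default `e_nondem` is computed in the full three-state model, so years
#' lived after a later dementia onset count towards it -- the reading that
#' makes the excess-life-years-lost contrast a like-for-like comparison of
#' two persons of the same age.  The alternative
#' `nondem_mode = "nondem_hazard_only"` treats non-DM as a plain survival
#' hazard instead.
#'
#' Both are computed by backward recursion over constant-hazard intervals;
#' transitions to dementia are taken to occur at mid-interval, consistent
#' with [build_lifetable()].
#'
#' @param rates A [transition_rates()] grid.
#' @param nondem_mode `"threestate"` (default) or `"nondem_hazard_only"`.
#' @return Data frame of class `state_expectancies` with columns `age`,
#'   `e_dem`, `e_nondem`; both are zero at age 100.
#' @export
state_expectancies <- function(rates,
                               nondem_mode = c("threestate",
                                               "nondem_hazard_only")) {
  nondem_mode <- match.arg(nondem_mode)
  m <- rate_mat(rates)
  n <- 35L
  e <- es <- numeric(n + 1L)   # e[i] at age 64 + i; terminal zero at 100

  for (i in n:1) {
    di <- m[i, "di"]; dm <- m[i, "dm"]; nm <- m[i, "nondm"]
    e[i] <- interval_time(dm) + exp(-dm) * e[i + 1L]
    if (nondem_mode == "threestate") {
      h <- di + nm
      p_onset <- if (h > 0) (1 - exp(-h)) * di / h else 0
      dem_years <- interval_time(dm, width = 0.5) + exp(-dm / 2) * e[i + 1L]
      es[i] <- interval_time(h) + p_onset * dem_years + exp(-h) * es[i + 1L]
    } else {
      es[i] <- interval_time(nm) + exp(-nm) * es[i + 1L]
    }
  }

  out <- data.frame(age = 65:100, e_dem = e, e_nondem = es)
  class(out) <- c("state_expectancies", "data.frame")
  out
}

#' Decrement-weighted average life expectancy with and without dementia
#'
#' Combines the age-specific expectancies into a single average life
#' expectancy (ALE) by weighting each age's expectancy with the life
#' table's normalised decrements to dementia, `w(x) = d(x) / sum(d)`: the
#' distribution of age at dementia onset in the stationary illness-death
#' population.  `ale_dem` is then the average years lived after onset,
#' `ale_nondem` the average years a same-aged dementia-free person would
#' live, their difference the excess life years lost (LYL), their sum the
#' total ALE, and `ratio = ale_dem / ale_total` the proportion of remaining
#' years lived with dementia.  Normalising the weights (rather than summing
#' raw decrements, which total the lifetime onset risk under radix 1) keeps
#' the ALE in years.
#'
#' @param exps A [state_expectancies()] table.
#' @param lt A [build_lifetable()] table built from the same rates.
#' @return A list of class `ale_result`: `ale_dem`, `ale_nondem`,
#'   `ale_total`, `lyl`, `ratio` and the weight distribution `weights`.
#' @export
average_life_expectancy <- function(exps, lt) {
  d <- lt$d[seq_len(35L)]
  if (sum(d) <= 0) {
    stop("undefined ALE: the life table has no decrements to dementia")
  }
  w <- d / sum(d)
  ale_dem <- sum(exps$e_dem[seq_len(35L)] * w)
  ale_nondem <- sum(exps$e_nondem[seq_len(35L)] * w)
  structure(list(ale_dem = ale_dem,
                 ale_nondem = ale_nondem,
                 ale_total = ale_dem + ale_nondem,
                 lyl = ale_nondem - ale_dem,
                 ratio = ale_dem / (ale_dem + ale_nondem),
                 weights = data.frame(age = 65:99, w = w)),
            class = "ale_result")
}

#' @export
print.ale_result <- function(x, digits = 2, ...) {
  cat(sprintf("Average life expectancy (ages 65-100, onset-age weighted):\n"))
  cat(sprintf("  with dementia:    %.*f years\n", digits, x$ale_dem))
  cat(sprintf("  without dementia: %.*f years\n", digits, x$ale_nondem))
  cat(sprintf("  total:            %.*f years\n", digits, x$ale_total))
  cat(sprintf("  excess LYL:       %.*f years\n", digits, x$lyl))
  cat(sprintf("  ratio dem/total:  %.*f\n", digits, x$ratio))
  invisible(x)
}

#' Average life expectancy straight from event tables
#'
#' Convenience wrapper for one stratum: smooths the rates
#' ([smooth_rates()]), builds the life table and expectancies, and returns
#' the ALE result.
#'
#' @inheritParams smooth_rates
#' @inheritParams state_expectancies
#' @return An `ale_result`.
#' @export
ale_from_tables <- function(event_tables, di_model = "kannisto",
                            nondem_mode = "threestate") {
  rates <- smooth_rates(event_tables, di_model = di_model)
  lt <- build_lifetable(rates)
  exps <- state_expectancies(rates, nondem_mode = nondem_mode)
  average_life_expectancy(exps, lt)
}
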