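# Person-years at risk and event counts by single year of age.

# Split person intervals [start, end) (integer months) at the persons'
# integer-age boundaries.  Returns one row per (person, age) with the months
# of overlap; exact month arithmetic, no rounding loss.
split_age_months <- function(start, end, birth) {
  a0 <- (start - birth) %/% 12L
  parts <- list()
  k <- 0L
  repeat {
    a <- a0 + k
    lo <- birth + 12L * a
    ov <- pmin(end, lo + 12L) - pmax(start, lo)
    sel <- which(ov > 0L)
    if (!length(sel)) break
    parts[[k + 1L]] <- data.frame(i = sel, age = a[sel], months = ov[sel])
    k <- k + 1L
  }
  if (!length(parts)) {
    return(data.frame(i = integer(), age = integer(), months = integer()))
  }
  do.call(rbind, parts)
}

cap_age <- function(age, max_age = 100L) {
  n_over <- sum(age > max_age)
  if (n_over > 0L) {
    message("pooling ", n_over, " cell contribution(s) above age ", max_age,
            " into age ", max_age)
  }
  pmin(age, max_age)
}

event_table_grid <- function(transition, period,
                             sexes = c("men", "women"), ages = 65:100) {
  g <- expand.grid(sex = sexes, age = ages, stringsAsFactors = FALSE)
  data.frame(transition = transition, sex = g$sex, period = period,
             age = g$age, events = 0L, person_years = 0,
             stringsAsFactors = FALSE)
}

accumulate_cells <- function(grid, sex, age, value, column) {
  if (!length(sex)) return(grid)
  key <- paste(sex, age)
  value <- rep(as.numeric(value), length.out = length(sex))
  sums <- rowsum(value, key)
  idx <- match(rownames(sums), paste(grid$sex, grid$age))
  grid[[column]][idx] <- grid[[column]][idx] + sums[, 1L]
  grid
}

#' Person-time and event counts by age, sex and transition
#'
#' Splits each person's follow-up at integer-age boundaries (exact-month
#' arithmetic, age in completed years) and tallies events and person-years
#' for the three transitions of the illness-death model: time before the
#' first valid diagnosis accrues to the shared DI / non-DM exposure, time
#' after it to DM exposure; a valid diagnosis is a DI event at the age of
#' diagnosis, a death before diagnosis a non-DM event, and a death after
#' (or at) diagnosis a DM event.  Ages above 100 are pooled into age 100.
#'
#' @param episodes An `episode_table` from [build_episodes()].
#' @param period Period label stored in the output tables; defaults to the
#'   episodes' `period` attribute.
#' @return Named list of three event tables (`di`, `dm`, `nondm`), each a
#'   data frame with columns `transition`, `sex`, `period`, `age`,
#'   `events`, `person_years` covering ages 65--100.
#' @export
person_time_slices <- function(episodes, period = NULL) {
  period <- period %||% attr(episodes, "period") %||% "P1"
  e <- as.data.frame(episodes)
  if (any(!is.na(e$first_valid_dx_ym) & e$first_valid_dx_ym > e$censor_ym)) {
    stop("inconsistent episodes: diagnosis after censoring for person(s) ",
         paste(utils::head(
           e$person_id[!is.na(e$first_valid_dx_ym) &
                         e$first_valid_dx_ym > e$censor_ym], 5L),
           collapse = ", "))
  }

  di <- event_table_grid("DI", period)
  dm <- event_table_grid("DM", period)
  nondm <- event_table_grid("nonDM", period)
  if (!nrow(e)) return(list(di = di, dm = dm, nondm = nondm))

  has_dx <- !is.na(e$first_valid_dx_ym)
  nd_end <- ifelse(has_dx, e$first_valid_dx_ym, e$censor_ym)

  # shared DI / non-DM exposure (pre-diagnosis)
  spl <- split_age_months(e$baseline_ym, nd_end, e$birth_ym)
  spl$age <- cap_age(spl$age)
  py <- spl$months / 12
  di <- accumulate_cells(di, e$sex[spl$i], spl$age, py, "person_years")
  nondm$person_years <- di$person_years

  # DM exposure (post-diagnosis)
  dxi <- which(has_dx)
  if (length(dxi)) {
    spl2 <- split_age_months(e$first_valid_dx_ym[dxi], e$censor_ym[dxi],
                             e$birth_ym[dxi])
    spl2$age <- cap_age(spl2$age)
    dm <- accumulate_cells(dm, e$sex[dxi][spl2$i], spl2$age,
                           spl2$months / 12, "person_years")
  }

  # events
  if (length(dxi)) {
    age_dx <- cap_age(age_completed(e$first_valid_dx_ym[dxi], e$birth_ym[dxi]))
    di <- accumulate_cells(di, e$sex[dxi], age_dx, 1L, "events")
  }
  dead <- which(e$censor_reason == "death")
  if (length(dead)) {
    age_death <- cap_age(age_completed(e$death_ym[dead], e$birth_ym[dead]))
    with_dx <- has_dx[dead]
    dm <- accumulate_cells(dm, e$sex[dead][with_dx], age_death[with_dx],
                           1L, "events")
    nondm <- accumulate_cells(nondm, e$sex[dead][!with_dx],
                              age_death[!with_dx], 1L, "events")
  }
  di$events <- as.integer(di$events)
  dm$events <- as.integer(dm$events)
  nondm$events <- as.integer(nondm$events)
  list(di = di, dm = dm, nondm = nondm)
}

#' Aggregate event rate per 1,000 person-years
#'
#' Crude rate with a 95% confidence interval from the Poisson normal
#' approximation on the count scale,
#' `rate +- 1.96 * 1000 * sqrt(events) / person_years`, the interval method
#' that reproduces published claims-cohort summary tables at one decimal.
#'
#' @param events Event count.
#' @param person_years Person-years at risk; must be positive.
#' @return One-row data frame: `events`, `person_years`, `rate_per_1000`,
#'   `ci_low`, `ci_high`.
#' @examples
#' aggregate_rate(2823, 145876)  # 19.4 per 1,000 person-years
#' @export
aggregate_rate <- function(events, person_years) {
  if (!is.finite(person_years) || person_years <= 0) {
    stop("undefined rate: person_years must be positive")
  }
  if (events < 0) stop("events must be non-negative")
  rate <- 1000 * events / person_years
  half <- 1.96 * 1000 * sqrt(events) / person_years
  data.frame(events = events, person_years = person_years,
             rate_per_1000 = rate,
             ci_low = max(0, rate - half), ci_high = rate + half)
}

#' Age-specific rates from an event table
#'
#' Divides events by person-years per single year of age.  Cells with zero
#' exposure are returned as `NA` ("missing"): at ages 80 and over they are
#' filled by smoothing ([smooth_rates()]); below 80 they are treated as
#' zero there, with a warning.
#'
#' @param table An event table (one transition; any sex/period strata).
#' @return The table with an added `rate` column (events per person-year).
#' @export
age_specific_rates <- function(table) {
  check_event_table(table)
  table$rate <- ifelse(table$person_years > 0,
                       table$events / table$person_years, NA_real_)
  table
}

check_event_table <- function(table) {
  need <- c("sex", "age", "events", "person_years")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(table$person_years < 0) || any(table$events < 0)) {
    stop("event table has negative counts or exposure")
  }
  if (any(table$events > 0 & table$person_years == 0)) {
    stop("event table has events in cells with zero person-years")
  }
  invisible(table)
}

#' Summary rate table across strata
#'
#' Builds the crude-rate summary of a study: one row per sex-by-period cell
#' of each transition plus the pooled (total) margin, each with events,
#' person-years and the [aggregate_rate()] confidence interval.
#'
#' @param event_tables Named list of event tables (`di`, `dm`, `nondm`),
#'   each covering all sex/period strata of the study.
#' @return Data frame with columns `transition`, `sex`, `period`, `events`,
#'   `person_years`, `rate_per_1000`, `ci_low`, `ci_high`.
#' @export
rate_summary <- function(event_tables) {
  rows <- list()
  for (nm in names(event_tables)) {
    tb <- event_tables[[nm]]
    cells <- unique(tb[, c("sex", "period")])
    cells <- cells[order(cells$sex, cells$period), , drop = FALSE]
    for (j in seq_len(nrow(cells))) {
      sub <- tb[tb$sex == cells$sex[j] & tb$period == cells$period[j], ]
      r <- aggregate_rate(sum(sub$events), sum(sub$person_years))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(transition = tb$transition[1L],
                         sex = cells$sex[j], period = cells$period[j]), r)
    }
    r <- aggregate_rate(sum(tb$events), sum(tb$person_years))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(transition = tb$transition[1L],
                       sex = "total", period = "total"), r)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
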