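#' Dementia case definition
#'
#' The ICD-10 code set and eligibility windows used to identify internally
#' validated incident dementia in claims panels.
#'
#' @param code_set ICD-10 prefixes identifying dementia.  Matching is by
#'   prefix on the dot-stripped code, so `"F05.1"` matches records coded
#'   `F051` or `F05.1` but not `F05.0`.
#' @param washout_years Years of dementia-free, continuously covered lead-in
#'   required before baseline, excluding prevalent cases.
#' @param followup_years Length of the follow-up window after baseline.
#' @param min_age Minimum age (completed years) at baseline.
#' @return A list of class `case_definition`.
#' @export
case_definition <- function(code_set = c("G30", "F00", "F01", "F02",
                                         "F03", "F05.1"),
                            washout_years = 2L,
                            followup_years = 3L,
                            min_age = 65L) {
  if (length(code_set) < 1L) stop("code_set must be non-empty")
  washout_years <- as.integer(washout_years)
  followup_years <- as.integer(followup_years)
  if (is.na(washout_years) || washout_years < 0L) {
    stop("washout_years must be >= 0")
  }
  if (is.na(followup_years) || followup_years < 1L) {
    stop("followup_years must be >= 1")
  }
  structure(list(code_set = code_set, washout_years = washout_years,
                 followup_years = followup_years,
                 min_age = as.integer(min_age)),
            class = "case_definition")
}

#' Internally validate dementia diagnoses
#'
#' Applies the claims-data case definition to a panel's diagnosis records.
#' A record is admissible if its code matches the dementia code set and it
#' is either an outpatient diagnosis marked verified or an inpatient
#' discharge/secondary diagnosis.  A person has a valid dementia diagnosis
#' if they accumulate at least two admissible records anywhere in the
#' observation period (which covers the stricter same-quarter case), or a
#' single admissible record in the quarter of their death.  The first valid
#' diagnosis is dated to the person's earliest admissible record, assigned
#' to the middle month of its quarter; when that quarter is the death
#' quarter the date is clamped to the death month, so the person dies in
#' the dementia state.
#'
#' @param panel A `claims_panel` (see [simulate_cohort()] or
#'   [read_claims_panel()]).
#' @param cdef A [case_definition()].
#' @return Data frame with columns `person_id` and `first_valid_dx_ym`
#'   (integer month), one row per person with a valid diagnosis.
#' @export
validate_diagnoses <- function(panel, cdef = case_definition()) {
  dg <- panel$diagnoses
  known_settings <- c("outpatient", "inpatient_discharge", "inpatient_secondary")
  known_status <- c("verified", "unverified")
  bad <- which(!(dg$setting %in% known_settings) | !(dg$status %in% known_status))
  if (length(bad)) {
    stop("unknown setting/status values in diagnosis rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  }
  empty <- data.frame(person_id = character(),
                      first_valid_dx_ym = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(dg)) return(empty)

  codes <- toupper(gsub(".", "", dg$code, fixed = TRUE))
  prefixes <- toupper(gsub(".", "", cdef$code_set, fixed = TRUE))
  is_dem <- Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)))
  admissible <- is_dem &
    (dg$setting != "outpatient" | dg$status == "verified")
  d <- dg[admissible, c("person_id", "year", "quarter"), drop = FALSE]
  if (!nrow(d)) return(empty)

  d$yq <- d$year * 4L + d$quarter - 1L
  per <- panel$persons
  death_ym <- per$death_ym[match(d$person_id, per$person_id)]
  death_yq <- death_ym %/% 3L
  # records after the death quarter cannot establish a diagnosis
  keep <- is.na(death_yq) | d$yq <= death_yq
  d <- d[keep, , drop = FALSE]
  death_yq <- death_yq[keep]
  if (!nrow(d)) return(empty)

  ord <- order(d$person_id, d$yq)
  d <- d[ord, , drop = FALSE]
  death_yq <- death_yq[ord]
  r <- rle(d$person_id)
  first_idx <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  pid <- r$values
  n_adm <- r$lengths
  first_yq <- d$yq[first_idx]
  dq <- death_yq[first_idx]

  valid <- n_adm >= 2L | (!is.na(dq) & first_yq == dq)
  pid <- pid[valid]
  first_yq <- first_yq[valid]
  if (!length(pid)) return(empty)

  dx_ym <- yq_mid_ym(first_yq)
  dym <- per$death_ym[match(pid, per$person_id)]
  clamp <- !is.na(dym) & (dym %/% 3L) == first_yq & dx_ym > dym
  dx_ym[clamp] <- dym[clamp]
  data.frame(person_id = pid, first_valid_dx_ym = as.integer(dx_ym),
             stringsAsFactors = FALSE)
}

#' Build the analysis episodes of one period cohort
#'
#' Selects the analysis sample -- persons at or above the minimum age at
#' baseline, continuously covered through the wash-out window, with no
#' valid dementia diagnosis before baseline -- and assigns each person a
#' first valid diagnosis date, death date and censoring date within the
#' follow-up window.  Persons leaving the insurer are censored at the month
#' after their last covered month; everyone still under observation is
#' censored at the end of the follow-up window.
#'
#' @param panel A `claims_panel` spanning at least
#'   `[baseline - washout_years, baseline + followup_years)`.
#' @param cdef A [case_definition()].
#' @param baseline_year Baseline calendar year; defaults to the panel's own.
#' @return Data frame of class `episode_table` with columns `person_id`,
#'   `sex`, `birth_ym`, `entry_age`, `baseline_ym`, `first_valid_dx_ym`,
#'   `death_ym`, `censor_ym`, `censor_reason` (one of `death`,
#'   `coverage_end`, `study_end`).  The cohort period label is carried as
#'   attribute `period`.
#' @export
build_episodes <- function(panel, cdef = case_definition(),
                           baseline_year = NULL) {
  baseline_year <- baseline_year %||% panel$baseline_year
  base <- ym(baseline_year, 1L)
  wstart <- base - 12L * cdef$washout_years
  fu_end <- base + 12L * cdef$followup_years
  win <- panel$window
  if (!is.null(win) && (win[["start"]] > wstart || win[["end"]] < fu_end)) {
    stop("panel window ", format_ym(win[["start"]]), "..",
         format_ym(win[["end"]] - 1L),
         " does not cover the study window ", format_ym(wstart), "..",
         format_ym(fu_end - 1L))
  }

  per <- panel$persons
  vd <- validate_diagnoses(panel, cdef)
  dx <- vd$first_valid_dx_ym[match(per$person_id, vd$person_id)]

  entry_age <- age_completed(base, per$birth_ym)
  eligible <- entry_age >= cdef$min_age &
    per$coverage_start_ym <= wstart &
    per$coverage_end_ym >= base &
    (is.na(per$death_ym) | per$death_ym >= base) &
    (is.na(dx) | dx >= base)

  per <- per[eligible, , drop = FALSE]
  dx <- dx[eligible]
  entry_age <- entry_age[eligible]

  censor <- pmin(per$coverage_end_ym + 1L, fu_end)
  reason <- ifelse(censor < fu_end, "coverage_end", "study_end")
  is_death <- !is.na(per$death_ym) & per$death_ym <= censor
  censor[is_death] <- per$death_ym[is_death]
  reason[is_death] <- "death"

  # diagnosis counts only inside the follow-up; a diagnosis in the censor
  # month itself counts only at death (tie: diagnosis first, death with
  # dementia)
  dx_in <- !is.na(dx) & dx >= base &
    (dx < censor | (dx == censor & reason == "death"))
  dx[!dx_in] <- NA_integer_

  out <- data.frame(person_id = per$person_id, sex = per$sex,
                    birth_ym = per$birth_ym, entry_age = entry_age,
                    baseline_ym = base,
                    first_valid_dx_ym = dx,
                    death_ym = ifelse(is_death, per$death_ym, NA_integer_),
                    censor_ym = as.integer(censor),
                    censor_reason = reason,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "period") <- panel$period
  class(out) <- c("episode_table", "data.frame")
  out
}
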