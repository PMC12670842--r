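# CSV interfaces.  All on-disk formats are plain CSV; year-month columns
# are written as "YYYY-MM" strings and parsed back to integer months.

read_checked_csv <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("format error: ", path, " is empty")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df) && !ncol(df)) stop("format error: ", path, " is empty")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  }
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & nzchar(trimws(df[[cl]])))
    if (length(bad)) {
      stop("format error in ", path, ": non-numeric '", cl, "' on line(s) ",
           paste(utils::head(bad + 1L, 5L), collapse = ", "))  # +1 header
    }
    df[[cl]] <- v
  }
  df[required]
}

#' Write / read a claims panel as CSV files
#'
#' `write_claims_panel()` writes `persons.csv`, `diagnoses.csv` and (when
#' ground truth is present) `truth.csv` into a directory;
#' `read_claims_panel()` reads them back.  Month columns use `YYYY-MM`.
#'
#' @param panel A `claims_panel`.
#' @param dir Directory path (created if needed).
#' @param period,baseline_year Cohort labels for `read_claims_panel()`,
#'   when the directory lacks a `panel.csv` metadata file.
#' @return `write_claims_panel()` returns `dir` invisibly;
#'   `read_claims_panel()` returns a `claims_panel`.
#' @export
write_claims_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- panel$persons
  p$birth_ym <- format_ym(p$birth_ym)
  p$death_ym <- format_ym(p$death_ym)
  p$coverage_start_ym <- format_ym(p$coverage_start_ym)
  p$coverage_end_ym <- format_ym(p$coverage_end_ym)
  utils::write.csv(p, file.path(dir, "persons.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(panel$diagnoses, file.path(dir, "diagnoses.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(panel$truth)) {
    tr <- panel$truth
    tr$onset_ym <- format_ym(tr$onset_ym)
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE,
                     na = "")
  }
  meta <- data.frame(period = panel$period,
                     baseline_year = panel$baseline_year,
                     window_start = format_ym(panel$window[["start"]]),
                     window_end = format_ym(panel$window[["end"]]))
  utils::write.csv(meta, file.path(dir, "panel.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_claims_panel
#' @export
read_claims_panel <- function(dir, period = "P1", baseline_year = NULL) {
  p <- read_checked_csv(file.path(dir, "persons.csv"),
                        c("person_id", "sex", "birth_ym", "death_ym",
                          "coverage_start_ym", "coverage_end_ym"))
  for (cl in c("birth_ym", "death_ym", "coverage_start_ym",
               "coverage_end_ym")) {
    p[[cl]] <- parse_ym(p[[cl]])
  }
  dg <- read_checked_csv(file.path(dir, "diagnoses.csv"),
                         c("person_id", "year", "quarter", "code",
                           "setting", "status"),
                         numeric_cols = c("year", "quarter"))
  dg$year <- as.integer(dg$year)
  dg$quarter <- as.integer(dg$quarter)
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    truth <- read_checked_csv(file.path(dir, "truth.csv"),
                              c("person_id", "onset_ym"))
    truth$onset_ym <- parse_ym(truth$onset_ym)
  }
  meta_path <- file.path(dir, "panel.csv")
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    period <- meta$period[1L]
    baseline_year <- meta$baseline_year[1L]
    window <- c(start = parse_ym(meta$window_start[1L]),
                end = parse_ym(meta$window_end[1L]))
  } else {
    window <- c(start = min(p$coverage_start_ym),
                end = max(p$coverage_end_ym, na.rm = TRUE) + 1L)
  }
  structure(list(persons = p, diagnoses = dg, truth = truth,
                 period = period, baseline_year = baseline_year,
                 window = window),
            class = "claims_panel")
}

#' Write / read an event table CSV
#'
#' Event tables round-trip losslessly through
#' `write_event_table()` / `read_rate_table()`.  The reader validates the
#' header (`transition, sex, period, age, events, person_years`), reports
#' malformed numeric rows with their line numbers, accepts (and warns
#' about) unknown extra columns, and rejects empty files.
#'
#' @param table An event table.
#' @param path CSV path.
#' @return `read_rate_table()` returns the event table data frame.
#' @export
write_event_table <- function(table, path) {
  check_event_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_rate_table <- function(path) {
  df <- read_checked_csv(path,
                         c("transition", "sex", "period", "age", "events",
                           "person_years"),
                         numeric_cols = c("age", "events", "person_years"))
  df$age <- as.integer(df$age)
  df$events <- as.integer(df$events)
  check_event_table(df)
  df
}

#' @rdname build_episodes
#' @param episodes An `episode_table`.
#' @param path CSV path.
#' @export
write_episodes <- function(episodes, path) {
  e <- as.data.frame(episodes)
  for (cl in c("birth_ym", "baseline_ym", "first_valid_dx_ym", "death_ym",
               "censor_ym")) {
    e[[cl]] <- format_ym(e[[cl]])
  }
  e$period <- attr(episodes, "period") %||% NA_character_
  utils::write.csv(e, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname build_episodes
#' @export
read_episodes <- function(path) {
  e <- read_checked_csv(path,
                        c("person_id", "sex", "birth_ym", "entry_age",
                          "baseline_ym", "first_valid_dx_ym", "death_ym",
                          "censor_ym", "censor_reason", "period"),
                        numeric_cols = "entry_age")
  period <- e$period[1L]
  e$period <- NULL
  for (cl in c("birth_ym", "baseline_ym", "first_valid_dx_ym", "death_ym",
               "censor_ym")) {
    e[[cl]] <- parse_ym(e[[cl]])
  }
  e$entry_age <- as.integer(e$entry_age)
  attr(e, "period") <- period
  class(e) <- c("episode_table", "data.frame")
  e
}
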