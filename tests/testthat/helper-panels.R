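# Hand-built miniature claims panels for rule-level tests.

mini_panel <- function(persons, diagnoses = NULL, baseline_year = 2006,
                       period = "P1") {
  base <- 12L * baseline_year
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(person_id = character(), year = integer(),
                            quarter = integer(), code = character(),
                            setting = character(), status = character(),
                            stringsAsFactors = FALSE)
  }
  structure(list(persons = persons, diagnoses = diagnoses, truth = NULL,
                 period = period, baseline_year = baseline_year,
                 window = c(start = base - 24L, end = base + 36L)),
            class = "claims_panel")
}

# a person born `age` years before baseline, fully covered over the panel
mini_person <- function(id, age = 75, sex = "men", baseline_year = 2006,
                        death_ym = NA_integer_, coverage_end_ym = NULL) {
  base <- 12L * baseline_year
  data.frame(person_id = id, sex = sex,
             birth_ym = base - 12L * age,
             death_ym = death_ym,
             coverage_start_ym = base - 24L,
             coverage_end_ym = coverage_end_ym %||%
               as.integer(min(base + 35L, death_ym, na.rm = TRUE)),
             stringsAsFactors = FALSE)
}

mini_dx <- function(id, year, quarter, code = "F03",
                    setting = "outpatient", status = "verified") {
  data.frame(person_id = id, year = as.integer(year),
             quarter = as.integer(quarter), code = code,
             setting = setting, status = status, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# event table for one stratum directly from age-specific counts
stratum_tables <- function(di_events, di_py, dm_events, dm_py,
                           nondm_events = NULL, sex = "women",
                           period = "P1", ages = 65:100) {
  mk <- function(tr, ev, py) {
    data.frame(transition = tr, sex = sex, period = period, age = ages,
               events = as.integer(round(ev)), person_years = py,
               stringsAsFactors = FALSE)
  }
  list(di = mk("DI", di_events, di_py),
       dm = mk("DM", dm_events, dm_py),
       nondm = mk("nonDM", nondm_events %||% (di_py * 0.03), di_py))
}
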