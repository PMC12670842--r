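# Internal calendar arithmetic.
#
# Vital events carry month precision, diagnoses quarter precision, so all
# internal time is integer: `ym` counts months since year 0 (year*12 + month-1)
# and `yq` counts calendar quarters since year 0.  Because months are grouped
# in aligned blocks of three, yq == ym %/% 3.

ym <- function(year, month = 1L) {
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

ym_year <- function(x) x %/% 12L
ym_month <- function(x) x %% 12L + 1L

format_ym <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%04d-%02d", x[ok] %/% 12L, x[ok] %% 12L + 1L)
  out
}

parse_ym <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & grepl("^[0-9]{4}-[0-9]{2}$", x)
  bad <- !is.na(x) & !grepl("^[0-9]{4}-[0-9]{2}$", x) & nzchar(trimws(x))
  if (any(bad)) {
    stop("malformed year-month value(s): ",
         paste(utils::head(unique(x[bad]), 5L), collapse = ", "))
  }
  out[ok] <- as.integer(substr(x[ok], 1L, 4L)) * 12L +
    as.integer(substr(x[ok], 6L, 7L)) - 1L
  out
}

ym_to_yq <- function(x) x %/% 3L
yq_year <- function(q) q %/% 4L
yq_quarter <- function(q) q %% 4L + 1L

# Middle month of a quarter (Feb, May, Aug, Nov): unbiased month assignment
# for a quarter-resolved event under uniform within-quarter timing.
yq_mid_ym <- function(q) q * 3L + 1L

# Age in completed years at month `at`, month-level floor.
age_completed <- function(at, birth) (at - birth) %/% 12L

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-stream seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
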