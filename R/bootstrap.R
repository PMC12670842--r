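# Binomial bootstrap of age-specific event counts through the smoothing +
# life-table pipeline.

#' Bootstrap configuration
#'
#' @param replications Number of bootstrap replicates.
#' @param seed Optional integer seed; when given, repeated calls reproduce
#'   identical replicate sequences.
#' @param ci_level Confidence level of the percentile interval.
#' @param resample_set Which event series are resampled.  The default
#'   resamples incident dementia cases and dementia deaths only, treating
#'   the (much larger-count) non-dementia death series as fixed; set to
#'   `c("di", "dm", "nondm")` to resample all three.
#' @param method `"binomial"` (default): counts are redrawn as
#'   `Binomial(round(person_years), events / round(person_years))`, one
#'   trial per person-year.  `"poisson"` is offered as a sensitivity check.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(replications = 1000L, seed = NULL,
                             ci_level = 0.95,
                             resample_set = c("di", "dm"),
                             method = c("binomial", "poisson")) {
  replications <- as.integer(replications)
  if (is.na(replications) || replications < 1L) {
    stop("replications must be >= 1")
  }
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie strictly between 0 and 1")
  }
  stopifnot(all(resample_set %in% c("di", "dm", "nondm")))
  structure(list(replications = replications,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 ci_level = ci_level,
                 resample_set = resample_set,
                 method = match.arg(method)),
            class = "bootstrap_config")
}

#' Resample an event table's counts
#'
#' Draws one bootstrap replicate of the age-specific counts: for each cell,
#' `events* ~ Binomial(n, p)` with `n = round(person_years)` and
#' `p = events / n` (exposures unchanged).  Cells whose count exceeds the
#' rounded exposure are clipped to `p = 1` with a warning.  Uses the
#' current RNG state.
#'
#' @param table An event table.
#' @param method `"binomial"` or `"poisson"` (`events* ~ Poisson(events)`).
#' @return The table with resampled `events`.
#' @export
resample_counts <- function(table, method = c("binomial", "poisson")) {
  method <- match.arg(method)
  check_event_table(table)
  if (method == "poisson") {
    table$events <- stats::rpois(nrow(table), table$events)
    return(table)
  }
  n <- as.integer(round(table$person_years))
  p <- ifelse(n > 0, table$events / n, 0)
  if (any(p > 1)) {
    warning("events exceed rounded person-years in ", sum(p > 1),
            " cell(s); resampling probability clipped to 1")
    p <- pmin(p, 1)
  }
  ev <- integer(nrow(table))
  pos <- n > 0L
  ev[pos] <- stats::rbinom(sum(pos), n[pos], p[pos])
  table$events <- ev
  table
}

#' Bootstrap confidence intervals for the ALE quantities
#'
#' Re-runs the entire rates -> smoothing -> life table -> ALE pipeline on
#' each bootstrap replicate of the age-specific event counts and returns
#' percentile confidence intervals for ALE with/without dementia, total
#' ALE, excess life years lost and the dementia/total ratio.  Point
#' estimates come from the unresampled data, never the replicate mean.
#' Replicates whose smoothing fit fails are dropped and counted; more than
#' 5% failures abort with an error (unstable stratum).
#'
#' @param event_tables Named list `di`, `dm`, `nondm` of single-stratum
#'   event tables.
#' @param cfg A [bootstrap_config()].
#' @param di_model,nondem_mode Passed to [ale_from_tables()].
#' @param keep_replicates If `TRUE`, the replicate matrix is attached.
#' @return A list of class `ale_ci`: `point` (the `ale_result`), `ci` (data
#'   frame metric/point/lo/hi), `n_reps_used`, `ci_level` and optionally
#'   `replicates`.
#' @export
bootstrap_ale <- function(event_tables, cfg = bootstrap_config(),
                          di_model = "kannisto", nondem_mode = "threestate",
                          keep_replicates = FALSE) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  point <- ale_from_tables(event_tables, di_model = di_model,
                           nondem_mode = nondem_mode)
  metrics <- c("ale_dem", "ale_nondem", "ale_total", "lyl", "ratio")

  run <- function() {
    reps <- matrix(NA_real_, nrow = cfg$replications, ncol = length(metrics),
                   dimnames = list(NULL, metrics))
    for (r in seq_len(cfg$replications)) {
      tabs <- event_tables
      for (s in cfg$resample_set) {
        tabs[[s]] <- resample_counts(tabs[[s]], method = cfg$method)
      }
      a <- tryCatch(
        suppressWarnings(ale_from_tables(tabs, di_model = di_model,
                                         nondem_mode = nondem_mode)),
        error = function(e) NULL)
      if (!is.null(a)) reps[r, ] <- unlist(a[metrics])
    }
    reps
  }
  reps <- if (is.null(cfg$seed)) run() else with_seed(cfg$seed, run())

  ok <- stats::complete.cases(reps)
  if (mean(!ok) > 0.05) {
    stop("unstable stratum: ", sum(!ok), " of ", cfg$replications,
         " bootstrap replicates failed the smoothing fit")
  }
  used <- reps[ok, , drop = FALSE]
  alpha <- 1 - cfg$ci_level
  qs <- apply(used, 2L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  ci <- data.frame(metric = metrics,
                   point = unlist(point[metrics]),
                   lo = qs[1L, ], hi = qs[2L, ], row.names = NULL)
  out <- list(point = point, ci = ci, n_reps_used = sum(ok),
              ci_level = cfg$ci_level)
  if (keep_replicates) out$replicates <- used
  class(out) <- "ale_ci"
  out
}

#' @export
print.ale_ci <- function(x, digits = 2, ...) {
  cat(sprintf("ALE with %d%% percentile bootstrap CIs (%d replicates):\n",
              round(100 * x$ci_level), x$n_reps_used))
  for (i in seq_len(nrow(x$ci))) {
    cat(sprintf("  %-10s %.*f  [%.*f, %.*f]\n", x$ci$metric[i],
                digits, x$ci$point[i], digits, x$ci$lo[i],
                digits, x$ci$hi[i]))
  }
  invisible(x)
}

#' Non-overlap significance of two interval estimates
#'
#' Declares a difference significant when the two confidence intervals do
#' not overlap, the decision rule used with bootstrap percentile intervals
#' when no joint resampling distribution is available.
#'
#' @param a,b Interval estimates: either numeric `c(lo, hi)` or lists with
#'   elements `lo` and `hi`.
#' @return `TRUE` iff the intervals are disjoint.
#' @examples
#' nonoverlap_significant(c(1, 2), c(3, 4))  # TRUE
#' nonoverlap_significant(c(1, 3), c(2, 4))  # FALSE
#' @export
nonoverlap_significant <- function(a, b) {
  bounds <- function(x) {
    if (is.numeric(x) && length(x) == 2L) {
      list(lo = min(x), hi = max(x))
    } else if (!is.null(x$lo) && !is.null(x$hi)) {
      list(lo = x$lo, hi = x$hi)
    } else {
      stop("interval must be c(lo, hi) or a list with lo and hi")
    }
  }
  a <- bounds(a); b <- bounds(b)
  if (a$lo > a$hi || b$lo > b$hi) stop("invalid interval: lo > hi")
  a$hi < b$lo || b$hi < a$lo
}
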