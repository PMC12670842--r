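# End-to-end orchestration: simulate -> validate -> exposure ->
# trends / smoothing -> life table -> bootstrap.

#' Study run configuration
#'
#' Bundles the stage configurations of a full study run.  All randomness
#' flows from the single `seed`: the simulator uses it directly (with
#' per-period substreams) and the bootstrap uses a derived substream per
#' stratum, so two runs with equal configuration are identical.
#'
#' @param sim A [sim_config()]; its `seed` is overridden by `seed`.
#' @param case_def A [case_definition()].
#' @param bootstrap A [bootstrap_config()], or `NULL` to skip bootstrap
#'   CIs.
#' @param di_model Smoothing model for the incidence transition.
#' @param nondem_mode Interpretation of the non-dementia expectancy, see
#'   [state_expectancies()].
#' @param centering_ages Optional named list of centering-age overrides for
#'   [fit_trend()], keyed `"<transition>.<sex>"` (e.g. `di.men = 73.92`).
#' @param stages Character vector of enabled stages, in pipeline order.
#' @param rate_tables Optional mid-stream entry point: a named list `di`,
#'   `dm`, `nondm` of event tables (or CSV paths readable by
#'   [read_rate_table()]).  When given, the simulate/validate stages are
#'   skipped.
#' @param out_dir Optional output directory for stage CSVs and the run
#'   manifest.
#' @param seed Global integer seed.
#' @param verbose Emit progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), case_def = case_definition(),
                       bootstrap = bootstrap_config(),
                       di_model = "kannisto", nondem_mode = "threestate",
                       centering_ages = NULL,
                       stages = c("simulate", "validate", "rates", "trends",
                                  "lifetable", "bootstrap"),
                       rate_tables = NULL, out_dir = NULL, seed = 1L,
                       verbose = TRUE) {
  known <- c("simulate", "validate", "rates", "trends", "lifetable",
             "bootstrap")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(sim = sim, case_def = case_def, bootstrap = bootstrap,
                 di_model = di_model, nondem_mode = nondem_mode,
                 centering_ages = centering_ages, stages = stages,
                 rate_tables = rate_tables, out_dir = out_dir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[setdiff(names(cfg), c("out_dir", "verbose"))], f)
  unname(tools::md5sum(f))
}

#' Run the full dementia-burden study pipeline
#'
#' Executes the enabled stages in order on synthetic cohorts (or on
#' supplied mid-stream rate tables) and returns the study summary: a
#' crude-rate table by transition, sex and period; period rate-ratio trend
#' fits; and the ALE / excess-LYL / ratio table per stratum with bootstrap
#' confidence intervals.  With `out_dir` set, all stage outputs are written
#' as CSV plus a machine-readable JSON run manifest (versions, seed,
#' configuration hash).
#'
#' @param cfg A [run_config()].
#' @return A list of class `dementia_study`: `rates_summary`, `trends`,
#'   `ale`, `lifetables`, `rates_smoothed`, `event_tables`, `manifest`.
#' @export
run_all <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (cfg$verbose) message(...)
  stage_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tabs <- NULL       # list(di, dm, nondm), all strata stacked
  episodes <- list()
  if (!is.null(cfg$rate_tables)) {
    say("using supplied rate tables (mid-stream entry)")
    tabs <- stage_guard("rates", lapply(cfg$rate_tables, function(x) {
      if (is.character(x)) read_rate_table(x) else check_event_table(x)
    }))
  } else if (any(c("simulate", "validate") %in% cfg$stages)) {
    cfg$sim$seed <- cfg$seed
    per_period <- list()
    for (p in c("P1", "P2")) {
      say("simulating cohort ", p, " (n = ", cfg$sim$n_per_cohort, ")")
      panel <- stage_guard("simulate", simulate_cohort(cfg$sim, p))
      say("validating diagnoses and building episodes, ", p)
      ep <- stage_guard("validate", build_episodes(panel, cfg$case_def))
      episodes[[p]] <- ep
      per_period[[p]] <- stage_guard("rates", person_time_slices(ep, p))
      if (!is.null(cfg$out_dir)) {
        write_claims_panel(panel, file.path(cfg$out_dir, paste0("panel_", p)))
        write_episodes(ep, file.path(cfg$out_dir,
                                     paste0("episodes_", p, ".csv")))
      }
    }
    tabs <- lapply(c(di = "di", dm = "dm", nondm = "nondm"), function(tr) {
      do.call(rbind, lapply(per_period, `[[`, tr))
    })
  } else {
    stop("no input: enable simulate/validate or supply rate_tables")
  }

  out <- list(event_tables = tabs)

  if ("rates" %in% cfg$stages) {
    out$rates_summary <- stage_guard("rates", rate_summary(tabs))
  }

  if ("trends" %in% cfg$stages) {
    say("fitting period-trend models")
    rows <- list()
    for (tr in names(tabs)) {
      for (s in unique(tabs[[tr]]$sex)) {
        sub <- tabs[[tr]][tabs[[tr]]$sex == s, , drop = FALSE]
        ca <- cfg$centering_ages[[paste(tr, s, sep = ".")]]
        fit <- tryCatch(fit_trend(sub, centering_age = ca),
                        error = function(e) e)
        rows[[paste(tr, s)]] <- if (inherits(fit, "error")) {
          data.frame(transition = tr, sex = s, rr_period = NA, ci_low = NA,
                     ci_high = NA, p_value = NA, dispersion = NA,
                     centering_age = NA,
                     note = conditionMessage(fit))
        } else {
          data.frame(transition = tr, sex = s, rr_period = fit$rr_period,
                     ci_low = fit$ci_low, ci_high = fit$ci_high,
                     p_value = fit$p_value, dispersion = fit$dispersion,
                     centering_age = fit$centering_age,
                     note = if (length(fit$notes)) fit$notes[1L] else "")
        }
      }
    }
    out$trends <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  if ("lifetable" %in% cfg$stages) {
    say("smoothing rates and building life tables")
    strata <- unique(do.call(rbind,
                             lapply(tabs, function(t) t[, c("sex", "period")])))
    strata <- strata[order(strata$sex, strata$period), , drop = FALSE]
    out$rates_smoothed <- list()
    out$lifetables <- list()
    ale_rows <- list()
    boot_i <- 0L
    for (j in seq_len(nrow(strata))) {
      s <- strata$sex[j]; p <- strata$period[j]
      key <- paste(s, p, sep = ".")
      sub <- lapply(tabs, function(t) {
        t[t$sex == s & t$period == p, , drop = FALSE]
      })
      rates <- stage_guard("lifetable",
                           smooth_rates(sub, di_model = cfg$di_model))
      lt <- build_lifetable(rates)
      exps <- state_expectancies(rates, nondem_mode = cfg$nondem_mode)
      ale <- average_life_expectancy(exps, lt)
      out$rates_smoothed[[key]] <- rates
      out$lifetables[[key]] <- lt
      row <- data.frame(sex = s, period = p,
                        ale_dem = ale$ale_dem, ale_nondem = ale$ale_nondem,
                        ale_total = ale$ale_total, lyl = ale$lyl,
                        ratio = ale$ratio)
      if ("bootstrap" %in% cfg$stages && !is.null(cfg$bootstrap)) {
        boot_i <- boot_i + 1L
        say("bootstrap (", cfg$bootstrap$replications, " reps), stratum ",
            key)
        bcfg <- cfg$bootstrap
        bcfg$seed <- derive_seed(cfg$seed, 7919L * boot_i)
        bb <- stage_guard("bootstrap",
                          bootstrap_ale(sub, bcfg, di_model = cfg$di_model,
                                        nondem_mode = cfg$nondem_mode))
        ci <- bb$ci
        for (m in ci$metric) {
          row[[paste0(m, "_lo")]] <- ci$lo[ci$metric == m]
          row[[paste0(m, "_hi")]] <- ci$hi[ci$metric == m]
        }
        row$n_reps_used <- bb$n_reps_used
      }
      ale_rows[[key]] <- row
    }
    out$ale <- do.call(rbind, c(ale_rows, make.row.names = FALSE))
  }

  out$manifest <- list(
    package = "demlife",
    version = as.character(utils::packageVersion("demlife")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    stages = cfg$stages,
    n_per_cohort = if (is.null(cfg$rate_tables)) cfg$sim$n_per_cohort else NA,
    config_hash = config_hash(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tr in names(tabs)) {
      write_event_table(tabs[[tr]],
                        file.path(cfg$out_dir,
                                  paste0("event_table_", tr, ".csv")))
    }
    if (!is.null(out$rates_summary)) {
      utils::write.csv(out$rates_summary,
                       file.path(cfg$out_dir, "rates_summary.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$trends)) {
      utils::write.csv(out$trends,
                       file.path(cfg$out_dir, "trend_results.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$ale)) {
      utils::write.csv(out$ale, file.path(cfg$out_dir, "ale_results.csv"),
                       row.names = FALSE)
      sm <- do.call(rbind, lapply(names(out$rates_smoothed), function(k) {
        r <- out$rates_smoothed[[k]]
        cbind(sex = attr(r, "sex"), period = attr(r, "period"),
              as.data.frame(r))
      }))
      utils::write.csv(sm, file.path(cfg$out_dir, "smoothed_rates.csv"),
                       row.names = FALSE)
      lt <- do.call(rbind, lapply(names(out$lifetables), function(k) {
        cbind(stratum = k, as.data.frame(out$lifetables[[k]]))
      }))
      utils::write.csv(lt, file.path(cfg$out_dir, "lifetable.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(out$manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  class(out) <- "dementia_study"
  out
}

#' @export
print.dementia_study <- function(x, ...) {
  cat("Dementia burden study (seed ", x$manifest$seed, ")\n", sep = "")
  if (!is.null(x$rates_summary)) {
    cat("\nCrude rates per 1,000 person-years:\n")
    rs <- x$rates_summary
    rs[, c("person_years", "rate_per_1000", "ci_low", "ci_high")] <-
      round(rs[, c("person_years", "rate_per_1000", "ci_low", "ci_high")], 1)
    print(rs, row.names = FALSE)
  }
  if (!is.null(x$trends)) {
    cat("\nPeriod rate ratios (P2 vs P1):\n")
    tr <- x$trends[, c("transition", "sex", "rr_period", "ci_low",
                       "ci_high", "p_value")]
    tr[, 3:6] <- round(tr[, 3:6], 3)
    print(tr, row.names = FALSE)
  }
  if (!is.null(x$ale)) {
    cat("\nAverage life expectancy (years), onset-age weighted:\n")
    al <- x$ale
    num <- vapply(al, is.numeric, logical(1L))
    al[num] <- round(al[num], 2)
    print(al, row.names = FALSE)
  }
  invisible(x)
}
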