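# Kannisto logistic smoothing of old-age transition rates.

#' Kannisto logistic hazard
#'
#' `mu(x) = a e^{b (x - 80)} / (1 + a e^{b (x - 80)})`: a logistic hazard
#' anchored at age 80 (a pure reparameterisation of the usual form), rising
#' towards an asymptote of 1 per year, the standard model for smoothing
#' old-age mortality.
#'
#' @param x Ages in years.
#' @param a Level parameter (> 0); `a / (1 + a)` is the hazard at age 80.
#' @param b Slope parameter (> 0) per year of age.
#' @return Hazard values in (0, 1).
#' @export
kannisto_hazard <- function(x, a, b) {
  stats::plogis(log(a) + b * (x - 80))
}

#' Fit the Kannisto model to events and exposure by age
#'
#' Maximum Poisson likelihood with mean `exposure(x) * mu(x)`, fitted on
#' the log-parameter scale by box-constrained quasi-Newton optimisation
#' with analytic gradients.  The deterministic starting point is `a` at the
#' observed rate at the first age (clipped to (1e-6, 0.9)) and `b = 0.1`;
#' on failure a small grid of restarts is tried.  Convergence is declared
#' when the gradient norm falls below `1e-8 * max(1, total events)` or a
#' parameter reaches its box bound (the flat-data limit `b -> 0` is
#' reported in `note`).  Poisson likelihood rather than least squares keeps
#' zero-event cells informative.
#'
#' @param events Event counts by age.
#' @param exposure Person-years by age; cells with zero exposure (and zero
#'   events) are ignored.
#' @param ages Integer ages, default 80--100; at least three ages must have
#'   positive exposure.
#' @return A list of class `kannisto_fit`: `a`, `b`, `loglik`, `ages`,
#'   `fitted` (hazard at `ages`), `converged`, `note`.
#' @export
fit_kannisto <- function(events, exposure, ages = 80:100) {
  if (length(events) != length(ages) || length(exposure) != length(ages)) {
    stop("events, exposure and ages must have equal length")
  }
  if (any(events > 0 & exposure <= 0)) {
    stop("events observed in cells with zero exposure")
  }
  pos <- exposure > 0
  if (sum(pos) < 3L) {
    stop("cannot fit: need at least 3 ages with positive exposure")
  }
  if (all(events[pos] == 0)) {
    stop("cannot smooth an all-zero hazard with the Kannisto model")
  }
  D <- events[pos]
  E <- exposure[pos]
  x <- ages[pos] - 80

  nll <- function(p) {
    eta <- p[1L] + exp(p[2L]) * x
    mu <- stats::plogis(eta)
    -sum(D * log(mu) - E * mu)
  }
  grad <- function(p) {
    b <- exp(p[2L])
    mu <- stats::plogis(p[1L] + b * x)
    resid <- (D - E * mu) * (1 - mu)
    -c(sum(resid), sum(resid * b * x))
  }

  lower <- c(log(1e-8), log(1e-4))
  upper <- c(log(1e4), log(5))
  r0 <- min(max(D[1L] / E[1L], 1e-6), 0.9)
  starts <- rbind(c(log(r0), log(0.1)),
                  c(log(r0), log(0.05)),
                  c(log(r0), log(0.2)),
                  c(log(r0 / 4), log(0.1)),
                  c(log(min(4 * r0, 0.9)), log(0.13)))
  tol <- 1e-8 * max(1, sum(D))

  best <- NULL
  note <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(stats::optim(starts[s, ], nll, grad, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500, factr = 10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    g <- grad(fit$par)
    at_bound <- any(abs(fit$par - lower) < 1e-10 | abs(fit$par - upper) < 1e-10)
    ok <- max(abs(g)) < tol || at_bound
    if (ok && (is.null(best) || fit$value < best$value)) {
      best <- fit
      note <- if (at_bound && abs(fit$par[2L] - lower[2L]) < 1e-10) {
        "slope at lower bound: flat-data (b -> 0) limit"
      } else if (at_bound) "parameter at box bound" else NULL
    }
    if (!is.null(best) && max(abs(grad(best$par))) < tol) break
  }
  if (is.null(best)) {
    stop("Kannisto fit did not converge after ", nrow(starts),
         " starts (ages ", min(ages), "-", max(ages), ", ",
         sum(D), " events); last gradient norm ",
         format(max(abs(grad(fit$par))), digits = 3))
  }

  a <- exp(best$par[1L])
  b <- exp(best$par[2L])
  structure(list(a = a, b = b, loglik = -best$value,
                 ages = ages, fitted = kannisto_hazard(ages, a, b),
                 converged = TRUE, note = note),
            class = "kannisto_fit")
}

#' @export
print.kannisto_fit <- function(x, ...) {
  cat(sprintf("Kannisto fit: a = %.5f, b = %.4f (ages %d-%d), logLik = %.2f\n",
              x$a, x$b, min(x$ages), max(x$ages), x$loglik))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Transition-rate grid for the illness-death model
#'
#' A complete grid of the three hazards on integer ages 65--100, the input
#' of [build_lifetable()] and [state_expectancies()].
#'
#' @param di,dm,nondm Hazards per person-year at `age`.
#' @param age Integer age grid.
#' @param sex,period Optional stratum labels (attributes).
#' @param src Optional data frame of provenance flags per transition.
#' @return Data frame of class `transition_rates`.
#' @export
transition_rates <- function(di, dm, nondm, age = 65:100,
                             sex = NA_character_, period = NA_character_,
                             src = NULL) {
  if (!all(lengths(list(di, dm, nondm)) == length(age))) {
    stop("di, dm, nondm must match the age grid length")
  }
  vals <- cbind(di, dm, nondm)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("transition rates must be finite and non-negative")
  }
  out <- data.frame(age = as.integer(age), di = di, dm = dm, nondm = nondm)
  if (!is.null(src)) {
    out$di_src <- src$di
    out$dm_src <- src$dm
    out$nondm_src <- src$nondm
  }
  attr(out, "sex") <- sex
  attr(out, "period") <- period
  class(out) <- c("transition_rates", "data.frame")
  out
}

single_stratum <- function(tb, name) {
  if (length(unique(tb$sex)) != 1L || length(unique(tb$period)) != 1L) {
    stop("event table '", name, "' must contain a single sex and period; ",
         "subset the stratum first")
  }
  tb[order(tb$age), , drop = FALSE]
}

#' Smooth old-age transition rates with the Kannisto model
#'
#' Builds the complete transition-rate grid of one stratum: observed rates
#' are kept below age 80 and replaced at ages 80--100 by a Kannisto
#' logistic fit to that stratum's events and exposure, separately for each
#' of the three transitions.  Zero-exposure cells below 80 are treated as
#' zero-rate with a warning; above 80 they are filled by the fitted curve.
#' The incidence hazard may alternatively be smoothed log-linearly
#' (Gompertz, a Poisson GLM), since a logistic asymptote is a mortality
#' assumption that incidence need not share.
#'
#' @param event_tables Named list `di`, `dm`, `nondm` of event tables, each
#'   restricted to one sex and one period.
#' @param raw Optional `transition_rates` whose sub-80 values override the
#'   observed rates (e.g. externally smoothed input).
#' @param di_model `"kannisto"` (default) or `"gompertz"` for the incidence
#'   transition.
#' @param smooth_from First age of the smoothing range.
#' @return A [transition_rates()] grid with provenance columns `*_src`
#'   (`"observed"` or `"smoothed"`).
#' @export
smooth_rates <- function(event_tables, raw = NULL,
                         di_model = c("kannisto", "gompertz"),
                         smooth_from = 80L) {
  di_model <- match.arg(di_model)
  stopifnot(all(c("di", "dm", "nondm") %in% names(event_tables)))
  ages <- 65:100
  hi <- ages >= smooth_from
  rates <- list()
  src <- list()
  stratum <- NULL
  for (nm in c("di", "dm", "nondm")) {
    tb <- single_stratum(check_event_table(event_tables[[nm]]), nm)
    if (!identical(as.integer(tb$age), ages)) {
      stop("event table '", nm, "' must cover ages 65-100")
    }
    stratum <- c(sex = tb$sex[1L], period = tb$period[1L])
    obs <- ifelse(tb$person_years > 0, tb$events / tb$person_years, NA_real_)
    if (!is.null(raw)) obs[!hi] <- raw[[nm]][match(ages[!hi], raw$age)]
    if (anyNA(obs[!hi])) {
      warning("zero exposure below age ", smooth_from, " for '", nm,
              "' at age(s) ", paste(ages[!hi][is.na(obs[!hi])], collapse = ", "),
              "; treated as rate 0")
      obs[!hi][is.na(obs[!hi])] <- 0
    }
    sm <- tryCatch({
      if (nm == "di" && di_model == "gompertz") {
        dat <- data.frame(events = tb$events[hi],
                          x = tb$age[hi] - smooth_from,
                          log_py = log(tb$person_years[hi]))
        dat <- dat[is.finite(dat$log_py), , drop = FALSE]
        gf <- stats::glm(events ~ x + offset(log_py),
                         family = stats::poisson(), data = dat)
        exp(stats::coef(gf)[1L] + stats::coef(gf)[2L] * (ages[hi] - smooth_from))
      } else {
        fit_kannisto(tb$events[hi], tb$person_years[hi], ages[hi])$fitted
      }
    }, error = function(e) {
      stop("smoothing failed for transition '", nm, "' (sex ", tb$sex[1L],
           ", period ", tb$period[1L], "): ", conditionMessage(e),
           call. = FALSE)
    })
    rates[[nm]] <- c(obs[!hi], sm)
    src[[nm]] <- c(rep("observed", sum(!hi)), rep("smoothed", sum(hi)))
  }
  transition_rates(rates$di, rates$dm, rates$nondm, age = ages,
                   sex = stratum[["sex"]], period = stratum[["period"]],
                   src = src)
}
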