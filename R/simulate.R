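#' Solver configuration
#'
#' @param rel_tol,abs_tol integrator tolerances (lsoda family).
#' @param max_step_days maximal internal step, days.
#' @param horizon_days simulation horizon, days. Milestones not reached by
#'   the horizon are reported as `NA` ("indefinite").
#' @param event_refine_tol_days requested accuracy of reported threshold
#'   crossing times.
#' @param sample_days spacing of the dense output series (at most 1 day).
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                           max_step_days = 1, horizon_days = 10000,
                           event_refine_tol_days = 1e-3, sample_days = 1) {
  stopifnot(rel_tol > 0, abs_tol > 0, max_step_days > 0, horizon_days > 0,
            event_refine_tol_days > 0, sample_days > 0, sample_days <= 1)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step_days = max_step_days, horizon_days = horizon_days,
                 event_refine_tol_days = event_refine_tol_days,
                 sample_days = sample_days),
            class = "solver_control")
}

# integrate one constant-drug piece; stops early at the root of `rootfun`
# (t, y, parms) -> scalar, if supplied. Returns the sampled series, the final
# state, and whether the root terminated the piece.
.integrate_piece <- function(y, t0, t1, drug_on, params, control, rootfun = NULL) {
  times <- seq(t0, t1, by = control$sample_days)
  if (times[length(times)] < t1) times <- c(times, t1)
  parms <- list(params = params, drug_on = drug_on)
  if (is.null(rootfun)) {
    out <- deSolve::ode(y, times, .lv_deriv, parms, method = "lsoda",
                        rtol = control$rel_tol, atol = control$abs_tol,
                        hmax = control$max_step_days)
    root_hit <- FALSE
  } else {
    out <- deSolve::ode(y, times, .lv_deriv, parms, method = "lsodar",
                        rootfunc = rootfun,
                        rtol = control$rel_tol, atol = control$abs_tol,
                        hmax = control$max_step_days)
    troot <- attr(out, "troot")
    root_hit <- length(troot) > 0 && !is.na(troot[1])
  }
  out <- unclass(out)
  ser <- cbind(out[, 1:5, drop = FALSE], drug_on = as.numeric(drug_on))
  yend <- out[nrow(out), 2:5]
  names(yend) <- c("x1", "x2", "x3", "psa")
  # cell abundances are non-negative up to integrator noise; clamp exposure
  yend[1:3] <- pmax(yend[1:3], 0)
  ser[, 2:4] <- pmax(ser[, 2:4], 0)
  list(series = ser, t_end = out[nrow(out), 1], y_end = yend,
       root_hit = root_hit)
}

#' Simulate one patient under one treatment policy
#'
#' Integrates the coupled cell-population/PSA dynamics from the 25%
#' initialization ([initialize_patient()]) to the horizon, switching the drug
#' according to the regimen. The trajectory is integrated piecewise between
#' drug switches with the state handed across; capacities change
#' discontinuously at switches (the drug acts instantaneously in this model,
#' with no pharmacokinetics). Policy switch times and the therapy trigger are
#' located by the integrator's root finder; milestone crossings are refined
#' from the dense output afterwards.
#'
#' @param params a [patient_params()].
#' @param spec a [regimen()].
#' @param control a [solver_control()].
#' @param inoculum T- inoculum for best-responder patients, see
#'   [initialize_patient()].
#' @return An object of class `lv_sim` with the dense series (`t, x1, x2,
#'   x3, psa, drug_on`), trigger time, baseline PSA, drug-on intervals, dose
#'   ledger, milestones (`tminus_5pct`, `tminus_90pct`, `progression`) and
#'   termination status (`"HORIZON"` or `"PROGRESSION"`).
#' @examples
#' \donttest{
#' sim <- simulate_patient(table3_patient(2), regimen("mtd"),
#'                         solver_control(horizon_days = 1500))
#' summary(sim)
#' }
#' @export
simulate_patient <- function(params, spec = regimen("adaptive"),
                             control = solver_control(), inoculum = 1) {
  stopifnot(inherits(params, "patient_params"), inherits(spec, "regimen"),
            inherits(control, "solver_control"))
  ess <- untreated_ess(params)
  y <- initialize_patient(params, inoculum, ess = ess)
  horizon <- control$horizon_days
  trigger_level <- spec$trigger_fraction * ess$psa_star

  pieces <- list()
  push <- function(p) pieces[[length(pieces) + 1]] <<- p

  # --- shared pre-therapy phase: drug off until PSA reaches the trigger ---
  if (y[["psa"]] >= trigger_level) {
    t_trig <- 0
  } else {
    pre <- .integrate_piece(y, 0, horizon, FALSE, params, control,
                            rootfun = function(t, y, p) y[4] - trigger_level)
    push(pre)
    y <- pre$y_end
    t_trig <- if (pre$root_hit) pre$t_end else NA_real_
  }
  baseline_psa <- trigger_level

  # --- policy phase ---
  if (!is.na(t_trig) && t_trig < horizon) {
    t <- t_trig
    if (spec$kind == "untreated") {
      push(.integrate_piece(y, t, horizon, FALSE, params, control))
    } else if (spec$kind == "mtd") {
      push(.integrate_piece(y, t, horizon, TRUE, params, control))
    } else if (spec$kind == "metronomic") {
      # induction block, then off/on cycling
      tb <- min(t + spec$induction_days, horizon)
      if (tb > t) {
        p <- .integrate_piece(y, t, tb, TRUE, params, control)
        push(p); y <- p$y_end; t <- tb
      }
      on_block <- FALSE  # first post-induction block is off
      while (t < horizon - 1e-9) {
        len <- if (on_block) spec$metronomic_on_days else spec$metronomic_off_days
        tb <- min(t + len, horizon)
        p <- .integrate_piece(y, t, tb, on_block, params, control)
        push(p); y <- p$y_end; t <- tb
        on_block <- !on_block
      }
    } else {  # adaptive
      if (spec$monitoring == "continuous") {
        on <- TRUE
        repeat {
          if (t >= horizon - 1e-9) break
          thr <- if (on) spec$adaptive_lower * baseline_psa
                 else spec$adaptive_upper * baseline_psa
          p <- .integrate_piece(y, t, horizon, on, params, control,
                                rootfun = function(t, y, parms) y[4] - thr)
          push(p); y <- p$y_end; t <- p$t_end
          if (!p$root_hit) break
          on <- !on
          if (length(pieces) > 5e4) {
            warning("adaptive policy: piece limit reached before horizon")
            break
          }
        }
      } else {
        on <- TRUE
        while (t < horizon - 1e-9) {
          tb <- min(t + spec$monitoring_interval_days, horizon)
          p <- .integrate_piece(y, t, tb, on, params, control)
          push(p); y <- p$y_end; t <- tb
          on <- drug_status(spec, t, y[["psa"]], baseline_psa, t_trig, on)
        }
      }
    }
  }

  # --- assemble dense series, drop duplicated piece-boundary rows ---
  mats <- lapply(seq_along(pieces), function(k) {
    m <- pieces[[k]]$series
    if (k > 1) m <- m[-1, , drop = FALSE]
    m
  })
  series <- as.data.frame(do.call(rbind, mats))
  names(series) <- c("t", "x1", "x2", "x3", "psa", "drug_on")
  rownames(series) <- NULL

  on_intervals <- .on_intervals(pieces)
  res <- structure(list(series = series, params = params, regimen = spec,
                        control = control, inoculum = inoculum, ess = ess,
                        trigger_time = t_trig, baseline_psa = baseline_psa,
                        on_intervals = on_intervals),
                   class = "lv_sim")
  ms <- milestone_times(res, c(0.05, 0.90))
  prog <- progression_time(res)
  res$milestones <- list(tminus_5pct = unname(ms[1]),
                         tminus_90pct = unname(ms[2]),
                         progression = prog)
  res$terminated <- if (!is.na(prog)) "PROGRESSION" else "HORIZON"
  wend <- if (!is.na(prog)) min(prog, horizon) else horizon
  wstart <- if (is.na(t_trig)) 0 else t_trig
  res$ledger <- dose_ledger(on_intervals, c(wstart, max(wend, wstart + 1e-9)))
  res
}

# merge consecutive on pieces into (start, end) intervals
.on_intervals <- function(pieces) {
  iv <- NULL
  for (p in pieces) {
    on <- p$series[1, 6] == 1
    t0 <- p$series[1, 1]; t1 <- p$t_end
    if (!on || t1 <= t0) next
    if (!is.null(iv) && abs(iv[nrow(iv), 2] - t0) < 1e-9)
      iv[nrow(iv), 2] <- t1
    else iv <- rbind(iv, c(t0, t1))
  }
  iv
}

# refine the upward crossing of series column `val` through `thr` inside the
# bracketing sample interval [i-1, i], by root finding on a local spline
.refine_cross <- function(tt, val, i, thr, tol) {
  if (i == 1) return(tt[1])
  lo <- max(1, i - 3); hi <- min(length(tt), i + 3)
  f <- stats::splinefun(tt[lo:hi], val[lo:hi] - thr, method = "natural")
  if (f(tt[i - 1]) > 0) return(tt[i - 1])
  stats::uniroot(f, c(tt[i - 1], tt[i]), tol = min(tol, 1e-4))$root
}

#' Times at which the resistant clone first reaches given frequencies
#'
#' For each threshold `f`, the first time with `x3 / (x1 + x2 + x3) >= f`,
#' refined between dense-output samples; `NA` if never reached within the
#' simulated span. A threshold already exceeded at the initial state reports
#' time 0.
#'
#' @param sim an `lv_sim` from [simulate_patient()].
#' @param thresholds numeric vector of frequency fractions.
#' @return Named numeric vector of days (`NA` = not reached).
#' @export
milestone_times <- function(sim, thresholds = c(0.05, 0.90)) {
  ser <- sim$series
  tot <- ser$x1 + ser$x2 + ser$x3
  freq <- ifelse(tot > 0, ser$x3 / tot, 0)
  tol <- sim$control$event_refine_tol_days
  out <- vapply(thresholds, function(thr) {
    i <- which(freq >= thr)[1]
    if (is.na(i)) return(NA_real_)
    .refine_cross(ser$t, freq, i, thr, tol)
  }, numeric(1))
  names(out) <- paste0("tminus_", formatC(100 * thresholds, format = "fg"), "pct")
  out
}

#' Radiographic progression time
#'
#' Progression is declared at the first time the resistant clone holds at
#' least 90% of the tumor while PSA stays at or above `psa_fraction` of the
#' pre-abiraterone baseline continuously for `window_days`. It is defined
#' relative to therapy: an untreated run, or a run whose therapy never
#' triggered, reports `NA`.
#'
#' @param sim an `lv_sim`.
#' @param psa_fraction PSA threshold as a fraction of baseline.
#' @param window_days length of the sustained window.
#' @return Day of progression, or `NA`.
#' @export
progression_time <- function(sim, psa_fraction = 0.5, window_days = 84) {
  if (sim$regimen$kind == "untreated" || is.na(sim$trigger_time))
    return(NA_real_)
  ser <- sim$series
  keep <- ser$t >= sim$trigger_time
  tt <- ser$t[keep]
  if (length(tt) < 2) return(NA_real_)
  tot <- (ser$x1 + ser$x2 + ser$x3)[keep]
  freq <- ifelse(tot > 0, ser$x3[keep] / tot, 0)
  psa <- ser$psa[keep]
  thr <- psa_fraction * sim$baseline_psa
  cond <- freq >= 0.90 & psa >= thr
  n <- length(tt)
  for (i in which(cond)) {
    jend <- which(tt >= tt[i] + window_days)[1]
    if (is.na(jend)) return(NA_real_)       # window exceeds simulated span
    if (all(cond[i:jend])) {
      tol <- sim$control$event_refine_tol_days
      t1 <- .refine_cross(tt, freq, i, 0.90, tol)
      t2 <- .refine_cross(tt, psa, i, thr, tol)
      return(max(t1, min(t2, tt[i])))
    }
  }
  NA_real_
}

#' Compare treatment policies for one patient
#'
#' Runs [simulate_patient()] once per regimen and tabulates the therapy
#' trigger, the 5% and 90% resistant-clone milestones, progression, and the
#' cumulative dose percentage over the window from the trigger to
#' progression or horizon. `NA` milestones mean "not reached by the horizon"
#' (indefinite control).
#'
#' @param params a [patient_params()].
#' @param specs list of [regimen()] objects (default: all four policies).
#' @param control a [solver_control()].
#' @param inoculum see [simulate_patient()].
#' @return Data frame, one row per regimen, with an attribute `sims` holding
#'   the full `lv_sim` objects.
#' @export
compare_regimens <- function(params,
                             specs = lapply(c("untreated", "mtd",
                                              "metronomic", "adaptive"),
                                            regimen),
                             control = solver_control(), inoculum = 1) {
  sims <- lapply(specs, function(sp)
    simulate_patient(params, sp, control, inoculum))
  out <- data.frame(
    regimen = vapply(specs, function(s) s$kind, character(1)),
    trigger_time = vapply(sims, function(s) s$trigger_time, numeric(1)),
    tminus_5pct = vapply(sims, function(s) s$milestones$tminus_5pct, numeric(1)),
    tminus_90pct = vapply(sims, function(s) s$milestones$tminus_90pct, numeric(1)),
    progression = vapply(sims, function(s) s$milestones$progression, numeric(1)),
    dose_pct = vapply(sims, function(s) dose_fraction(s$ledger), numeric(1)),
    terminated = vapply(sims, function(s) s$terminated, character(1)))
  attr(out, "sims") <- sims
  out
}

#' @export
print.lv_sim <- function(x, ...) {
  cat("Lotka-Volterra therapy simulation (", toupper(x$regimen$kind), ")\n",
      sep = "")
  cat("  span: 0 -", max(x$series$t), "days;",
      nrow(x$series), "samples\n")
  cat("  therapy trigger:",
      if (is.na(x$trigger_time)) "not reached" else
        paste(round(x$trigger_time, 1), "days"), "\n")
  invisible(x)
}

#' @export
summary.lv_sim <- function(object, ...) {
  m <- object$milestones
  fin <- utils::tail(object$series, 1)
  cat("Simulation summary (", toupper(object$regimen$kind), ")\n", sep = "")
  cat("  therapy trigger      :", .fmt_day(object$trigger_time), "\n")
  cat("  T- reaches 5%        :", .fmt_day(m$tminus_5pct), "\n")
  cat("  T- reaches 90%       :", .fmt_day(m$tminus_90pct), "\n")
  cat("  progression          :", .fmt_day(m$progression), "\n")
  cat("  cumulative dose      :", sprintf("%.1f%%", dose_fraction(object$ledger)), "\n")
  cat("  terminated           :", object$terminated, "\n")
  cat("  final state          : x = (",
      paste(sprintf("%.1f", fin[c("x1", "x2", "x3")]), collapse = ", "),
      "), PSA =", sprintf("%.1f", fin$psa), "\n")
  invisible(object)
}

.fmt_day <- function(d) if (is.na(d)) "indefinite" else sprintf("%.1f d", d)

#' Plot a therapy simulation
#'
#' Two stacked base-graphics panels: phenotype abundances and PSA over time,
#' with drug-on intervals shaded.
#'
#' @param x an `lv_sim`.
#' @param ... ignored.
#' @export
plot.lv_sim <- function(x, ...) {
  ser <- x$series
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  shade <- function(ylim) {
    iv <- x$on_intervals
    if (!is.null(iv))
      graphics::rect(iv[, 1], ylim[1], iv[, 2], ylim[2],
                     col = grDevices::grey(0.9), border = NA)
  }
  ylim <- c(0, max(ser$x1, ser$x2, ser$x3))
  plot(NA, xlim = range(ser$t), ylim = ylim, xlab = "", ylab = "cells",
       main = paste("populations,", x$regimen$kind))
  shade(ylim)
  graphics::lines(ser$t, ser$x1, col = "#7570b3")
  graphics::lines(ser$t, ser$x2, col = "#1b9e77")
  graphics::lines(ser$t, ser$x3, col = "#d95f02")
  graphics::legend("topright", legend = PHENOTYPES, bty = "n", lty = 1,
                   col = c("#7570b3", "#1b9e77", "#d95f02"))
  ylim <- c(0, max(ser$psa))
  plot(NA, xlim = range(ser$t), ylim = ylim, xlab = "days", ylab = "PSA")
  shade(ylim)
  graphics::lines(ser$t, ser$psa)
  graphics::abline(h = x$baseline_psa * c(0.5, 1), lty = 3)
  invisible(x)
}
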