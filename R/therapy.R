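#' Treatment regimen specification
#'
#' Encodes one of the four simulated policies. All regimens share the same
#' pre-therapy phase: the tumor grows untreated until serum PSA reaches
#' `trigger_fraction` of its untreated equilibrium value, the clinical
#' trigger for starting abiraterone.
#'
#' * `untreated` -- no drug, ever.
#' * `mtd` -- maximum tolerated dose: drug on continuously from the trigger.
#' * `metronomic` -- an induction block of `induction_days` of continuous
#'   drug from the trigger, then a fixed, state-blind cycle of
#'   `metronomic_off_days` off / `metronomic_on_days` on. The default 28/84
#'   post-induction cycle (25% on-time) is this package's calibration; the
#'   interval lengths behind the published metronomic dose figure are not
#'   stated.
#' * `adaptive` -- hysteresis cycling on the patient's own PSA: stop drug
#'   when PSA falls to `adaptive_lower` of the pre-abiraterone baseline,
#'   restart when it returns to `adaptive_upper` of baseline.
#'
#' With `monitoring = "interval"` switching decisions are taken only at
#'4-weekly labs (`monitoring_interval_days`), mimicking the clinical
#' protocol; the default continuous monitoring locates crossings exactly.
#'
#' @param kind one of `"untreated"`, `"mtd"`, `"metronomic"`, `"adaptive"`.
#' @param trigger_fraction PSA fraction of the untreated equilibrium that
#'   initiates therapy.
#' @param adaptive_lower,adaptive_upper stop/restart PSA fractions of the
#'   pre-abiraterone baseline; must satisfy `adaptive_lower < adaptive_upper`.
#' @param induction_days metronomic induction length in days.
#' @param metronomic_on_days,metronomic_off_days post-induction cycle blocks.
#' @param monitoring `"continuous"` or `"interval"`.
#' @param monitoring_interval_days spacing of interval-mode decisions.
#' @return An object of class `regimen`.
#' @examples
#' regimen("adaptive")
#' @export
regimen <- function(kind = c("untreated", "mtd", "metronomic", "adaptive"),
                    trigger_fraction = 0.8,
                    adaptive_lower = 0.5, adaptive_upper = 1.0,
                    induction_days = 240,
                    metronomic_on_days = 28, metronomic_off_days = 84,
                    monitoring = c("continuous", "interval"),
                    monitoring_interval_days = 28) {
  kind <- match.arg(kind)
  monitoring <- match.arg(monitoring)
  stopifnot(trigger_fraction > 0, trigger_fraction <= 1,
            adaptive_lower > 0, adaptive_lower < adaptive_upper,
            induction_days >= 0, metronomic_on_days > 0,
            metronomic_off_days > 0, monitoring_interval_days > 0)
  structure(list(kind = kind, trigger_fraction = trigger_fraction,
                 adaptive_lower = adaptive_lower,
                 adaptive_upper = adaptive_upper,
                 induction_days = induction_days,
                 metronomic_on_days = metronomic_on_days,
                 metronomic_off_days = metronomic_off_days,
                 monitoring = monitoring,
                 monitoring_interval_days = monitoring_interval_days),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat("Regimen:", toupper(x$kind), "\n")
  cat("  therapy trigger: PSA at", x$trigger_fraction, "of untreated equilibrium\n")
  if (x$kind == "adaptive")
    cat("  hysteresis band: off at", x$adaptive_lower, "x baseline, on at",
        x$adaptive_upper, "x baseline (", x$monitoring, "monitoring )\n")
  if (x$kind == "metronomic")
    cat("  induction", x$induction_days, "d, then cycle",
        x$metronomic_off_days, "d off /", x$metronomic_on_days, "d on\n")
  invisible(x)
}

#' Drug status demanded by a regimen at one instant
#'
#' The pure decision rule shared by the simulation engine and interval-mode
#' monitoring. Before `trigger_time` every regimen is off (the pre-therapy
#' phase is common to all policies).
#'
#' @param spec a [regimen()].
#' @param t time in days.
#' @param psa current PSA value.
#' @param baseline_psa pre-abiraterone baseline (PSA at the trigger).
#' @param trigger_time day therapy was triggered.
#' @param currently_on current drug state (hysteresis memory).
#' @return Logical: is the drug on at `t`?
#' @examples
#' sp <- regimen("adaptive")
#' drug_status(sp, 100, psa = 49, baseline_psa = 100, trigger_time = 50,
#'             currently_on = TRUE)   # FALSE: PSA fell through 50% of baseline
#' @export
drug_status <- function(spec, t, psa, baseline_psa, trigger_time, currently_on) {
  stopifnot(t >= 0, baseline_psa > 0)
  if (spec$kind == "untreated" || is.na(trigger_time) || t < trigger_time)
    return(FALSE)
  switch(spec$kind,
    mtd = TRUE,
    metronomic = {
      u <- t - trigger_time
      if (u < spec$induction_days) TRUE
      else {
        v <- (u - spec$induction_days) %%
          (spec$metronomic_on_days + spec$metronomic_off_days)
        v >= spec$metronomic_off_days
      }
    },
    adaptive = {
      if (psa <= spec$adaptive_lower * baseline_psa) FALSE
      else if (psa >= spec$adaptive_upper * baseline_psa) TRUE
      else isTRUE(currently_on)
    })
}

#' Dose ledger: drug-on intervals within an accounting window
#'
#' @param on_intervals two-column numeric matrix of (start, end) day pairs,
#'   disjoint and sorted, or NULL for none.
#' @param window length-2 numeric (start, end) of the accounting window.
#' @return An object of class `dose_ledger`.
#' @export
dose_ledger <- function(on_intervals, window) {
  if (is.null(on_intervals) || length(on_intervals) == 0)
    on_intervals <- matrix(numeric(0), ncol = 2)
  on_intervals <- matrix(as.numeric(on_intervals), ncol = 2)
  stopifnot(length(window) == 2, window[2] >= window[1])
  if (nrow(on_intervals)) {
    # clip to window, drop empties
    on_intervals[, 1] <- pmax(on_intervals[, 1], window[1])
    on_intervals[, 2] <- pmin(on_intervals[, 2], window[2])
    on_intervals <- on_intervals[on_intervals[, 2] > on_intervals[, 1], , drop = FALSE]
    if (nrow(on_intervals) > 1) {
      on_intervals <- on_intervals[order(on_intervals[, 1]), , drop = FALSE]
      if (any(on_intervals[-1, 1] < on_intervals[-nrow(on_intervals), 2] - 1e-9))
        stop("drug-on intervals must be disjoint")
    }
  }
  structure(list(on_intervals = on_intervals, window = as.numeric(window)),
            class = "dose_ledger")
}

#' Cumulative dose as a percentage of continuous dosing
#'
#' Drug-on days divided by the window length, times 100: continuous MTD over
#' its own window is exactly 100%, an untreated run 0%.
#'
#' @param ledger a [dose_ledger()].
#' @return Percentage in 0..100.
#' @export
dose_fraction <- function(ledger) {
  stopifnot(inherits(ledger, "dose_ledger"))
  len <- diff(ledger$window)
  if (len <= 0) stop("zero-length dose accounting window")
  on <- if (nrow(ledger$on_intervals))
    sum(ledger$on_intervals[, 2] - ledger$on_intervals[, 1]) else 0
  100 * on / len
}

#' Serialize a dose ledger to an interval table
#'
#' @param ledger a [dose_ledger()].
#' @return Data frame with columns `start_day`, `end_day`, `status`
#'   covering the window with alternating on/off rows.
#' @export
ledger_intervals <- function(ledger) {
  iv <- ledger$on_intervals
  w <- ledger$window
  bounds <- sort(unique(c(w, iv)))
  out <- data.frame(start_day = bounds[-length(bounds)],
                    end_day = bounds[-1])
  out$status <- vapply(seq_len(nrow(out)), function(k) {
    mid <- (out$start_day[k] + out$end_day[k]) / 2
    if (nrow(iv) && any(mid >= iv[, 1] & mid < iv[, 2])) "on" else "off"
  }, character(1))
  out
}
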