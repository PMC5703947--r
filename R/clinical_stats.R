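#' One-sided Fisher exact test (lower tail) on a 2x2 table
#'
#' With rows = cohorts and columns = outcome / no outcome, the count in the
#' upper-left cell under fixed margins is hypergeometric; the one-sided
#' p-value is the lower tail `P(X <= a)` (or the upper tail `P(X >= a)` with
#' `upper = TRUE`). Degenerate margins (an all-zero row or column) carry no
#' information and report p = 1 with a `degenerate` attribute.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`a b / c d`); alternatively `a` may be a 2x2 matrix.
#' @param upper if `TRUE`, return `P(X >= a)` instead.
#' @return p-value with attribute `degenerate`.
#' @examples
#' fisher_exact_leq(1, 10, 273, 273)  # 0.006: trial vs historic PSA progression
#' @export
fisher_exact_leq <- function(a, b = NULL, c = NULL, d = NULL, upper = FALSE) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cnt <- c(a, b, c, d)
  stopifnot(all(cnt >= 0), all(cnt == round(cnt)), sum(cnt) > 0)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    return(structure(1, degenerate = TRUE))
  p <- if (upper)
    stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
  else
    stats::phyper(a, m = a + c, n = b + d, k = a + b)
  structure(p, degenerate = FALSE)
}

#' The adaptive-therapy pilot cohort
#'
#' Per-patient records of the 11 pilot-trial patients: subject id, Gleason
#' score, metastatic site, pre-abiraterone PSA (ng/ml) and cumulative
#' abiraterone dose as a percentage of standard-of-care dosing.
#'
#' @return Data frame with 11 rows.
#' @export
trial_cohort <- function() {
  path <- system.file("extdata", "trial_cohort.csv", package = "adaptlv",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cohort cumulative-dose summary
#'
#' @param cohort data frame with a `dose_pct` column (default: the pilot
#'   cohort, [trial_cohort()]).
#' @return List with `mean_pct` (unrounded) and `mean_pct_rounded`
#'   (integer percent, as reported).
#' @examples
#' cohort_dose_summary()$mean_pct_rounded  # 47
#' @export
cohort_dose_summary <- function(cohort = trial_cohort()) {
  if (NROW(cohort) == 0) stop("empty cohort")
  m <- mean(cohort$dose_pct)
  list(mean_pct = m, mean_pct_rounded = round(m))
}

#' Normal-approximation comparison of a mean time to a reference mean
#'
#' Computes `z = (observed_mean - reference_mean) / sqrt(reference_mean / n)`
#' -- the standardized excess of the observed cohort mean over a reference
#' mean whose variance is taken as Poisson-like (variance = mean) -- with a
#' one-sided upper-tail p-value. This is this package's fixed, documented
#' construction for the "is the cohort mean larger than the reference"
#' question; it is an approximation, not an exact small-sample test.
#'
#' @param observed_mean cohort mean (months).
#' @param n cohort size.
#' @param reference_mean reference mean (months).
#' @return List with `z` and one-sided `p` (`P(mean >= observed)` under the
#'   reference).
#' @examples
#' poisson_mean_comparison(24, 11, 17.2)
#' @export
poisson_mean_comparison <- function(observed_mean, n, reference_mean) {
  stopifnot(n >= 1, observed_mean > 0, reference_mean > 0)
  z <- (observed_mean - reference_mean) / sqrt(reference_mean / n)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}
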