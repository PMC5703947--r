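#' adaptlv: evolutionary Lotka-Volterra dynamics of adaptive abiraterone therapy
#'
#' Tools to simulate competition between three prostate-cancer phenotypes --
#' androgen-dependent "cheaters" (T+), testosterone-producing cells (TP), and
#' androgen-independent resistant cells (T-) -- before and during abiraterone
#' therapy, and to compare treatment scheduling policies by time to
#' competitive release of the resistant clone.
#'
#' @section Phenotype indexing:
#' Throughout the package the three phenotypes are indexed in the fixed order
#' T+ = 1, TP = 2, T- = 3.
#'
#' @keywords internal
#' @aliases adaptlv-package
"_PACKAGE"

#' Phenotype labels in canonical order (T+, TP, T-)
#' @export
PHENOTYPES <- c("T+", "TP", "T-")

# floor below which a carrying capacity is treated as vanished; the logistic
# bracket is then replaced by -1 so the ODE stays Lipschitz (maximal
# per-capita decline -r_i x_i)
K_FLOOR <- 1e-9

#' Patient parameterization for the three-phenotype competition model
#'
#' Bundles the per-day intrinsic growth rates, the 3x3 competition matrix and
#' the carrying-capacity rule constants for one (virtual) patient.
#'
#' The carrying capacities are not all constant: T+ cells survive androgen
#' deprivation only by "cheating" on testosterone produced by TP cells, so
#' their capacity is proportional to the current TP abundance
#' (`K1 = cheater_factor * x2`, with a smaller factor while abiraterone is
#' administered). Abiraterone also collapses the TP capacity from `k2_off` to
#' `k2_on`. The resistant T- capacity `k3` is drug-independent.
#'
#' @param competition 3x3 numeric matrix `a[i, j]`, the per-capita effect of
#'   phenotype `j` on the growth of phenotype `i`. Unit diagonal, off-diagonal
#'   entries strictly inside (0, 1).
#' @param growth_rates positive numeric vector of length 3, per day. The
#'   default is 10% of the doubling-time-derived rates of the LNCaP, H295R
#'   and PC-3 cell lines.
#' @param k2_off,k2_on TP carrying capacity (cells) without / under drug.
#' @param k3 T- carrying capacity (cells).
#' @param cheater_factor_off,cheater_factor_on T+ capacity per TP cell
#'   without / under drug.
#' @return An object of class `patient_params`.
#' @examples
#' p <- patient_params(table3_matrix(1))
#' p
#' @export
patient_params <- function(competition,
                           growth_rates = 0.1 * c(0.278, 0.355, 0.665),
                           k2_off = 10000, k2_on = 100, k3 = 10000,
                           cheater_factor_off = 1.5, cheater_factor_on = 0.5) {
  competition <- as.matrix(competition)
  stopifnot(is.numeric(competition), identical(dim(competition), c(3L, 3L)))
  if (any(abs(diag(competition) - 1) > 1e-12))
    stop("competition matrix must have unit diagonal (a_ii = 1)")
  off <- competition[row(competition) != col(competition)]
  if (any(off <= 0 | off >= 1))
    stop("off-diagonal competition coefficients must lie strictly in (0, 1)")
  stopifnot(length(growth_rates) == 3, all(growth_rates > 0),
            k2_off > 0, k2_on > 0, k3 > 0,
            cheater_factor_off > 0, cheater_factor_on > 0)
  if (k2_on >= k2_off)
    stop("k2_on must be smaller than k2_off (drug lowers the TP capacity)")
  dimnames(competition) <- list(PHENOTYPES, PHENOTYPES)
  structure(list(growth_rates = as.numeric(growth_rates),
                 competition = competition,
                 k2_off = k2_off, k2_on = k2_on, k3 = k3,
                 cheater_factor_off = cheater_factor_off,
                 cheater_factor_on = cheater_factor_on),
            class = "patient_params")
}

#' @export
print.patient_params <- function(x, ...) {
  cat("Three-phenotype Lotka-Volterra patient parameterization\n")
  cat("  growth rates (/day):", format(x$growth_rates, digits = 4), "\n")
  cat("  capacities: K2 off/on =", x$k2_off, "/", x$k2_on,
      "; K3 =", x$k3, "\n")
  cat("  cheater factor off/on =", x$cheater_factor_off, "/",
      x$cheater_factor_on, " (K1 = factor * x2)\n")
  cat("  competition matrix:\n")
  print(x$competition)
  cls <- attr(x, "ordering_index")
  if (!is.null(cls)) cat("  (ordering #", cls, " of the admissible set)\n", sep = "")
  invisible(x)
}

#' Tumor state vector
#'
#' A tumor state is a named numeric vector `c(x1, x2, x3, psa)` of the three
#' phenotype abundances (cells) and serum PSA (arbitrary units; one unit
#' produced per cell per day, 50% serum decay per day).
#'
#' @param x numeric vector of 3 non-negative abundances (T+, TP, T-).
#' @param psa non-negative PSA value.
#' @return Named numeric vector of length 4.
#' @export
tumor_state <- function(x, psa) {
  stopifnot(length(x) == 3, all(x >= 0), psa >= 0)
  c(x1 = x[[1]], x2 = x[[2]], x3 = x[[3]], psa = psa)
}

#' Carrying capacities at a given state and drug status
#'
#' `K1` tracks the TP population (`cheater_factor * x2`; zero when TP is
#' extinct), `K2` switches between its off- and on-drug values, and `K3` is
#' constant.
#'
#' @param state tumor state vector (see [tumor_state()]); only `x2` is used.
#' @param params a [patient_params()] object.
#' @param drug_on logical, is abiraterone administered at this instant?
#' @return Numeric vector `c(K1, K2, K3)`.
#' @examples
#' p <- patient_params(table3_matrix(1))
#' carrying_capacities(tumor_state(c(0, 1000, 0), 0), p, drug_on = FALSE)
#' @export
carrying_capacities <- function(state, params, drug_on) {
  cf <- if (drug_on) params$cheater_factor_on else params$cheater_factor_off
  k2 <- if (drug_on) params$k2_on else params$k2_off
  c(cf * state[["x2"]], k2, params$k3)
}

#' Right-hand side of the coupled cell-population and PSA dynamics
#'
#' Implements the Lotka-Volterra competition equations
#' `dx_i/dt = r_i x_i (1 - sum_j a_ij x_j / K_i)` together with the PSA proxy
#' `dPSA/dt = sum_i x_i - 0.5 PSA`. When a capacity falls below the internal
#' floor (T+ after TP extinction) the bracket is replaced by -1, giving the
#' maximal per-capita decline `-r_i x_i`.
#'
#' @inheritParams carrying_capacities
#' @return Numeric vector of length 4: `c(dx1, dx2, dx3, dpsa)`.
#' @examples
#' p <- patient_params(table3_matrix(2))
#' lv_rhs(tumor_state(c(0, 0, 10000), 0), p, drug_on = FALSE)  # T- at K3
#' @export
lv_rhs <- function(state, params, drug_on) {
  x <- pmax(unname(state[1:3]), 0)
  K <- carrying_capacities(state, params, drug_on)
  Ax <- as.numeric(params$competition %*% x)
  bracket <- ifelse(K < K_FLOOR, -1, 1 - Ax / pmax(K, K_FLOOR))
  dx <- params$growth_rates * x * bracket
  c(dx, sum(x) - 0.5 * state[["psa"]])
}

# deSolve-facing wrapper: y = c(x1,x2,x3,psa), parms = list(params, drug_on)
.lv_deriv <- function(t, y, parms) {
  st <- c(x1 = y[[1]], x2 = y[[2]], x3 = y[[3]], psa = y[[4]])
  list(lv_rhs(st, parms$params, parms$drug_on))
}
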