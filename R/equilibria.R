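#' Solve a candidate untreated equilibrium community
#'
#' For a chosen subset of phenotypes, solves the steady-state linear system
#' `sum_j a_ij x_j = K_i` (rows restricted to present types, absent types set
#' to zero), with the T+ capacity coupling `K1 = cheater_factor_off * x2`
#' substituted so the system stays linear. Drug is off: these are the
#' pre-abiraterone (ADT-era) communities.
#'
#' T+ cannot form a community without TP, because its capacity is
#' proportional to the TP abundance; such subsets are reported infeasible
#' immediately.
#'
#' @param params a [patient_params()] object.
#' @param present integer subset of `1:3` (T+ = 1, TP = 2, T- = 3).
#' @return An object of class `lv_community`: a list with elements `present`,
#'   `abundances` (length 3, zeros for absent types), `frequencies`,
#'   `psa_star` (`= 2 * total`), `feasible` (logical) and `singular`
#'   (logical diagnostic).
#' @examples
#' solve_community(table3_patient(1), c(1, 2))
#' @export
solve_community <- function(params, present) {
  present <- sort(unique(as.integer(present)))
  stopifnot(length(present) >= 1, all(present %in% 1:3))
  A <- params$competition
  x <- numeric(3)
  infeasible <- function(singular = FALSE) {
    structure(list(present = integer(0), abundances = numeric(3),
                   frequencies = numeric(3), psa_star = 0,
                   feasible = FALSE, singular = singular),
              class = "lv_community")
  }
  if (1L %in% present && !(2L %in% present)) return(infeasible())
  n <- length(present)
  M <- A[present, present, drop = FALSE]
  b <- c(0, params$k2_off, params$k3)[present]
  if (1L %in% present) {
    # row for T+: sum_j a_1j x_j = cf * x2  ->  move cf*x2 to the left
    M[which(present == 1L), which(present == 2L)] <-
      M[which(present == 1L), which(present == 2L)] - params$cheater_factor_off
  }
  sol <- tryCatch(solve(M, b), error = function(e) NULL)
  if (is.null(sol)) return(infeasible(singular = TRUE))
  if (any(sol <= 0)) return(infeasible())
  x[present] <- sol
  structure(list(present = present, abundances = x,
                 frequencies = x / sum(x), psa_star = 2 * sum(x),
                 feasible = TRUE, singular = FALSE),
            class = "lv_community")
}

#' @export
print.lv_community <- function(x, ...) {
  if (!x$feasible) {
    cat("Infeasible community",
        if (x$singular) "(singular steady-state system)" else "", "\n")
    return(invisible(x))
  }
  cat("Equilibrium community {", paste(PHENOTYPES[x$present], collapse = ", "),
      "}\n", sep = "")
  df <- data.frame(abundance = round(x$abundances, 1),
                   frequency = round(x$frequencies, 4),
                   row.names = PHENOTYPES)
  print(df)
  cat("PSA* =", round(x$psa_star, 1), "\n")
  invisible(x)
}

#' Invasion fitness of a rare phenotype at a resident equilibrium
#'
#' Returns the logistic bracket `1 - sum_j a_ij x_j / K_i` evaluated at the
#' resident abundances: the sign of the per-capita growth rate of an
#' infinitesimally rare invader (the positive factor `r_i` is omitted). For a
#' T+ invader the capacity is `cheater_factor_off * x2` of the resident;
#' when that capacity vanishes (no TP present) the invader cannot grow and
#' the fitness is -1 by convention.
#'
#' @param params a [patient_params()] object.
#' @param resident an `lv_community` (see [solve_community()]).
#' @param invader phenotype index 1..3, not present in the resident.
#' @return Scalar invasion fitness.
#' @examples
#' p1 <- table3_patient(1)
#' invasion_fitness(p1, solve_community(p1, c(1, 2)), 3)  # -0.0455: T- excluded
#' @export
invasion_fitness <- function(params, resident, invader) {
  invader <- as.integer(invader)
  stopifnot(invader %in% 1:3, !(invader %in% resident$present))
  x <- resident$abundances
  K <- c(params$cheater_factor_off * x[2], params$k2_off, params$k3)[invader]
  if (K < K_FLOOR) return(-1)
  1 - sum(params$competition[invader, ] * x) / K
}

# numeric Jacobian of the cell-population subsystem restricted to the present
# types, evaluated at a community; the K1 = cf*x2 coupling is differentiated
# through because K1 is state, not a constant
.community_jacobian <- function(params, comm, h = 1e-4) {
  pr <- comm$present
  f <- function(xp) {
    x <- numeric(3); x[pr] <- xp
    st <- c(x1 = x[1], x2 = x[2], x3 = x[3], psa = 0)
    lv_rhs(st, params, drug_on = FALSE)[pr]
  }
  x0 <- comm$abundances[pr]
  J <- matrix(0, length(pr), length(pr))
  for (j in seq_along(pr)) {
    dx <- h * max(1, abs(x0[j]))
    e <- numeric(length(pr)); e[j] <- dx
    J[, j] <- (f(x0 + e) - f(x0 - e)) / (2 * dx)
  }
  J
}

#' Untreated evolutionarily stable community (ESS)
#'
#' Enumerates all candidate communities (non-empty subsets of the three
#' phenotypes), keeps the feasible ones, and selects the community that is
#' both internally stable (all eigenvalues of the community Jacobian have
#' non-positive real part, with the T+ capacity coupling differentiated
#' through) and uninvadable (invasion fitness of every absent type is not
#' positive, up to `tol`).
#'
#' If several communities qualify, the one reached by forward integration
#' from a 25% initialization with a one-cell inoculum in every type is
#' returned, with a warning.
#'
#' @param params a [patient_params()] object.
#' @param tol numeric tolerance on invasion fitness and eigenvalue sign.
#' @return An `lv_community` with attribute `tminus_fitness`: the invasion
#'   fitness of T- at the ESS when T- is absent (NA when present).
#' @examples
#' untreated_ess(table3_patient(2))
#' @export
untreated_ess <- function(params, tol = 1e-9) {
  subsets <- list(3L, 2L, c(2L, 3L), c(1L, 2L), c(1L, 2L, 3L))
  cands <- list()
  for (s in subsets) {
    comm <- solve_community(params, s)
    if (!comm$feasible) next
    fits <- vapply(setdiff(1:3, s), function(i) invasion_fitness(params, comm, i),
                   numeric(1))
    if (any(fits > tol)) next
    ev <- eigen(.community_jacobian(params, comm), only.values = TRUE)$values
    if (any(Re(ev) > 1e-6)) next
    cands[[length(cands) + 1]] <- comm
  }
  if (length(cands) == 0)
    stop("no uninvadable feasible community found; the parameterization ",
         "violates the model's assumptions")
  comm <- cands[[1]]
  if (length(cands) > 1) {
    warning("multiple uninvadable communities; selecting by forward integration")
    comm <- .select_by_integration(params, cands)
  }
  attr(comm, "tminus_fitness") <-
    if (3L %in% comm$present) NA_real_ else invasion_fitness(params, comm, 3L)
  comm
}

# disambiguate multiple ESS candidates: integrate long from a 25% start with
# a one-cell inoculum in every type and match on community membership
.select_by_integration <- function(params, cands) {
  tot <- max(vapply(cands, function(c) sum(c$abundances), numeric(1)))
  y0 <- c(x1 = 1, x2 = 1, x3 = 1, psa = 0) + c(0.25 * tot / 3 * c(1, 1, 1), 0)
  out <- deSolve::ode(y0, c(0, 2e4), .lv_deriv,
                      list(params = params, drug_on = FALSE),
                      method = "lsoda", rtol = 1e-8, atol = 1e-8)
  xf <- pmax(out[nrow(out), 2:4], 0)
  memb <- which(xf / sum(xf) >= 1e-4)
  hit <- which(vapply(cands, function(c) setequal(c$present, memb), logical(1)))
  if (length(hit) >= 1) cands[[hit[1]]] else cands[[1]]
}

#' Classify a virtual patient by the fate of the resistant clone
#'
#' Patients fall into three printed categories by the status of T- in the
#' untreated equilibrium community:
#' * `BEST_RESPONDER` -- T- is structurally excluded: its invasion fitness at
#'   the ESS is strictly negative, so no resistant clone is present before
#'   therapy;
#' * `NON_RESPONDER` -- the T- equilibrium frequency is at least 20%;
#' * `RESPONDER` -- everything in between, including the knife-edge case of
#'   exactly neutral T- invasion fitness (a resistant clone is not excluded,
#'   merely not amplified).
#'
#' @param params a [patient_params()] object.
#' @param tol tolerance used for the strict-negativity and the 20% cutoffs.
#' @return Character scalar, one of `"BEST_RESPONDER"`, `"RESPONDER"`,
#'   `"NON_RESPONDER"`, with the ESS attached as attribute `ess`.
#' @examples
#' classify_patient(table3_patient(1))  # BEST_RESPONDER
#' classify_patient(table3_patient(2))  # RESPONDER
#' @export
classify_patient <- function(params, tol = 1e-9) {
  ess <- untreated_ess(params, tol = tol)
  f3 <- ess$frequencies[3]
  fit <- attr(ess, "tminus_fitness")
  cls <- if (!is.na(fit) && fit < -tol) "BEST_RESPONDER"
         else if (f3 >= 0.20 - tol) "NON_RESPONDER"
         else "RESPONDER"
  attr(cls, "ess") <- ess
  cls
}

#' Initial tumor state: 25% of the untreated equilibrium
#'
#' The pre-abiraterone tumor is initialized at the ESS frequencies with total
#' cell count and PSA at 25% of their untreated equilibrium values. When T-
#' is absent from the ESS (best responders) a small inoculum is placed in
#' `x3` so that a resistant clone can later emerge under therapy; it decays
#' before therapy (negative invasion fitness) and expands under drug.
#'
#' @param params a [patient_params()] object.
#' @param tminus_inoculum cells to seed into `x3` when T- is absent from the
#'   ESS (default 1). Zero keeps T- extinct for all time.
#' @param ess optionally, a precomputed [untreated_ess()].
#' @return A [tumor_state()] vector at time 0.
#' @export
initialize_patient <- function(params, tminus_inoculum = 1, ess = NULL) {
  stopifnot(tminus_inoculum >= 0)
  if (is.null(ess)) ess <- untreated_ess(params)
  x <- 0.25 * ess$abundances
  if (!(3L %in% ess$present)) x[3] <- tminus_inoculum
  tumor_state(x, 0.25 * ess$psa_star)
}
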