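#' Labels of the six off-diagonal competition coefficients
#'
#' Label `aij` is the effect of phenotype `j` on phenotype `i`
#' (row = affected, column = acting), in the fixed order used throughout:
#' `a12, a13, a21, a23, a31, a32`.
#' @export
COEF_LABELS <- c("a12", "a13", "a21", "a23", "a31", "a32")

# the partial order on coefficient ranks: each row says "first > second".
# T+ deprived of exogenous testosterone is the weakest competitor, and T-
# presses harder on TP than on T+.
.INEQUALITIES <- matrix(c("a31", "a21",
                          "a32", "a12",
                          "a13", "a23",
                          "a13", "a12",
                          "a23", "a21",
                          "a32", "a31"),
                        ncol = 2, byrow = TRUE)

#' Check a rank assignment against the model's six inequalities
#'
#' @param ranks integer vector of length 6, a permutation of 1..6 assigning a
#'   rank (1 = smallest coefficient) to each label in [COEF_LABELS] order.
#' @return `TRUE` if all six inequalities hold on the ranks, else `FALSE`.
#'   Errors if `ranks` is not a permutation of 1..6.
#' @examples
#' validate_ordering(c(4, 5, 1, 2, 3, 6))  # Table-3 patient 1
#' @export
validate_ordering <- function(ranks) {
  ranks <- as.integer(ranks)
  if (length(ranks) != 6 || !identical(sort(ranks), 1:6))
    stop("ranks must be a permutation of 1..6")
  names(ranks) <- COEF_LABELS
  all(ranks[.INEQUALITIES[, 1]] > ranks[.INEQUALITIES[, 2]])
}

#' Enumerate all admissible rank orderings of the competition coefficients
#'
#' Filters every permutation of ranks 1..6 over the six off-diagonal labels
#' through the model's six pairwise inequalities. The admissible set (the
#' linear extensions of the partial order) has 22 members and is returned in
#' a canonical order: lexicographic by rank tuple in [COEF_LABELS] order, so
#' that "ordering #k" is stable across calls and versions.
#'
#' @return Integer matrix with 22 rows and 6 columns (named by
#'   [COEF_LABELS]); each row is one admissible rank assignment.
#' @examples
#' nrow(enumerate_orderings())  # 22
#' @export
enumerate_orderings <- function() {
  if (!is.null(.ordering_cache$orderings)) return(.ordering_cache$orderings)
  P <- pracma::perms(1:6)
  keep <- apply(P, 1, function(p) {
    names(p) <- COEF_LABELS
    all(p[.INEQUALITIES[, 1]] > p[.INEQUALITIES[, 2]])
  })
  out <- P[keep, , drop = FALSE]
  out <- out[do.call(order, as.data.frame(out)), , drop = FALSE]
  storage.mode(out) <- "integer"
  colnames(out) <- COEF_LABELS
  rownames(out) <- seq_len(nrow(out))
  .ordering_cache$orderings <- out
  out
}

# enumeration is deterministic; cache it for repeated draws
.ordering_cache <- new.env(parent = emptyenv())

#' Coefficient value grid assigned to ranks 1..6
#'
#' @param values strictly increasing numeric vector of 6 values in (0, 1);
#'   rank k receives `values[k]`.
#' @return The validated vector.
#' @export
coefficient_values <- function(values = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9)) {
  stopifnot(length(values) == 6)
  if (any(diff(values) <= 0))
    stop("coefficient values must be strictly increasing (ties would break the rank taxonomy)")
  if (any(values <= 0 | values >= 1))
    stop("coefficient values must lie strictly in (0, 1)")
  values
}

#' Mean-preserving rescaling of the coefficient value grid
#'
#' Widens (`spread > 1`) or narrows (`spread < 1`) the six coefficient values
#' about their mean, for sensitivity sweeps over the strength of inter-type
#' competition.
#'
#' @param spread positive scalar multiplier of deviations from the mean.
#' @param values base grid, see [coefficient_values()].
#' @return A new strictly increasing grid; errors if the result leaves (0, 1).
#' @export
spread_values <- function(spread, values = coefficient_values()) {
  stopifnot(spread > 0)
  coefficient_values(mean(values) + spread * (values - mean(values)))
}

#' Build a competition matrix from a rank ordering and a value grid
#'
#' @inheritParams validate_ordering
#' @param values value grid, see [coefficient_values()].
#' @return 3x3 competition matrix with unit diagonal; entry for label `aij`
#'   is `values[rank(aij)]`.
#' @examples
#' ordering_to_matrix(c(4, 5, 1, 2, 3, 6))  # Table-3 patient 1 matrix
#' @export
ordering_to_matrix <- function(ranks, values = coefficient_values()) {
  if (!validate_ordering(ranks))
    stop("rank assignment violates the competition partial order")
  values <- coefficient_values(values)
  A <- diag(3)
  idx <- matrix(c(1,2, 1,3, 2,1, 2,3, 3,1, 3,2), ncol = 2, byrow = TRUE)
  A[idx] <- values[as.integer(ranks)]
  dimnames(A) <- list(PHENOTYPES, PHENOTYPES)
  A
}

#' Competition matrices of the two representative patients
#'
#' The two printed representative parameterizations: patient 1 (no resistant
#' T- clone before therapy) and patient 2 (small T- clone present at
#' equilibrium).
#'
#' @param which 1 or 2.
#' @return 3x3 competition matrix.
#' @export
table3_matrix <- function(which) {
  which <- match.arg(as.character(which), c("1", "2"))
  if (which == "1")
    m <- rbind(c(1, 0.7, 0.8), c(0.4, 1, 0.5), c(0.6, 0.9, 1))
  else
    m <- rbind(c(1, 0.6, 0.8), c(0.4, 1, 0.7), c(0.5, 0.9, 1))
  dimnames(m) <- list(PHENOTYPES, PHENOTYPES)
  m
}

#' Full parameterization of a representative patient
#'
#' @inheritParams table3_matrix
#' @param ... passed to [patient_params()].
#' @return A [patient_params()] object.
#' @export
table3_patient <- function(which, ...) {
  patient_params(table3_matrix(which), ...)
}

#' Parameterization from an admissible ordering index
#'
#' @param index row index into [enumerate_orderings()] (1..22).
#' @param values value grid, see [coefficient_values()].
#' @param ... passed to [patient_params()].
#' @return A [patient_params()] object carrying an `ordering_index` attribute.
#' @export
ordering_patient <- function(index, values = coefficient_values(), ...) {
  ords <- enumerate_orderings()
  stopifnot(length(index) == 1, index >= 1, index <= nrow(ords))
  p <- patient_params(ordering_to_matrix(ords[index, ], values), ...)
  attr(p, "ordering_index") <- as.integer(index)
  p
}

#' Draw a virtual patient uniformly from the admissible matrix space
#'
#' Samples one of the 22 admissible rank orderings uniformly at random and
#' returns the full default parameterization. Patient-to-patient variability
#' in the model is entirely carried by the arrangement of the competition
#' matrix.
#'
#' @param seed optional integer; when given, the draw is a deterministic
#'   function of the seed and the caller's RNG state is left untouched.
#' @param values value grid, see [coefficient_values()].
#' @param ... passed to [patient_params()].
#' @return A [patient_params()] object with an `ordering_index` attribute.
#' @export
sample_virtual_patient <- function(seed = NULL, values = coefficient_values(), ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  ordering_patient(sample.int(22L, 1L), values, ...)
}
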