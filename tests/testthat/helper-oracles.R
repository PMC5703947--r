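# Independent oracles, deliberately implemented without touching the
# package's own code paths.

# all permutations of 1..n by recursive insertion
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  smaller <- perms_oracle(n - 1)
  out <- NULL
  for (i in seq_len(nrow(smaller))) {
    row <- smaller[i, ]
    for (pos in 0:(n - 1))
      out <- rbind(out, append(row, n, after = pos))
  }
  out
}

# brute-force filter of all 720 rank permutations against the six pairwise
# constraints, labels in (a12, a13, a21, a23, a31, a32) order
orderings_oracle <- function() {
  P <- perms_oracle(6)
  keep <- apply(P, 1, function(p) {
    a12 <- p[1]; a13 <- p[2]; a21 <- p[3]; a23 <- p[4]; a31 <- p[5]; a32 <- p[6]
    a31 > a21 && a32 > a12 && a13 > a23 && a13 > a12 && a23 > a21 && a32 > a31
  })
  P[keep, , drop = FALSE]
}

# hypergeometric lower tail by direct summation of point masses in log space
hyper_tail_oracle <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  ks <- max(0, n - (N - K)):min(n, K)
  ks <- ks[ks <= a]
  if (length(ks) == 0) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# steady state of the untreated community by an independent linear solve:
# rows i in `present` of  sum_j a_ij x_j = K_i  with K1 = 1.5 x2 moved left
steady_state_oracle <- function(A, present, k2 = 1e4, k3 = 1e4, cf = 1.5) {
  M <- A[present, present, drop = FALSE]
  b <- c(0, k2, k3)[present]
  if (1 %in% present && 2 %in% present) {
    i <- which(present == 1); j <- which(present == 2)
    M[i, j] <- M[i, j] - cf
  }
  x <- numeric(3)
  x[present] <- solve(M, b)
  x
}
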