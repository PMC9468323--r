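# Independent oracles used across the suite.  Each is written as plain,
# direct arithmetic so it cannot share a code path with the package.

# Permutation- and scale-invariant discrepancy between a true mixing A and
# an estimated unmixing W: amari_distance(W %*% A) is 0 iff W A is a
# scaled permutation.
amari_distance <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  row_term <- sum(rowSums(P / apply(P, 1, max)) - 1)
  col_term <- sum(colSums(sweep(P, 2, apply(P, 2, max), "/")) - 1)
  (row_term + col_term) / (2 * n * (n - 1))
}

# Pearson correlation by direct summation of the normalised products,
# population denominators throughout.
pearson_by_sums <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sa <- sqrt(sum((a - ma)^2) / n)
  sb <- sqrt(sum((b - mb)^2) / n)
  total <- 0
  for (k in seq_len(n))
    total <- total + ((a[k] - ma) / sa) * ((b[k] - mb) / sb)
  total / n
}

# Scalar (H = 1, d = 1) LSTM cell evaluated step by step with plain
# arithmetic: weights are length-2 vectors acting on c(h_prev, x).
scalar_cell_oracle <- function(wf, bf, wi, bi, wc, bc, wo, bo,
                               x, h_prev, c_prev) {
  sig <- function(u) 1 / (1 + exp(-u))
  z <- c(h_prev, x)
  f <- sig(sum(wf * z) + bf)
  i <- sig(sum(wi * z) + bi)
  ctil <- tanh(sum(wc * z) + bc)
  c_new <- c_prev * f + i * ctil
  h_new <- sig(sum(wo * z) + bo) * tanh(c_new)
  list(h = h_new, C = c_new)
}

# Mean dwell time of a state sequence via run-length tally.
mean_dwell_of <- function(states) mean(rle(states)$lengths)

# Small stationary single-state cohort time courses for reuse.
make_test_tc <- function(n_time = 120, K = 6, r = 0.4, seed = 7) {
  C <- diag(K)
  C[1, 2] <- C[2, 1] <- r
  sample_component_timecourses(integer(n_time), list(C), seed = seed)
}
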