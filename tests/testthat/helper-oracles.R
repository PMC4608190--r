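# Independent oracles and small fixtures shared across test files.

# Literal triple-sum evaluation of the trilinear model, kept independent of
# the package's matrix implementation.
reconstruct_oracle <- function(A, B, C, G) {
  n <- nrow(A); m <- nrow(B); TT <- nrow(C)
  P <- ncol(A); Q <- ncol(B); R <- ncol(C)
  X <- array(0, dim = c(n, m, TT))
  for (i in seq_len(n)) for (j in seq_len(m)) for (k in seq_len(TT)) {
    acc <- 0
    for (p in seq_len(P)) for (q in seq_len(Q)) for (r in seq_len(R))
      acc <- acc + A[i, p] * B[j, q] * C[k, r] * G[p, q, r]
    X[i, j, k] <- acc
  }
  X
}

random_factors <- function(n, m, TT, P, Q, R) {
  list(A = matrix(rnorm(n * P), n, P), B = matrix(rnorm(m * Q), m, Q),
       C = matrix(rnorm(TT * R), TT, R),
       G = array(rnorm(P * Q * R), dim = c(P, Q, R)))
}

# Long records for a fully crossed tiny design with deterministic scores.
tiny_records <- function(n = 2, m = 2, TT = 2, items = c("5", "10")) {
  g <- expand.grid(person_id = sprintf("p%d", seq_len(n)), item = items[seq_len(m)],
                   time = seq_len(TT), stringsAsFactors = FALSE)
  g$score <- (seq_len(nrow(g)) %% 3)
  g[, c("person_id", "time", "item", "score")]
}

# Full raw QIDS record set (16 items) for one or more person-times.
raw_qids_records <- function(persons = c("a", "b"), times = 1:2, score = 1L) {
  g <- expand.grid(person_id = persons, time = times, item = as.character(1:16),
                   stringsAsFactors = FALSE)
  g$score <- score
  g[, c("person_id", "time", "item", "score")]
}

expect_orthonormal <- function(M, tol = 1e-8) {
  expect_lt(max(abs(crossprod(M) - diag(ncol(M)))), tol)
}
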