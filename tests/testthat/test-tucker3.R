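test_that("unfolding follows the stated index conventions and round-trips", {
  x <- array(0, dim = c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (t in 1:2)
    x[i, j, t] <- i + 2 * (j - 1) + 4 * (t - 1)
  expect_equal(unfold_cube(x, "person")[1, ], c(1, 3, 5, 7))
  set.seed(21)
  for (rep in 1:10) {
    y <- array(rnorm(24), dim = c(2, 3, 4))
    for (mode in 1:3)
      expect_identical(refold_cube(unfold_cube(y, mode), mode, dim(y)), y)
  }
  expect_true(all(unfold_cube(array(0, c(2, 2, 2)), "time") == 0))
  expect_error(unfold_cube(x, "bogus"))
})

test_that("reconstruction matches the triple-loop oracle", {
  set.seed(22)
  f <- random_factors(4, 3, 2, 3, 2, 2)
  expect_lt(max(abs(tucker3_reconstruct(f$A, f$B, f$C, f$G) -
                      reconstruct_oracle(f$A, f$B, f$C, f$G))), 1e-12)
  expect_true(all(tucker3_reconstruct(f$A, f$B, f$C, array(0, dim = c(3, 2, 2))) == 0))
  expect_error(tucker3_reconstruct(f$A, f$B, f$C, array(0, dim = c(2, 2, 2))),
               "core dimensions", class = "hetcube_invalid_input")
})

test_that("HOSVD initialization gives orthonormal, subspace-recovering bases", {
  set.seed(23)
  x <- array(rnorm(8 * 5 * 4), dim = c(8, 5, 4))
  init <- hosvd_init(x, 3, 2, 2)
  for (M in init) expect_orthonormal(M)
  full <- hosvd_init(x, 8, 5, 4)
  for (M in full) expect_orthonormal(M)
  # noise-free planted cube: column spaces match the planted spaces
  g <- generate_planted_cube(n = 20, m = 8, T = 6, P = 2, Q = 2, R = 2,
                             noise_sd = 0, seed = 7)
  est <- hosvd_init(g$cube, 2, 2, 2)
  ang <- function(U, V) max(abs(svd(crossprod(U, V))$d - 1))
  expect_lt(ang(est$A, g$truth$A), 1e-8)
  expect_lt(ang(est$B, g$truth$B), 1e-8)
  expect_lt(ang(est$C, g$truth$C), 1e-8)
  expect_error(hosvd_init(x, 9, 2, 2), "exceed", class = "hetcube_invalid_input")
})

test_that("least-squares core satisfies the planted-core and Parseval identities", {
  set.seed(24)
  A <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  B <- qr.Q(qr(matrix(rnorm(5 * 2), 5, 2)))
  C <- qr.Q(qr(matrix(rnorm(4 * 3), 4, 3)))
  G <- array(rnorm(12), dim = c(2, 2, 3))
  x <- tucker3_reconstruct(A, B, C, G)
  expect_lt(max(abs(compute_core(x, A, B, C) - G)), 1e-10)
  expect_true(all(compute_core(array(0, dim = dim(x)), A, B, C) == 0))
  expect_error(compute_core(x, A * 2, B, C), "orthonormal",
               class = "hetcube_invalid_input")
  # saturated basis reconstructs exactly
  y <- array(rnorm(3 * 3 * 3), dim = c(3, 3, 3))
  full <- hosvd_init(y, 3, 3, 3)
  Gf <- compute_core(y, full$A, full$B, full$C)
  expect_lt(max(abs(tucker3_reconstruct(full$A, full$B, full$C, Gf) - y)), 1e-9)
})

test_that("fit percentage is 100 for exact fits and 0 for the zero model", {
  set.seed(25)
  x <- array(rnorm(4 * 3 * 3), dim = c(4, 3, 3))
  expect_equal(fit_percentage(x, x)$fit_percent, 100)
  expect_equal(fit_percentage(x, array(0, dim = dim(x)))$fit_percent, 0)
  expect_error(fit_percentage(array(0, dim = dim(x)), x),
               class = "hetcube_degenerate_input")
})

test_that("ALS recovers planted structure, saturates, and is deterministic", {
  g <- generate_planted_cube(n = 15, m = 6, T = 5, P = 3, Q = 2, R = 2,
                             noise_sd = 0, seed = 9)
  m1 <- fit_tucker3(g$cube, 3, 2, 2, n_starts = 2, seed = 1)
  expect_gt(m1$fit_percent, 99.999)
  for (M in list(m1$A, m1$B, m1$C)) expect_orthonormal(M)
  expect_true(all(diff(m1$fit_trace) > -1e-10))
  sat <- fit_tucker3(g$cube, 15, 6, 5, n_starts = 1)
  expect_equal(sat$fit_percent, 100, tolerance = 1e-6)
  m2 <- fit_tucker3(g$cube, 3, 2, 2, n_starts = 2, seed = 1)
  expect_identical(m1[c("A", "B", "C", "G", "fit_percent")],
                   m2[c("A", "B", "C", "G", "fit_percent")])
  expect_error(fit_tucker3(g$cube, 16, 2, 2), "exceed",
               class = "hetcube_invalid_input")
})

test_that("ALS fit never falls below the HOSVD-only fit", {
  set.seed(26)
  for (rep in 1:5) {
    x <- array(rnorm(10 * 6 * 5), dim = c(10, 6, 5))
    init <- hosvd_init(x, 2, 2, 2)
    g0 <- compute_core(x, init$A, init$B, init$C)
    hosvd_fit <- 100 * sum(g0^2) / sum(x^2)
    m <- fit_tucker3(x, 2, 2, 2, n_starts = 3, seed = rep)
    expect_gte(m$fit_percent, hosvd_fit - 1e-9)
  }
})

test_that("sign convention and component ordering are canonical", {
  g <- generate_planted_cube(n = 12, m = 6, T = 5, P = 2, Q = 2, R = 2,
                             noise_sd = 0.05, seed = 4)
  m <- fit_tucker3(g$cube, 2, 2, 2, n_starts = 2, seed = 1)
  for (M in list(m$A, m$B, m$C))
    for (k in seq_len(ncol(M)))
      expect_gt(M[which.max(abs(M[, k])), k], 0)
  for (mode in 1:3) {
    ss <- rowSums(unfold_cube(m$G, mode)^2)
    expect_true(all(diff(ss) <= 1e-10))
  }
})

test_that("rotating loadings and counter-rotating the core leaves the fit unchanged", {
  set.seed(27)
  g <- generate_planted_cube(n = 10, m = 5, T = 4, P = 2, Q = 2, R = 2,
                             noise_sd = 0.1, seed = 2)
  m <- fit_tucker3(g$cube, 2, 2, 2, n_starts = 1)
  for (rep in 1:5) {
    Rot <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
    A2 <- m$A %*% Rot
    G1 <- unfold_cube(m$G, 1)
    G2 <- refold_cube(crossprod(Rot, G1), 1, dim(m$G))
    expect_lt(max(abs(tucker3_reconstruct(A2, m$B, m$C, G2) -
                        tucker3_reconstruct(m$A, m$B, m$C, m$G))), 1e-10)
  }
})

test_that("ALS objective is monotone across random cubes and seeds", {
  set.seed(28)
  for (rep in 1:20) {
    x <- array(rnorm(8 * 5 * 4), dim = c(8, 5, 4))
    m <- fit_tucker3(x, sample(1:3, 1), sample(1:3, 1), sample(1:3, 1),
                     n_starts = 2, seed = rep)
    expect_true(all(diff(m$fit_trace) > -1e-10))
  }
})
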