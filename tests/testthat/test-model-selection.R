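test_that("free-parameter count uses the orthonormality correction", {
  expect_equal(tucker3_free_params(82, 12, 9, 3, 2, 2),
               82 * 3 + 12 * 2 + 9 * 2 + 12 - 9 - 4 - 4)
  # strictly increasing in each mode count away from saturation
  base <- tucker3_free_params(82, 12, 9, 2, 2, 2)
  expect_gt(tucker3_free_params(82, 12, 9, 3, 2, 2), base)
  expect_gt(tucker3_free_params(82, 12, 9, 2, 3, 2), base)
  expect_gt(tucker3_free_params(82, 12, 9, 2, 2, 3), base)
})

test_that("grid fits are monotone along every coordinate", {
  g <- generate_planted_cube(n = 16, m = 7, T = 5, P = 2, Q = 2, R = 2,
                             target_fit = 85, seed = 3)
  grid <- grid_search(g$cube, 3, 3, 3, seed = 1)
  df <- as.data.frame(grid)
  for (i in seq_len(nrow(df))) {
    for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      j <- which(df$P == df$P[i] + d[1] & df$Q == df$Q[i] + d[2] &
                   df$R == df$R[i] + d[3])
      if (length(j))
        expect_gte(df$fit_percent[j], df$fit_percent[i] - 1e-9)
    }
  }
})

test_that("bounds of one produce a single-entry grid", {
  g <- generate_planted_cube(n = 8, m = 5, T = 4, noise_sd = 0.2, seed = 5)
  grid <- grid_search(g$cube, 1, 1, 1)
  expect_equal(nrow(grid), 1L)
  expect_error(grid_search(g$cube, 9, 1, 1), "exceed",
               class = "hetcube_invalid_input")
})

test_that("elbow rule reproduces the stated small-grid decision", {
  toy <- data.frame(P = c(1, 2, 2, 2, 3), Q = c(1, 1, 2, 1, 1),
                    R = c(1, 1, 1, 2, 1),
                    fit_percent = c(50, 80, 80.4, 80.2, 80.3),
                    free_params = c(1, 2, 3, 4, 5))
  expect_equal(unname(select_model(toy, 1.0)$selected), c(2, 1, 1))
  flat <- data.frame(P = c(1, 2), Q = c(1, 2), R = c(1, 2),
                     fit_percent = c(70, 70), free_params = c(1, 2))
  expect_equal(unname(select_model(flat)$selected), c(1, 1, 1))
})

test_that("elbow rule is monotone in its threshold", {
  g <- generate_planted_cube(n = 20, m = 8, T = 6, P = 2, Q = 2, R = 2,
                             target_fit = 80, seed = 11)
  grid <- grid_search(g$cube, 3, 3, 3, seed = 1)
  sizes <- sapply(c(0.25, 0.5, 1, 2, 5, 20),
                  function(th) sum(select_model(grid, th)$selected))
  expect_true(all(diff(sizes) <= 0))
})

test_that("noise-free planted data select the planted component numbers", {
  g <- generate_planted_cube(n = 20, m = 8, T = 6, P = 3, Q = 2, R = 2,
                             noise_sd = 0, seed = 13)
  grid <- grid_search(g$cube, 4, 4, 4, seed = 1)
  df <- as.data.frame(grid)
  f <- function(P, Q, R) df$fit_percent[df$P == P & df$Q == Q & df$R == R]
  expect_gte(f(3, 2, 2), 99.9)
  expect_lt(f(2, 2, 2), f(3, 2, 2) - 1)
  expect_equal(unname(select_model(grid)$selected), c(3, 2, 2))
})
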