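test_that("planted cubes are seeded, exact at zero noise, and fit as constructed", {
  g1 <- generate_planted_cube(n = 20, m = 8, T = 6, noise_sd = 0.1, seed = 42)
  g2 <- generate_planted_cube(n = 20, m = 8, T = 6, noise_sd = 0.1, seed = 42)
  expect_identical(g1$cube, g2$cube)
  g0 <- generate_planted_cube(n = 20, m = 8, T = 6, P = 3, Q = 2, R = 2,
                              noise_sd = 0, seed = 1)
  m <- fit_tucker3(g0$cube, 3, 2, 2, n_starts = 1)
  expect_equal(m$fit_percent, 100, tolerance = 1e-6)
  # construction-expected fit at large size: observed within 2 points
  gt <- generate_planted_cube(n = 82, m = 12, T = 9, target_fit = 80, seed = 2)
  mt <- fit_tucker3(gt$cube, 3, 2, 2, n_starts = 1)
  expect_lt(abs(mt$fit_percent - 80), 2)
  expect_error(generate_planted_cube(core_scale = -1),
               class = "hetcube_invalid_input")
})

test_that("QIDS-like records are complete, ordinal, deterministic and trending down", {
  g <- generate_qids_like(seed = 3)
  expect_identical(g$records, generate_qids_like(seed = 3)$records)
  expect_true(all(g$records$score %in% 0:2))
  cube <- build_cube(g$records)
  expect_equal(dim(cube), c(82, 12, 9))
  s <- sum_scores(cube)
  expect_true(all(s >= 0 & s <= 24))
  expect_lt(mean(s[, 9]), mean(s[, 1]))             # shared downward trend
  expect_equal(length(g$truth$archetype), 82)
  expect_setequal(unique(g$truth$severity_class), 1:2)
})

test_that("raw-scale QIDS records exercise the full recoding path", {
  g <- generate_qids_like(n = 12, seed = 5, scale = "raw")
  expect_true(all(g$records$score %in% 0:3))
  expect_setequal(unique(g$records$item), as.character(1:16))
  rec <- recode_items(merge_top_category(g$records))
  cube <- build_cube(rec)
  expect_equal(dim(cube), c(12, 12, 9))
  expect_true(all(cube %in% 0:2))
})

test_that("zero interaction scale leaves only the shared trend", {
  g <- generate_qids_like(effect_scale = 0, seed = 7)
  pre <- preprocess_cube(build_cube(g$records))
  grid <- grid_search(pre, 2, 2, 2, seed = 7)
  sel <- select_model(grid)
  expect_equal(unname(sel$selected), c(1, 1, 1))
})

test_that("default QIDS-like cubes carry three-two-two structure", {
  g <- generate_qids_like(seed = 21)
  pre <- preprocess_cube(build_cube(g$records))
  grid <- grid_search(pre, 3, 3, 3, seed = 21)
  df <- as.data.frame(grid)
  f <- function(P, Q, R) df$fit_percent[df$P == P & df$Q == Q & df$R == R]
  expect_gt(f(3, 2, 2), f(2, 2, 2) + 1)             # third person component is material
})

test_that("LCA generator matches its mixture-implied category frequencies", {
  ip <- array(0, c(2, 4, 3))
  ip[1, , ] <- rep(c(0.6, 0.3, 0.1), each = 4)
  ip[2, , ] <- rep(c(0.2, 0.2, 0.6), each = 4)
  w <- c(0.3, 0.7)
  d <- generate_lca_data(w, ip, n = 10000, seed = 9)
  implied <- w[1] * ip[1, 1, ] + w[2] * ip[2, 1, ]
  emp <- sapply(0:2, function(c) mean(d$data[, 1] == c))
  expect_lt(max(abs(emp - implied)), 0.02)
  expect_true(all(generate_lca_data(1, ip[1, , , drop = FALSE], 20, 1)$classes == 1))
  expect_error(generate_lca_data(c(0.5, 0.6), ip, 10),
               class = "hetcube_invalid_input")
})

test_that("growth generator produces exact curves at zero variance", {
  beta <- rbind(c(10, -1, 0.05), c(20, 0.5, -0.02))
  d <- generate_growth_data(c(0.5, 0.5), beta, n = 20, T = 6, sigma2 = 0,
                            tau2 = 0, seed = 4)
  tt <- 1:6
  X <- cbind(1, tt, tt^2)
  for (i in 1:20)
    expect_equal(d$data[i, ], as.vector(X %*% beta[d$classes[i], ]),
                 tolerance = 1e-12)
  expect_error(generate_growth_data(1, beta[1, , drop = FALSE], 10, sigma2 = -1),
               class = "hetcube_invalid_input")
})
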