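test_that("information criteria follow their definitions", {
  ic <- information_criteria(-10, 2, 100)
  expect_equal(ic$aic, 24)
  expect_equal(ic$bic, 20 + 2 * log(100))
  expect_error(information_criteria(NaN, 2, 10), class = "hetcube_invalid_input")
  expect_error(information_criteria(-10, 0, 10))
  # BIC >= AIC once ln(n) > 2
  ic8 <- information_criteria(-50, 3, 8)
  expect_gte(ic8$bic, ic8$aic)
})

test_that("one-class LCA is the closed-form multinomial fit", {
  set.seed(41)
  dat <- matrix(sample(0:2, 60 * 6, replace = TRUE, prob = c(0.5, 0.3, 0.2)), 60, 6)
  f <- fit_lca(dat, 1)
  expect_equal(f$weights, 1)
  freq <- sapply(0:2, function(c) colMeans(dat == c))
  expect_equal(matrix(f$item_probs[1, , ], ncol = 3), freq, tolerance = 1e-12,
               ignore_attr = TRUE)
  ll <- sum(sapply(seq_len(6), function(j)
    sum(sapply(0:2, function(c) sum(dat[, j] == c) * log(freq[j, c + 1])))))
  expect_equal(f$loglik, ll, tolerance = 1e-9)
  expect_equal(f$n_params, 0 + 1 * 6 * 2)
})

test_that("LCA EM is monotone and recovers separated two-class structure", {
  ip <- array(0, c(2, 8, 3))
  ip[1, , ] <- rep(c(0.90, 0.07, 0.03), each = 8)
  ip[2, , ] <- rep(c(0.03, 0.07, 0.90), each = 8)
  d <- generate_lca_data(c(0.6, 0.4), ip, n = 1000, seed = 8)
  f <- suppressWarnings(fit_lca(d$data, 2, n_starts = 3, seed = 8))
  expect_true(all(diff(f$loglik_trace) > -1e-8))
  expect_true(all(diff(f$weights) <= 0))           # descending class weights
  # match classes by weight order (true class 1 has weight 0.6)
  expect_lt(max(abs(f$item_probs[1, , ] - ip[1, , ])), 0.05)
  expect_lt(max(abs(f$item_probs[2, , ] - ip[2, , ])), 0.05)
  expect_error(fit_lca(d$data, 2000), "exceeds", class = "hetcube_invalid_input")
  expect_error(fit_lca(d$data + 5, 2), class = "hetcube_invalid_input")
})

test_that("class profile table gives the probability of a non-zero response", {
  ip <- array(0, c(1, 3, 3))
  ip[1, , ] <- rbind(c(1, 0, 0), c(0.4, 0.35, 0.25), c(0, 0.5, 0.5))
  d <- generate_lca_data(1, ip, n = 50, seed = 2)
  f <- suppressWarnings(fit_lca(d$data, 1))
  tab <- class_profile_table(f)
  expect_equal(tab$class1, 1 - f$item_probs[1, , 1], tolerance = 1e-12)
  expect_equal(tab$class1[1], 0)                    # always category 0
  expect_equal(tab$class1[3], 1)                    # never category 0
})

test_that("one-class LCGM collapses to the pooled quadratic least-squares fit", {
  set.seed(42)
  d <- generate_growth_data(1, matrix(c(20, -2, 0.1), 1), n = 40, T = 9,
                            sigma2 = 4, seed = 5)
  f <- fit_growth_mixture(d$data, 1, "lcgm")
  tt <- rep(1:9, each = 40)
  y <- as.vector(d$data)
  ols <- lm(y ~ tt + I(tt^2))
  expect_equal(unname(f$beta[1, ]), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$sigma2, mean(residuals(ols)^2), tolerance = 1e-8)
  expect_equal(f$tau2, 0)
})

test_that("growth mixture EM is monotone and recovers separated classes", {
  d <- generate_growth_data(c(0.7, 0.3), rbind(c(20, -2, 0.05), c(22, -0.5, 0)),
                            n = 500, T = 9, sigma2 = 4, tau2 = 0, seed = 12)
  f <- suppressWarnings(fit_growth_mixture(d$data, 2, "lcgm", n_starts = 3, seed = 12))
  expect_true(all(diff(f$loglik_trace) > -1e-6))
  expect_lt(abs(f$weights[1] - 0.7), 0.05)
  km <- kmeans(d$data, centers = 2, nstart = 5)
  agree <- max(mean((km$cluster == 1) == (d$classes == 1)),
               mean((km$cluster == 2) == (d$classes == 1)))
  expect_gte(agree, 0.95)                           # sanity oracle on separation
  expect_error(fit_growth_mixture(d$data[, 1:2], 2), "T >= 3",
               class = "hetcube_invalid_input")
})

test_that("the random-intercept model nests the latent-class growth model", {
  for (s in 1:3) {
    d <- generate_growth_data(c(0.6, 0.4), rbind(c(18, -1.5, 0.05), c(22, -0.2, 0)),
                              n = 120, T = 9, sigma2 = 3, tau2 = 3, seed = s)
    l <- suppressWarnings(fit_growth_mixture(d$data, 2, "lcgm", n_starts = 2, seed = s))
    g <- suppressWarnings(fit_growth_mixture(d$data, 2, "gmm_ri", n_starts = 2, seed = s))
    expect_gte(g$loglik, l$loglik - 1e-6)
    expect_equal(l$tau2, 0)
    expect_gt(g$tau2, 0)
  }
})

test_that("one-class data lead BIC to prefer one class most of the time", {
  wins <- 0L
  for (s in 1:10) {
    d <- generate_growth_data(1, matrix(c(20, -1.5, 0.05), 1), n = 500, T = 9,
                              sigma2 = 4, seed = s)
    f1 <- suppressWarnings(fit_growth_mixture(d$data, 1, "lcgm"))
    f2 <- suppressWarnings(fit_growth_mixture(d$data, 2, "lcgm", n_starts = 2, seed = s))
    wins <- wins + (f1$bic < f2$bic)
  }
  expect_gte(wins, 9L)
})

test_that("comparison table collects k, loglik, AIC and BIC per model", {
  d <- generate_growth_data(1, matrix(c(20, -1, 0), 1), n = 30, T = 5,
                            sigma2 = 2, seed = 3)
  f1 <- suppressWarnings(fit_growth_mixture(d$data, 1, "lcgm"))
  f2 <- suppressWarnings(fit_growth_mixture(d$data, 1, "gmm_ri"))
  tab <- ic_comparison_table(list(f1, f2))
  expect_equal(tab$model, c("LCGM", "GMM_RI"))
  expect_equal(tab$k, c(4, 5))
  expect_equal(tab$aic, -2 * tab$loglik + 2 * tab$k)
})
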