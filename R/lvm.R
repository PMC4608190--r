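#' @title Single-slice latent variable baselines
#' @description The traditional models the multiway decomposition is compared
#'   against: latent class analysis of the cross-sectional ordinal item slice
#'   (finite mixture with local independence) and trajectory mixtures of the
#'   sum-score matrix — latent class growth models (no within-class variance)
#'   and growth mixture models with random intercepts. Models are compared
#'   via AIC and BIC.
#' @name lvm
NULL

logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Akaike and Bayesian information criteria
#'
#' AIC = -2 loglik + 2 k; BIC = -2 loglik + k log(n) with n the number of
#' persons.
#'
#' @param loglik maximized log-likelihood. @param k free parameters (>= 1).
#' @param n sample size (persons).
#' @return list with `aic`, `bic`, `k`, `n`.
#' @export
information_criteria <- function(loglik, k, n) {
  if (!is.finite(loglik))
    stop_hetcube("non-finite log-likelihood", class = "hetcube_invalid_input")
  stopifnot(k >= 1, n >= 1)
  list(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n), k = k, n = n)
}

#' Latent class analysis of an ordinal item slice by EM
#'
#' Finite mixture of K classes for n x m items scored 0/1/2, with local
#' independence within class. The E-step computes posterior class
#' responsibilities; the M-step sets class weights and class-conditional
#' category probabilities to responsibility-weighted frequencies, so the
#' observed-data log-likelihood is non-decreasing across iterations. The best
#' of `n_starts` seeded random initializations is returned, with classes
#' ordered by descending weight.
#'
#' @param slice n x m integer matrix with entries in {0, 1, 2}.
#' @param K number of classes (>= 1).
#' @param n_starts,tol,max_iter,seed EM settings.
#' @return an `lca_model`: `K`, `weights`, `item_probs` (K x m x 3),
#'   `loglik`, `aic`, `bic`, `n_params`, `loglik_trace`, `responsibilities`,
#'   `assignments`.
#' @export
fit_lca <- function(slice, K, n_starts = 5L, tol = 1e-8, max_iter = 500L,
                    seed = 1L) {
  stopifnot(is.matrix(slice), nrow(slice) >= 1L, ncol(slice) >= 1L)
  if (!all(slice %in% 0:2))
    stop_hetcube("slice entries must be in {0,1,2}", class = "hetcube_invalid_input")
  n <- nrow(slice); m <- ncol(slice)
  if (K > n) stop_hetcube("K = %d exceeds n = %d", K, n,
                          class = "hetcube_invalid_input")
  ncat <- 3L
  # indicator matrices per category: n x m
  ind <- lapply(0:2, function(c) slice == c)

  run_em <- function(resp) {
    trace <- numeric(0)
    prev <- -Inf
    for (iter in seq_len(max_iter)) {
      # M-step from current responsibilities
      wsum <- colSums(resp)                      # K
      weights <- wsum / n
      item_probs <- array(0, dim = c(K, m, ncat))
      for (c in seq_len(ncat))
        item_probs[, , c] <- t(crossprod(ind[[c]], resp)) / wsum  # K x m
      # E-step densities
      logp <- log(pmax(item_probs, 1e-300))
      logf <- matrix(0, n, K)
      for (c in seq_len(ncat))
        logf <- logf + ind[[c]] %*% t(matrix(logp[, , c], nrow = K))
      lw <- sweep(logf, 2, log(pmax(weights, 1e-300)), "+")
      ll <- sum(logsumexp(lw))
      trace <- c(trace, ll)
      resp <- exp(lw - logsumexp(lw))
      if (is.finite(prev) && abs(ll - prev) < tol * (abs(ll) + 1)) break
      prev <- ll
    }
    list(weights = weights, item_probs = item_probs, loglik = ll,
         trace = trace, resp = resp, iterations = iter,
         converged = iter < max_iter)
  }

  best <- NULL
  for (s in seq_len(max(n_starts, 1L))) {
    set.seed(derive_seed(seed, 100L + s))
    resp <- matrix(stats::runif(n * K) + 0.1, n, K)
    resp <- resp / rowSums(resp)
    if (K == 1L) resp <- matrix(1, n, 1)
    r <- run_em(resp)
    if (is.null(best) || r$loglik > best$loglik) best <- r
    if (K == 1L) break  # closed form after one M-step; no restarts needed
  }

  ord <- order(-best$weights, seq_len(K))
  n_params <- (K - 1L) + K * m * (ncat - 1L)
  ic <- information_criteria(best$loglik, n_params, n)
  assignments <- apply(best$resp[, ord, drop = FALSE], 1, which.max)
  sizes <- tabulate(assignments, K)
  if (any(sizes < 10))
    warning(sprintf("smallest class contains < 10 subjects (sizes: %s)",
                    paste(sizes, collapse = ", ")))
  structure(list(K = K, weights = best$weights[ord],
                 item_probs = best$item_probs[ord, , , drop = FALSE],
                 loglik = best$loglik, aic = ic$aic, bic = ic$bic,
                 n_params = n_params, n = n, m = m,
                 loglik_trace = best$trace,
                 responsibilities = best$resp[, ord, drop = FALSE],
                 assignments = assignments,
                 iterations = best$iterations, converged = best$converged),
            class = "lca_model")
}

#' Per-class probability of a non-zero response per item
#'
#' Entry = 1 - P(category 0 | class, item): the endorsement-probability
#' profile usually plotted to interpret class differences.
#'
#' @param model an `lca_model`.
#' @param item_labels optional item names for the table's first column.
#' @return data frame: item, one `class<k>` column per class.
#' @export
class_profile_table <- function(model, item_labels = NULL) {
  stopifnot(inherits(model, "lca_model"))
  pnz <- 1 - model$item_probs[, , 1, drop = FALSE]
  dim(pnz) <- dim(model$item_probs)[1:2]
  out <- data.frame(item = item_labels %||% as.character(seq_len(model$m)))
  for (k in seq_len(model$K)) out[[paste0("class", k)]] <- pnz[k, ]
  out
}

#' Growth mixtures of sum-score trajectories by EM
#'
#' K-class mixture of T-variate normals over per-person trajectories, each
#' class with a quadratic mean curve beta0 + beta1 t + beta2 t^2 on time
#' t = 1..T. `kind = "lcgm"` (latent class growth model) uses within-class
#' covariance sigma^2 I — all growth-parameter variances fixed at zero.
#' `kind = "gmm_ri"` adds a random intercept: covariance tau^2 J + sigma^2 I
#' (compound symmetry). Slopes and quadratic terms never get random effects,
#' and sigma^2 (and tau^2) are shared across classes. Fitting is
#' expectation/conditional-maximization: class curves by generalized least
#' squares given the variances, then exact closed-form variance updates via
#' the compound-symmetry eigendecomposition, so the log-likelihood is
#' non-decreasing. LCGM is the tau^2 = 0 restriction of the random-intercept
#' model.
#'
#' @param sums n x T numeric matrix of sum scores.
#' @param K number of classes.
#' @param kind `"lcgm"` or `"gmm_ri"`.
#' @param n_starts,tol,max_iter,seed EM settings; start 1 is k-means on the
#'   trajectories, the rest are random partitions.
#' @return a `growth_mixture`: `K`, `kind`, `weights`, `beta` (K x 3),
#'   `sigma2`, `tau2`, `loglik`, `aic`, `bic`, `n_params`, `loglik_trace`,
#'   `responsibilities`, `assignments`.
#' @export
fit_growth_mixture <- function(sums, K, kind = c("lcgm", "gmm_ri"),
                               n_starts = 5L, tol = 1e-8, max_iter = 500L,
                               seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(sums))
  if (any(!is.finite(sums)))
    stop_hetcube("sum-score matrix contains non-finite values",
                 class = "hetcube_invalid_input")
  n <- nrow(sums); TT <- ncol(sums)
  if (TT < 3) stop_hetcube("quadratic growth curve needs T >= 3 time points",
                           class = "hetcube_invalid_input")
  if (K > n) stop_hetcube("K = %d exceeds n = %d", K, n,
                          class = "hetcube_invalid_input")
  tt <- seq_len(TT)
  X <- cbind(1, tt, tt^2)

  # log N(y; mu, sigma2 I + tau2 J) via the compound-symmetry spectrum:
  # eigenvalue sigma2 + T tau2 on the constant direction, sigma2 elsewhere.
  class_logdens <- function(beta, sigma2, tau2) {
    b <- sigma2 + TT * tau2
    out <- matrix(0, n, K)
    for (k in seq_len(K)) {
      D <- sums - matrix(X %*% beta[k, ], n, TT, byrow = TRUE)
      mi <- rowMeans(D)
      si <- rowSums((D - mi)^2)
      out[, k] <- -0.5 * (TT * log(2 * pi) + (TT - 1) * log(sigma2) + log(b) +
                            si / sigma2 + TT * mi^2 / b)
    }
    out
  }

  mstep <- function(resp, sigma2, tau2) {
    wsum <- colSums(resp)
    weights <- wsum / n
    # GLS class curves: with a common design, weighted GLS reduces to GLS on
    # the responsibility-weighted mean trajectory.
    b <- sigma2 + TT * tau2
    rho <- tau2 / b
    Sinv <- (diag(TT) - rho * matrix(1, TT, TT)) / sigma2
    XtS <- crossprod(X, Sinv)
    H <- solve(XtS %*% X)
    beta <- matrix(0, K, 3)
    for (k in seq_len(K)) {
      ybar <- colSums(resp[, k] * sums) / wsum[k]
      beta[k, ] <- H %*% (XtS %*% ybar)
    }
    # exact variance update given the curves
    ssdev <- 0; ssmean <- 0
    for (k in seq_len(K)) {
      D <- sums - matrix(X %*% beta[k, ], n, TT, byrow = TRUE)
      mi <- rowMeans(D)
      ssdev <- ssdev + sum(resp[, k] * rowSums((D - mi)^2))
      ssmean <- ssmean + sum(resp[, k] * TT * mi^2)
    }
    if (kind == "gmm_ri") {
      a <- ssdev / (n * (TT - 1))
      bb <- ssmean / n
      if (bb > a) { sigma2 <- a; tau2 <- (bb - a) / TT }
      else { sigma2 <- (ssdev + ssmean) / (n * TT); tau2 <- 0 }
    } else {
      sigma2 <- (ssdev + ssmean) / (n * TT)
      tau2 <- 0
    }
    list(weights = weights, beta = beta,
         sigma2 = max(sigma2, 1e-10), tau2 = tau2)
  }

  run_em <- function(resp) {
    p <- mstep(resp, sigma2 = stats::var(as.vector(sums)) + 1e-8, tau2 = 0)
    trace <- numeric(0)
    prev <- -Inf
    for (iter in seq_len(max_iter)) {
      lw <- sweep(class_logdens(p$beta, p$sigma2, p$tau2), 2,
                  log(pmax(p$weights, 1e-300)), "+")
      ll <- sum(logsumexp(lw))
      trace <- c(trace, ll)
      resp <- exp(lw - logsumexp(lw))
      if (is.finite(prev) && abs(ll - prev) < tol * (abs(ll) + 1)) break
      prev <- ll
      p <- mstep(resp, p$sigma2, p$tau2)
    }
    c(p, list(loglik = ll, trace = trace, resp = resp, iterations = iter,
              converged = iter < max_iter))
  }

  best <- NULL
  for (s in seq_len(max(n_starts, 1L))) {
    set.seed(derive_seed(seed, 200L + s))
    resp <- matrix(0, n, K)
    if (K == 1L) {
      resp[, 1] <- 1
    } else if (s == 1L) {
      km <- stats::kmeans(sums, centers = K, nstart = 5)
      resp[cbind(seq_len(n), km$cluster)] <- 1
    } else {
      resp[cbind(seq_len(n), sample.int(K, n, replace = TRUE))] <- 1
      if (any(colSums(resp) == 0)) next
    }
    r <- run_em(resp)
    if (is.null(best) || r$loglik > best$loglik) best <- r
    if (K == 1L) break
  }

  ord <- order(-best$weights, seq_len(K))
  n_params <- (K - 1L) + 3L * K + 1L + (kind == "gmm_ri")
  ic <- information_criteria(best$loglik, n_params, n)
  assignments <- apply(best$resp[, ord, drop = FALSE], 1, which.max)
  sizes <- tabulate(assignments, K)
  if (any(sizes < 10))
    warning(sprintf("smallest class contains < 10 subjects (sizes: %s)",
                    paste(sizes, collapse = ", ")))
  structure(list(K = K, kind = kind, weights = best$weights[ord],
                 beta = best$beta[ord, , drop = FALSE],
                 sigma2 = best$sigma2, tau2 = best$tau2,
                 loglik = best$loglik, aic = ic$aic, bic = ic$bic,
                 n_params = n_params, n = n, T = TT,
                 loglik_trace = best$trace,
                 responsibilities = best$resp[, ord, drop = FALSE],
                 assignments = assignments,
                 iterations = best$iterations, converged = best$converged),
            class = "growth_mixture")
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf("Latent class model: K = %d, loglik %.2f, AIC %.1f, BIC %.1f\n",
              x$K, x$loglik, x$aic, x$bic))
  cat("  class weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.growth_mixture <- function(x, ...) {
  cat(sprintf("%s: K = %d, loglik %.2f, AIC %.1f, BIC %.1f\n",
              if (x$kind == "lcgm") "Latent class growth model"
              else "Growth mixture model (random intercept)",
              x$K, x$loglik, x$aic, x$bic))
  cat(sprintf("  sigma2 %.3f, tau2 %.3f; weights %s\n", x$sigma2, x$tau2,
              paste(sprintf("%.3f", x$weights), collapse = " ")))
  invisible(x)
}

#' Model comparison table over class counts
#'
#' Fits a sequence of models and tabulates free parameters, log-likelihood,
#' AIC and BIC, the layout used to compare competing class numbers.
#'
#' @param fits list of `lca_model` / `growth_mixture` objects.
#' @return data frame: model, K, k (free params), loglik, aic, bic.
#' @export
ic_comparison_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(model = if (inherits(f, "lca_model")) "LCM" else toupper(f$kind),
               K = f$K, k = f$n_params, loglik = f$loglik,
               aic = f$aic, bic = f$bic)
  }))
}
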