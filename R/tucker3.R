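#' @title Tucker3 three-mode principal component analysis
#' @description Fits the Tucker3 model
#'   \deqn{X_{ijk} = \sum_{p=1}^P \sum_{q=1}^Q \sum_{r=1}^R
#'         a_{ip} b_{jq} c_{kr} g_{pqr} + e_{ijk}}
#'   by alternating least squares with column-orthonormal component matrices
#'   A (n x P, persons), B (m x Q, symptoms), C (T x R, time points) and a
#'   free core array G (P x Q x R) describing how the three modes' components
#'   interact. The fit percentage is 100 (1 - SSE/SST) on the preprocessed
#'   cube.
#' @name tucker3
NULL

#' Mode-n matricization of a three-mode array
#'
#' Person-mode unfolding is n x (mT) with column index j + (t-1) m (items
#' fastest); the symptom- and time-mode unfoldings use the analogous
#' conventions (persons fastest).
#'
#' @param x n x m x T array.
#' @param mode `"person"`, `"symptom"`, or `"time"` (or 1, 2, 3).
#' @return the unfolded matrix.
#' @export
unfold_cube <- function(x, mode) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  mode <- match_mode(mode)
  d <- dim(x)
  switch(mode,
    `1` = { dim(x) <- c(d[1], d[2] * d[3]); x },
    `2` = { y <- aperm(x, c(2, 1, 3)); dim(y) <- c(d[2], d[1] * d[3]); y },
    `3` = { y <- aperm(x, c(3, 1, 2)); dim(y) <- c(d[3], d[1] * d[2]); y })
}

#' Inverse of [unfold_cube()]
#' @param mat unfolded matrix.
#' @param mode mode of the unfolding.
#' @param dims the original c(n, m, T).
#' @return the refolded array; `refold_cube(unfold_cube(x, mode), mode, dim(x))`
#'   is exactly `x`.
#' @export
refold_cube <- function(mat, mode, dims) {
  mode <- match_mode(mode)
  switch(mode,
    `1` = { dim(mat) <- dims; mat },
    `2` = { dim(mat) <- dims[c(2, 1, 3)]; aperm(mat, c(2, 1, 3)) },
    `3` = { dim(mat) <- dims[c(3, 1, 2)]; aperm(mat, c(2, 3, 1)) })
}

match_mode <- function(mode) {
  if (is.character(mode)) {
    mode <- match(match.arg(mode, c("person", "symptom", "time")),
                  c("person", "symptom", "time"))
  }
  if (!mode %in% 1:3)
    stop_hetcube("invalid mode token", class = "hetcube_invalid_input")
  as.character(mode)
}

#' Evaluate the Tucker3 model
#'
#' Computes the trilinear expansion
#' \eqn{\hat X_{ijk} = \sum_{p,q,r} A_{ip} B_{jq} C_{kr} G_{pqr}} through the
#' person-mode identity \eqn{\hat X_{(1)} = A G_{(1)} (C \otimes B)'}.
#'
#' @param A n x P person-mode matrix.
#' @param B m x Q symptom-mode matrix.
#' @param C T x R time-mode matrix.
#' @param G P x Q x R core array.
#' @return n x m x T array.
#' @export
tucker3_reconstruct <- function(A, B, C, G) {
  stopifnot(is.matrix(A), is.matrix(B), is.matrix(C),
            is.array(G), length(dim(G)) == 3L)
  dg <- dim(G)
  if (ncol(A) != dg[1] || ncol(B) != dg[2] || ncol(C) != dg[3])
    stop_hetcube("core dimensions %s do not match component columns (%d,%d,%d)",
                 paste(dg, collapse = "x"), ncol(A), ncol(B), ncol(C),
                 class = "hetcube_invalid_input")
  G1 <- unfold_cube(G, 1)
  X1 <- A %*% G1 %*% t(kronecker(C, B))
  refold_cube(X1, 1, c(nrow(A), nrow(B), nrow(C)))
}

#' Least-squares core array for given orthonormal loadings
#'
#' \eqn{G_{pqr} = \sum_{i,j,k} A_{ip} B_{jq} C_{kr} X_{ijk}}; by Parseval,
#' the core's sum of squares equals the fitted part's sum of squares.
#'
#' @param x cube array or `preprocessed_cube`.
#' @param A,B,C column-orthonormal component matrices.
#' @return P x Q x R core array.
#' @export
compute_core <- function(x, A, B, C) {
  x <- cube_values(x)
  for (M in list(A, B, C)) {
    if (max(abs(crossprod(M) - diag(ncol(M)))) > 1e-8)
      stop_hetcube("component matrix columns are not orthonormal",
                   class = "hetcube_invalid_input")
  }
  G1 <- crossprod(A, unfold_cube(x, 1)) %*% kronecker(C, B)
  refold_cube(G1, 1, c(ncol(A), ncol(B), ncol(C)))
}

cube_values <- function(x) {
  if (inherits(x, "preprocessed_cube")) x$values else x
}

#' Higher-order SVD initialization
#'
#' A, B, C are the leading left singular vectors of the person-, symptom- and
#' time-mode unfoldings; deterministic given the cube (column signs fixed so
#' the largest-magnitude entry is positive). If a mode asks for more
#' components than its unfolding's rank supports, the basis is completed with
#' deterministic orthonormal columns.
#'
#' @param x cube array or `preprocessed_cube`.
#' @param P,Q,R component counts per mode.
#' @return list with orthonormal A, B, C.
#' @export
hosvd_init <- function(x, P, Q, R) {
  x <- cube_values(x)
  d <- dim(x)
  check_components(d, P, Q, R)
  list(A = leading_lsv(unfold_cube(x, 1), P),
       B = leading_lsv(unfold_cube(x, 2), Q),
       C = leading_lsv(unfold_cube(x, 3), R))
}

check_components <- function(d, P, Q, R) {
  if (P > d[1] || Q > d[2] || R > d[3])
    stop_hetcube("component numbers (%d,%d,%d) exceed mode sizes (%s)",
                 P, Q, R, paste(d, collapse = ","),
                 class = "hetcube_invalid_input")
  if (P < 1 || Q < 1 || R < 1)
    stop_hetcube("component numbers must be at least 1",
                 class = "hetcube_invalid_input")
  invisible(TRUE)
}

# First k left singular vectors, orthonormally completed when the matrix has
# fewer than k columns/rank, with deterministic sign fixing.
leading_lsv <- function(M, k) {
  s <- svd(M, nu = min(k, min(dim(M))))
  U <- s$u
  if (ncol(U) < k) U <- complete_basis(U, k)
  fix_column_signs(U)
}

complete_basis <- function(U, k) {
  n <- nrow(U)
  Q <- qr.Q(qr(cbind(U, diag(n))))[, seq_len(k), drop = FALSE]
  # keep the original leading columns exactly
  Q[, seq_len(ncol(U))] <- U
  Q
}

fix_column_signs <- function(M) {
  s <- apply(M, 2, function(col) sign(col[which.max(abs(col))]))
  s[s == 0] <- 1
  sweep(M, 2, s, "*")
}

#' Fit percentage of a model on a (preprocessed) cube
#'
#' @param x cube array or `preprocessed_cube`.
#' @param model a `tucker3` model or an array approximation of `x`.
#' @return list with `sse`, `sst`, `fit_percent` = 100 (1 - sse/sst).
#' @export
fit_percentage <- function(x, model) {
  x <- cube_values(x)
  xhat <- if (inherits(model, "tucker3"))
    tucker3_reconstruct(model$A, model$B, model$C, model$G) else model
  if (!identical(dim(xhat), dim(x)))
    stop_hetcube("model and cube shapes differ", class = "hetcube_invalid_input")
  sst <- sum(x^2)
  if (sst == 0)
    stop_hetcube("all-zero cube: fit percentage undefined",
                 class = "hetcube_degenerate_input")
  sse <- sum((x - xhat)^2)
  list(sse = sse, sst = sst, fit_percent = 100 * (1 - sse / sst))
}

#' Fit a Tucker3 model by alternating least squares
#'
#' Runs higher-order orthogonal iteration: each sweep replaces one mode's
#' loadings with the leading left singular vectors of the data projected on
#' the other two modes' current loadings, which never decreases the explained
#' sum of squares. The best solution over `n_starts` starts is returned; the
#' HOSVD start is always included, the remaining starts are random orthonormal
#' bases drawn from seeded sub-streams. Columns are sign-fixed
#' (largest-magnitude entry positive, flips absorbed into the core) and
#' ordered by descending explained sum of squares, so refits are reproducible.
#'
#' @param x cube array or `preprocessed_cube`.
#' @param P,Q,R number of components for the person, symptom and time mode.
#' @param tol convergence threshold on the relative fit change per sweep.
#' @param max_iter maximum ALS sweeps per start.
#' @param n_starts number of initializations (HOSVD + n_starts - 1 random).
#' @param seed master seed for the random starts.
#' @param extra_starts optional list of additional `list(A, B, C)` starts
#'   (used by the grid search to warm-start from nested solutions).
#' @return a `tucker3` object: components `A`, `B`, `C`, core `G`,
#'   `fit_percent`, `sse`, `sst`, `iterations`, `converged`, `fit_trace`.
#' @export
fit_tucker3 <- function(x, P, Q, R, tol = 1e-8, max_iter = 500L,
                        n_starts = 5L, seed = 1L, extra_starts = NULL) {
  xv <- cube_values(x)
  if (any(!is.finite(xv)))
    stop_hetcube("cube contains non-finite values", class = "hetcube_invalid_input")
  d <- dim(xv)
  check_components(d, P, Q, R)
  sst <- sum(xv^2)
  if (sst == 0)
    stop_hetcube("all-zero cube", class = "hetcube_degenerate_input")

  X1 <- unfold_cube(xv, 1); X2 <- unfold_cube(xv, 2); X3 <- unfold_cube(xv, 3)

  starts <- list(hosvd_init(xv, P, Q, R))
  if (n_starts > 1L) {
    for (s in seq_len(n_starts - 1L)) {
      set.seed(derive_seed(seed, s))
      starts[[length(starts) + 1L]] <- list(
        A = rand_orth(d[1], P), B = rand_orth(d[2], Q), C = rand_orth(d[3], R))
    }
  }
  for (st in extra_starts %||% list()) starts[[length(starts) + 1L]] <- st

  best <- NULL
  for (st in starts) {
    res <- als_run(X1, X2, X3, d, st$A, st$B, st$C, sst, tol, max_iter)
    if (is.null(best) || res$fit_percent > best$fit_percent) best <- res
  }

  G <- compute_core(xv, best$A, best$B, best$C)
  out <- canonicalize_tucker3(best$A, best$B, best$C, G)
  model <- structure(list(
    A = label_rows(out$A, dimnames(xv)[[1]], "P"),
    B = label_rows(out$B, dimnames(xv)[[2]], "Q"),
    C = label_rows(out$C, dimnames(xv)[[3]], "R"),
    G = out$G,
    fit_percent = best$fit_percent,
    sse = sst * (1 - best$fit_percent / 100), sst = sst,
    iterations = best$iterations, converged = best$converged,
    fit_trace = best$fit_trace,
    components = c(P = P, Q = Q, R = R), dim = d), class = "tucker3")
  model
}

label_rows <- function(M, labels, prefix) {
  dimnames(M) <- list(labels, paste0(prefix, seq_len(ncol(M))))
  M
}

rand_orth <- function(n, k) {
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
}

# One ALS run from a given start. Fit is tracked from the singular values of
# the last mode update (||G||^2 = sum of the leading R squared singular values
# of X3 (B x A)), avoiding a separate core computation per sweep.
als_run <- function(X1, X2, X3, d, A, B, C, sst, tol, max_iter) {
  P <- ncol(A); Q <- ncol(B); R <- ncol(C)
  ssfit <- function(A, B, C) {
    G1 <- crossprod(A, X1) %*% kronecker(C, B)
    sum(G1^2)
  }
  fit0 <- 100 * ssfit(A, B, C) / sst
  trace <- fit0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    A <- leading_lsv(X1 %*% kronecker(C, B), P)
    B <- leading_lsv(X2 %*% kronecker(C, A), Q)
    MC <- X3 %*% kronecker(B, A)
    sv <- svd(MC, nu = min(R, min(dim(MC))))
    C <- if (ncol(sv$u) < R) fix_column_signs(complete_basis(sv$u, R)) else
      fix_column_signs(sv$u)
    ss <- sum(sv$d[seq_len(min(R, length(sv$d)))]^2)
    fit <- 100 * ss / sst
    trace <- c(trace, fit)
    if (abs(fit - trace[length(trace) - 1L]) < tol * max(trace[length(trace) - 1L], 1)) {
      converged <- TRUE
      break
    }
  }
  list(A = A, B = B, C = C, fit_percent = trace[length(trace)],
       iterations = iter, converged = converged, fit_trace = trace)
}

# Sign-fix columns (flips absorbed into G) and order components within each
# mode by descending explained SS (core slice SS), ties by original index.
canonicalize_tucker3 <- function(A, B, C, G) {
  flip <- function(M, G, mode) {
    s <- apply(M, 2, function(col) { v <- sign(col[which.max(abs(col))]); if (v == 0) 1 else v })
    M <- sweep(M, 2, s, "*")
    Gm <- unfold_cube(G, mode)
    Gm <- sweep(Gm, 1, s, "*")
    list(M = M, G = refold_cube(Gm, mode, dim(G)))
  }
  reorder1 <- function(M, G, mode) {
    Gm <- unfold_cube(G, mode)
    ss <- rowSums(Gm^2)
    ord <- order(-ss, seq_along(ss))
    Gm <- Gm[ord, , drop = FALSE]
    list(M = M[, ord, drop = FALSE], G = refold_cube(Gm, mode, dim(G)))
  }
  for (mode in 1:3) {
    M <- list(A, B, C)[[mode]]
    r <- reorder1(M, G, mode)
    f <- flip(r$M, r$G, mode)
    G <- f$G
    if (mode == 1) A <- f$M else if (mode == 2) B <- f$M else C <- f$M
  }
  list(A = A, B = B, C = C, G = G)
}

#' @export
print.tucker3 <- function(x, ...) {
  cat(sprintf("Tucker3 model (%d,%d,%d) on a %s cube\n",
              x$components[1], x$components[2], x$components[3],
              paste(x$dim, collapse = " x ")))
  cat(sprintf("  fit: %.2f%%  (SSE %.4g / SST %.4g), %d ALS sweeps%s\n",
              x$fit_percent, x$sse, x$sst, x$iterations,
              if (x$converged) ", converged" else " (max_iter reached)"))
  invisible(x)
}
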