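#' @title Fit-percentage grid and component-number selection
#' @description Computes Tucker3 fit percentages over a grid of component
#'   combinations (P, Q, R) and selects a parsimonious model by trading fit
#'   against the number of free parameters.
#' @name model_selection
NULL

#' Free parameters of a Tucker3 model
#'
#' n P + m Q + T R + P Q R - P^2 - Q^2 - R^2: the loading and core entries
#' minus the rotational indeterminacy absorbed by the orthonormality
#' constraints on each mode.
#'
#' @param n,m,T mode sizes. @param P,Q,R component counts.
#' @return integer free-parameter count.
#' @export
tucker3_free_params <- function(n, m, T, P, Q, R) {
  n * P + m * Q + T * R + P * Q * R - P^2 - Q^2 - R^2
}

#' Fit the Tucker3 model over a grid of component combinations
#'
#' Fits every (P, Q, R) with P <= max_P, Q <= max_Q, R <= max_R. Each cell's
#' start set contains the HOSVD start plus the zero-padded best solution of
#' every coordinate-wise smaller neighbour, which guarantees the grid's fit
#' percentages are non-decreasing along each coordinate. Grid cells use a
#' lighter convergence setting than a final single fit (`tol`, `max_iter`
#' below); refit the selected combination with [fit_tucker3()] defaults for
#' the reported model.
#'
#' @param x cube array or `preprocessed_cube`.
#' @param max_P,max_Q,max_R upper bounds per mode.
#' @param tol,max_iter ALS settings per cell.
#' @param seed master seed (random starts are not used in grid cells, but the
#'   seed is threaded through for reproducibility of any future options).
#' @return a `fit_grid` data frame: columns P, Q, R, fit_percent, free_params,
#'   with attributes `dim` and `models` (the fitted loadings per cell).
#' @export
grid_search <- function(x, max_P, max_Q, max_R, tol = 1e-6, max_iter = 200L,
                        seed = 1L) {
  xv <- cube_values(x)
  d <- dim(xv)
  check_components(d, max_P, max_Q, max_R)
  combos <- expand.grid(P = seq_len(max_P), Q = seq_len(max_Q), R = seq_len(max_R))
  combos <- combos[order(combos$P + combos$Q + combos$R, combos$P, combos$Q, combos$R), ]
  models <- list()
  key <- function(P, Q, R) paste(P, Q, R, sep = ",")
  rows <- vector("list", nrow(combos))
  for (ii in seq_len(nrow(combos))) {
    P <- combos$P[ii]; Q <- combos$Q[ii]; R <- combos$R[ii]
    extra <- list()
    for (nb in list(c(P - 1, Q, R), c(P, Q - 1, R), c(P, Q, R - 1))) {
      if (all(nb >= 1)) {
        prev <- models[[key(nb[1], nb[2], nb[3])]]
        extra[[length(extra) + 1L]] <- list(
          A = pad_orth(prev$A, P), B = pad_orth(prev$B, Q), C = pad_orth(prev$C, R))
      }
    }
    fit <- fit_tucker3(xv, P, Q, R, tol = tol, max_iter = max_iter,
                       n_starts = 1L, seed = seed, extra_starts = extra)
    models[[key(P, Q, R)]] <- fit
    rows[[ii]] <- data.frame(P = P, Q = Q, R = R,
                             fit_percent = fit$fit_percent,
                             free_params = tucker3_free_params(d[1], d[2], d[3], P, Q, R))
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  structure(grid, dim_cube = d, models = models,
            class = c("fit_grid", "data.frame"))
}

# Pad an orthonormal matrix to k columns with deterministic orthonormal
# complements (zero-padded warm start for the nested grid).
pad_orth <- function(M, k) {
  if (ncol(M) >= k) return(M[, seq_len(k), drop = FALSE])
  complete_basis(M, k)
}

#' Select component numbers from a fit grid by the elbow rule
#'
#' Returns the smallest model (by total component count, then
#' lexicographically) whose fit cannot be raised by at least
#' `min_gain_percent` fit-percentage points per added component by any
#' expansion of at most one component per mode. Expansions must be judged
#' jointly, not one mode at a time: a Tucker3 mode's effective rank is capped
#' by the product of the other two modes' component numbers, so e.g. a
#' (2,1,1) model always fits exactly like (1,1,1) and single-mode steps alone
#' would never leave the smallest model. This makes the informal "fit
#' percentage versus number of parameters" trade-off reproducible; the full
#' grid is always available for alternative rules.
#'
#' @param grid a `fit_grid`.
#' @param min_gain_percent elbow threshold in fit-percentage points per
#'   added component (default 1.0).
#' @return list with `selected` = c(P, Q, R), `fit_percent`, `free_params`,
#'   and `candidates`: all grid rows satisfying the rule, best first.
#' @export
select_model <- function(grid, min_gain_percent = 1.0) {
  stopifnot(inherits(grid, "data.frame"), nrow(grid) >= 1L)
  g <- as.data.frame(grid)
  fit_at <- function(P, Q, R) {
    i <- which(g$P == P & g$Q == Q & g$R == R)
    if (length(i)) g$fit_percent[i[1]] else NA_real_
  }
  steps <- expand.grid(dP = 0:1, dQ = 0:1, dR = 0:1)
  steps <- steps[rowSums(steps) > 0, ]
  ok <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    P <- g$P[i]; Q <- g$Q[i]; R <- g$R[i]; f <- g$fit_percent[i]
    gains <- mapply(function(dP, dQ, dR)
      (fit_at(P + dP, Q + dQ, R + dR) - f) / (dP + dQ + dR),
      steps$dP, steps$dQ, steps$dR)
    ok[i] <- all(is.na(gains) | gains < min_gain_percent)
  }
  cand <- g[ok, , drop = FALSE]
  if (!nrow(cand))
    stop_hetcube("no grid entry satisfies the elbow rule; enlarge the grid",
                 class = "hetcube_invalid_input")
  cand <- cand[order(cand$P + cand$Q + cand$R, cand$P, cand$Q, cand$R), , drop = FALSE]
  list(selected = c(P = cand$P[1], Q = cand$Q[1], R = cand$R[1]),
       fit_percent = cand$fit_percent[1], free_params = cand$free_params[1],
       candidates = cand)
}
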