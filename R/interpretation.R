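#' @title Component interpretation tables
#' @description Turns fitted component matrices and the core array into the
#'   tables used to read a three-mode solution: per-entity component scores
#'   with an assignment to the dominant component, the labeled core-array
#'   interaction table, and a congruence-based matcher for recovery studies.
#' @name interpretation
NULL

#' Assign each entity to its dominant component
#'
#' Each row (item, time point, or person) is assigned to the component on
#' which it has the largest absolute score — the rule behind boldfacing in
#' component-score tables. Near-ties (absolute gap below `tie_tol`) and
#' negative dominant scores are flagged so borderline or sign-reversed
#' assignments are visible.
#'
#' @param loadings numeric matrix of component scores (rows = entities).
#' @param labels optional row labels.
#' @param tie_tol flag threshold on the gap between the top two absolute
#'   scores (default 0.05).
#' @return data frame: entity, one column per component, `assigned`,
#'   `negative` (dominant score < 0), `tie` (gap below `tie_tol`).
#' @export
assign_components <- function(loadings, labels = NULL, tie_tol = 0.05) {
  stopifnot(is.matrix(loadings), nrow(loadings) >= 1L)
  if (any(!is.finite(loadings)))
    stop_hetcube("non-finite loadings", class = "hetcube_invalid_input")
  labels <- labels %||% rownames(loadings) %||% as.character(seq_len(nrow(loadings)))
  k <- ncol(loadings)
  a <- apply(abs(loadings), 1, which.max)   # ties -> lowest index
  gap <- apply(abs(loadings), 1, function(v) {
    s <- sort(v, decreasing = TRUE)
    if (length(s) > 1) s[1] - s[2] else Inf
  })
  out <- data.frame(entity = labels, stringsAsFactors = FALSE)
  scores <- as.data.frame(loadings)
  names(scores) <- colnames(loadings) %||% paste0("comp", seq_len(k))
  out <- cbind(out, scores)
  out$assigned <- a
  out$negative <- loadings[cbind(seq_len(nrow(loadings)), a)] < 0
  out$tie <- gap < tie_tol
  rownames(out) <- NULL
  out
}

#' Long-format labeled core-array table
#'
#' One row per (person component, symptom component, time component) cell of
#' the core array G — the interactions that integrate the three modes.
#' Ordered person-component major; a (3,2,2) model yields 12 rows.
#'
#' @param model a `tucker3` model.
#' @param person_labels,symptom_labels,time_labels optional narrative
#'   component labels (user-supplied strings; never inferred).
#' @return data frame: person_component, symptom_component, time_component,
#'   core (values equal G entries exactly).
#' @export
core_table <- function(model, person_labels = NULL, symptom_labels = NULL,
                       time_labels = NULL) {
  stopifnot(inherits(model, "tucker3"))
  G <- model$G
  d <- dim(G)
  idx <- expand.grid(r = seq_len(d[3]), q = seq_len(d[2]), p = seq_len(d[1]))
  idx <- idx[, c("p", "q", "r")]
  lab <- function(i, labs, k) if (is.null(labs)) i else paste0(i, ": ", labs[i])
  out <- data.frame(
    person_component = lab(idx$p, person_labels),
    symptom_component = lab(idx$q, symptom_labels),
    time_component = lab(idx$r, time_labels),
    core = G[cbind(idx$p, idx$q, idx$r)])
  rownames(out) <- NULL
  out
}

#' Rebuild the core array from a core table
#' @param tab output of [core_table()] built without narrative labels.
#' @return P x Q x R array, bit-identical to the model core.
#' @export
core_from_table <- function(tab) {
  p <- as.integer(sub(":.*", "", tab$person_component))
  q <- as.integer(sub(":.*", "", tab$symptom_component))
  r <- as.integer(sub(":.*", "", tab$time_component))
  G <- array(0, dim = c(max(p), max(q), max(r)))
  G[cbind(p, q, r)] <- tab$core
  G
}

#' Tucker congruence coefficient between two vectors
#'
#' \eqn{\phi(x, y) = \sum x y / \sqrt{\sum x^2 \sum y^2}}: the cosine between
#' two loading vectors, the standard factor-recovery metric.
#'
#' @param x,y numeric vectors of equal length.
#' @return phi in [-1, 1].
#' @export
tucker_congruence <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop_hetcube("zero-norm column in congruence computation",
                 class = "hetcube_invalid_input")
  sum(x * y) / (nx * ny)
}

#' Match estimated components to reference components
#'
#' Greedy maximum-|phi| assignment of estimated columns to reference columns.
#' Components are sign- and order-indeterminate, so matching quality is read
#' from |phi|; the signed phi is reported per matched pair.
#'
#' @param estimated,reference matrices with equal dimensions.
#' @return list: `permutation` (for each reference column, the matched
#'   estimated column), `phi` (signed congruences, reference order),
#'   `mean_abs_phi`.
#' @export
match_components <- function(estimated, reference) {
  stopifnot(is.matrix(estimated), is.matrix(reference),
            nrow(estimated) == nrow(reference),
            ncol(estimated) == ncol(reference))
  k <- ncol(reference)
  phi_mat <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    phi_mat[i, j] <- tucker_congruence(reference[, i], estimated[, j])
  perm <- integer(k); phi <- numeric(k)
  avail_ref <- seq_len(k); avail_est <- seq_len(k)
  for (step in seq_len(k)) {
    sub <- abs(phi_mat[avail_ref, avail_est, drop = FALSE])
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    i <- avail_ref[w[1]]; j <- avail_est[w[2]]
    perm[i] <- j; phi[i] <- phi_mat[i, j]
    avail_ref <- setdiff(avail_ref, i); avail_est <- setdiff(avail_est, j)
  }
  list(permutation = perm, phi = phi, mean_abs_phi = mean(abs(phi)))
}
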