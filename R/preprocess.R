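#' @title Fiber centering and slab normalization
#' @description Standard three-way preprocessing applied before the Tucker3
#'   fit. Centering across the person mode within every (item, time) fiber
#'   removes the mean trajectory each symptom shares across patients, so the
#'   decomposition models heterogeneity up-and-above the general mean trend.
#'   Normalization rescales every item slab to mean square one so that
#'   high-variance symptoms do not dominate the least-squares fit.
#' @name preprocess
NULL

#' Center every (item, time) fiber across persons
#'
#' @param cube n x m x T numeric array.
#' @return list with `values` (centered array) and `offsets` (m x T matrix of
#'   removed fiber means). Idempotent: centering a centered cube changes
#'   nothing and returns zero offsets.
#' @export
center_fibers <- function(cube) {
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  if (any(!is.finite(cube)))
    stop_hetcube("cube contains non-finite values", class = "hetcube_invalid_input")
  offsets <- apply(cube, c(2, 3), mean)
  centered <- sweep(cube, c(2, 3), offsets, "-")
  dimnames(centered) <- dimnames(cube)
  list(values = centered, offsets = offsets)
}

#' Rescale item slabs to mean square one
#'
#' Each item's n x T slab is divided by its root mean square, so afterwards
#' every slab satisfies sum of squares = n*T and the full array has total sum
#' of squares n*m*T (the denominator base for fit percentages).
#'
#' @param centered n x m x T array, already fiber-centered.
#' @return list with `values` and `scales` (length-m positive vector).
#' @export
normalize_slabs <- function(centered) {
  stopifnot(is.array(centered), length(dim(centered)) == 3L)
  d <- dim(centered)
  ms <- apply(centered^2, 2, mean)          # per-item mean square over (i,t)
  if (any(ms <= 0)) {
    bad <- dimnames(centered)[[2]][which(ms <= 0)] %||% which(ms <= 0)
    stop_hetcube("degenerate item slab (zero variance): %s",
                 paste(bad, collapse = ", "), class = "hetcube_degenerate_item")
  }
  scales <- sqrt(ms)
  values <- sweep(centered, 2, scales, "/")
  dimnames(values) <- dimnames(centered)
  list(values = values, scales = scales)
}

#' Preprocess a data cube for the Tucker3 fit
#'
#' @param cube a `data_cube` or plain 3-d array.
#' @param center center (item, time) fibers across persons (default TRUE).
#' @param normalize `"item_slab"` (default) scales item slabs to mean square
#'   one; `"none"` skips scaling.
#' @return a `preprocessed_cube`: list with `values`, `offsets` (m x T),
#'   `scales` (length m), `dim`, and `dimnames`.
#' @export
preprocess_cube <- function(cube, center = TRUE,
                            normalize = c("item_slab", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  d <- dim(cube)
  offsets <- matrix(0, d[2], d[3])
  scales <- rep(1, d[2])
  values <- cube
  if (center) {
    cf <- center_fibers(cube)
    values <- cf$values
    offsets <- cf$offsets
  }
  if (normalize == "item_slab") {
    ns <- normalize_slabs(values)
    values <- ns$values
    scales <- ns$scales
  }
  structure(list(values = values, offsets = offsets, scales = scales,
                 dim = d, dimnames = dimnames(cube)),
            class = "preprocessed_cube")
}

#' Map an approximation back to the original score scale
#'
#' Applies the inverse affine transform (multiply by item scales, add fiber
#' offsets). `inverse_transform(pre, pre$values)` restores the source cube.
#'
#' @param pre a `preprocessed_cube`.
#' @param approx n x m x T array on the preprocessed scale.
#' @return array on the original scale.
#' @export
inverse_transform <- function(pre, approx) {
  stopifnot(inherits(pre, "preprocessed_cube"))
  if (!identical(dim(approx), pre$dim))
    stop_hetcube("shape mismatch: approx is %s, cube is %s",
                 paste(dim(approx), collapse = "x"),
                 paste(pre$dim, collapse = "x"),
                 class = "hetcube_invalid_input")
  out <- sweep(approx, 2, pre$scales, "*")
  out <- sweep(out, c(2, 3), pre$offsets, "+")
  dimnames(out) <- pre$dimnames
  out
}

#' @export
print.preprocessed_cube <- function(x, ...) {
  cat(sprintf("Preprocessed cube: %s (total SS %.4g)\n",
              paste(x$dim, collapse = " x "), sum(x$values^2)))
  invisible(x)
}
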