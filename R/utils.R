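#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages in the package draw their randomness from a single
#' master seed through this function, so that partial reruns of a pipeline
#' are consistent with full reruns.
#'
#' @param seed master integer seed.
#' @param counter non-negative integer identifying the sub-stream.
#' @return an integer seed strictly below 2^31.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  # multiplicative congruential step (Park-Miller modulus), counter-keyed
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) + 1
  ((s * 48271 + as.numeric(counter) * 9973) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hetcube <- function(fmt, ..., class) {
  stop(structure(class = c(class, "hetcube_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
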