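# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages draw their seeds from a single master seed through
#' this function, so that pipeline stages are independently reproducible and
#' permutation streams do not collide across analyses.
#'
#' @param seed master integer seed.
#' @param k stage index (any non-negative integer).
#' @return an integer seed < 2^31.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  as.integer((as.double(seed) + as.double(k) * 100003) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# empirical p-value convention: never 0, (1 + k) / (n + 1)
empirical_p <- function(k, n) (1 + k) / (n + 1)
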