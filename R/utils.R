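#' @keywords internal
"_PACKAGE"

#' Round half away from zero to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed disparity fractions use
#' the conventional half-up rule (e.g. 73/97 -> 75.26), so that rule is
#' implemented explicitly here.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a reproducible substream seed from a base seed
#'
#' A single user-facing seed fans out to independent per-component
#' substreams so that, e.g., adding noise genes to the expression matrix
#' does not perturb the survival-time draws. The derived seed is kept
#' strictly below 2^31 (R integers are 32-bit).
#'
#' @param seed base integer seed.
#' @param stream small non-negative integer identifying the component.
#' @return an integer seed usable with [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # multiplicative congruential step (Park-Miller constants), offset by stream
  s <- (abs(as.double(seed)) %% 2147483646) + 1
  s <- (s * 48271) %% 2147483647
  as.integer((s + 1000003 * (stream + 1)) %% 2147483647)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-precision numeric formatting so that write -> read round-trips
# finite doubles bit-identically
num_chr <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}
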