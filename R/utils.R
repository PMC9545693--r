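# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Presentation rounding for percentages. All internal computation is kept in
#' full precision; values are rounded half-up only when printed or compared
#' against published two-decimal figures (base `round()` rounds half to even,
#' which disagrees with how compendium reports print percentages).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(13.535, 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Derive a 32-bit sub-seed from a master seed and a stream label, so each
# simulation artifact (universe, names, severities, advice, ...) has its own
# reproducible stream and adding a stream never perturbs the others.
stream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes) * 131) %% 1e6
  as.integer((abs(seed) + h * 1009) %% 2147483046L)
}

with_stream <- function(seed, label, code) {
  withr::with_seed(stream_seed(seed, label), code)
}

# Locale-independent, case-insensitive total order on identifiers: rank by
# byte-wise (radix) sort of the lower-cased values, breaking exact-lowercase
# ties byte-wise on the original strings.
radix_rank <- function(x) {
  o <- order(tolower(x), x, method = "radix")
  r <- integer(length(x))
  r[o] <- seq_along(x)
  r
}

stopf <- function(class, fmt, ...) {
  rlang::abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
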