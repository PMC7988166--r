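#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero, unlike [round()], which
#' rounds half to even.  Used wherever a printed integer or fixed-decimal
#' value is reported (genotype expectations, allele frequencies,
#' mortality percentages).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_up(2.5)   # 3, where round(2.5) gives 2
#' round_half_up(0.0425, 3)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive an independent 31-bit substream seed from a global seed and a
# stream label, so every stochastic operation in a run is reproducible yet
# decoupled from the others.  Linear congruential step (Park-Miller
# modulus) keeps results inside R's integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  salt <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + salt * 16807) %% 2147483647)
}

# Stop with a formatted message, without the call in the condition.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Emit a key=value log line (machine-parseable, see run logs).
log_kv <- function(key, value, verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf("%s=%s", key, paste(value, collapse = ",")))
  invisible(NULL)
}
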