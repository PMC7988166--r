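#' Genotype counts at a biallelic site
#'
#' A (hom-reference, heterozygote, hom-risk) triple, the input to the
#' allele-frequency, Hardy-Weinberg and segregation tests.
#'
#' @param n_rr count of reference homozygotes.
#' @param n_rv count of heterozygotes.
#' @param n_vv count of risk-allele homozygotes.
#' @return object of class `genotype_counts`.
#' @examples
#' genotype_counts(946, 191, 0)
#' @export
genotype_counts <- function(n_rr, n_rv, n_vv) {
  x <- c(n_rr = n_rr, n_rv = n_rv, n_vv = n_vv)
  if (anyNA(x) || any(x < 0) || any(x != floor(x)))
    abort("genotype counts must be non-negative integers")
  structure(as.list(x), class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype_counts: %d/%d/%d (N = %d)\n",
              x$n_rr, x$n_rv, x$n_vv, x$n_rr + x$n_rv + x$n_vv))
  invisible(x)
}

# Accept a genotype_counts object or a bare length-3 vector.
as_counts <- function(counts) {
  if (inherits(counts, "genotype_counts")) return(counts)
  if (is.numeric(counts) && length(counts) == 3L)
    return(genotype_counts(counts[1L], counts[2L], counts[3L]))
  abort("expected a genotype_counts object or a length-3 numeric vector")
}

counts_n <- function(c) c$n_rr + c$n_rv + c$n_vv

#' Risk-allele frequency from genotype counts
#'
#' `(n_rv + 2 n_vv) / 2N`, optionally rounded half away from zero the way
#' frequencies are printed in candidate tables.
#'
#' @param counts [genotype_counts()] or length-3 vector (rr, rv, vv).
#' @param decimals decimal places for the returned value; `NULL` for the
#'   unrounded frequency.
#' @return risk-allele frequency in \[0, 1\].
#' @examples
#' allele_frequency(c(473, 44, 0))   # 0.043
#' @export
allele_frequency <- function(counts, decimals = 3) {
  counts <- as_counts(counts)
  N <- counts_n(counts)
  if (N == 0) abort("allele_frequency undefined for N = 0")
  f <- (counts$n_rv + 2 * counts$n_vv) / (2 * N)
  if (is.null(decimals)) f else round_half_up(f, decimals)
}

#' Hardy-Weinberg expected genotype counts
#'
#' Expected (hom-ref, het, hom-risk) counts under random mating at the
#' observed allele frequency: `N(1-p)^2, 2Np(1-p), Np^2`, with p taken
#' unrounded from the counts.  The integer triple uses largest-remainder
#' (sum-preserving) rounding, the convention of published genotype
#' tables, whose expected triples always total N; remainder ties go to
#' the smaller class, where the relative rounding error is larger.
#'
#' @inheritParams allele_frequency
#' @return list with `expected` (unrounded numeric triple), `rounded`
#'   (largest-remainder integer triple summing to N) and `p`
#'   (risk-allele frequency).
#' @examples
#' hwe_expected(c(435, 82, 0))$rounded  # 438 76 3
#' @export
hwe_expected <- function(counts) {
  counts <- as_counts(counts)
  N <- counts_n(counts)
  if (N == 0) abort("hwe_expected undefined for N = 0")
  p <- allele_frequency(counts, decimals = NULL)
  e <- c(e_rr = N * (1 - p)^2, e_rv = 2 * N * p * (1 - p), e_vv = N * p^2)
  f <- floor(e)
  short <- N - sum(f)
  if (short > 0) {
    # remainders compared at 9 decimals so that mathematically tied
    # fractional parts (computed along different float paths) tie exactly
    idx <- order(round(e - f, 9), -e, decreasing = TRUE)[seq_len(short)]
    f[idx] <- f[idx] + 1
  }
  list(expected = e, rounded = setNames(as.integer(f), names(f)), p = p)
}

#' Chi-square test for Hardy-Weinberg homozygote deficit
#'
#' Goodness of fit of the observed genotype triple against its
#' Hardy-Weinberg expectation.  The default single degree of freedom
#' reflects the one free genotype dimension after estimating the allele
#' frequency from the same counts.
#'
#' @inheritParams allele_frequency
#' @param df degrees of freedom for the reference distribution.
#' @return list with `chi2`, `p`, `expected` (unrounded triple).
#' @examples
#' hwe_deficit_chisq(c(946, 191, 0))  # chi2 ~ 9.56, p ~ 0.002
#' @export
hwe_deficit_chisq <- function(counts, df = 1) {
  counts <- as_counts(counts)
  e <- hwe_expected(counts)$expected
  if (any(e <= 0))
    abort("an expected genotype class is zero; use homozygote_absence_binomial() instead")
  o <- c(counts$n_rr, counts$n_rv, counts$n_vv)
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, df = df, lower.tail = FALSE), expected = e)
}

#' One-sided binomial probability of observing no risk homozygotes
#'
#' Companion test for sites where the expected homozygote class is too
#' small for the chi-square: the probability that none of N random-mating
#' individuals is homozygous, `(1 - f^2)^N`, at the unrounded risk-allele
#' frequency f.
#'
#' @inheritParams allele_frequency
#' @return probability in \[0, 1\].
#' @export
homozygote_absence_binomial <- function(counts) {
  counts <- as_counts(counts)
  N <- counts_n(counts)
  if (N == 0) abort("undefined for N = 0")
  f <- allele_frequency(counts, decimals = NULL)
  (1 - f^2)^N
}

#' Segregation test against a Mendelian ratio
#'
#' Chi-square goodness of fit of observed genotype counts (typically
#' embryos from carrier x carrier matings) against an expected ratio,
#' 1:2:1 by default.
#'
#' @inheritParams allele_frequency
#' @param ratio expected genotype ratio (length 3).
#' @param df degrees of freedom.
#' @return list with `expected` triple, `chi2`, `p`.
#' @examples
#' segregation_test(c(7, 27, 0))  # expected 8.5/17/8.5, p ~ 1e-4
#' @export
segregation_test <- function(counts, ratio = c(1, 2, 1), df = 1) {
  counts <- as_counts(counts)
  N <- counts_n(counts)
  if (N == 0) abort("segregation_test undefined for N = 0")
  e <- N * ratio / sum(ratio)
  o <- c(counts$n_rr, counts$n_rv, counts$n_vv)
  chi2 <- sum((o - e)^2 / e)
  list(expected = e, chi2 = chi2, p = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Genotype concordance rate between two call sets
#'
#' Percentage of matching genotype calls between two matrices sharing
#' sample/marker keys (e.g. array vs sequencing calls); entries missing in
#' either matrix are excluded from numerator and denominator.
#'
#' @param calls_a,calls_b matrices (samples x markers) of genotype codes;
#'   `NA` marks a missing call.  Dimnames, when present on both, are used
#'   to align the matrices.
#' @return concordance percentage in \[0, 100\].
#' @export
concordance_rate <- function(calls_a, calls_b) {
  if (!is.null(dimnames(calls_a)) && !is.null(dimnames(calls_b))) {
    rs <- intersect(rownames(calls_a), rownames(calls_b))
    cs <- intersect(colnames(calls_a), colnames(calls_b))
    if (!length(rs) || !length(cs)) abort("matrices share no sample/marker keys")
    calls_a <- calls_a[rs, cs, drop = FALSE]
    calls_b <- calls_b[rs, cs, drop = FALSE]
  }
  if (!all(dim(calls_a) == dim(calls_b)))
    abort("call matrices must have matching dimensions")
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(ok)) abort("no comparable (jointly non-missing) calls")
  100 * sum(calls_a[ok] == calls_b[ok]) / sum(ok)
}
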