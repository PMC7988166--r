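# Shared fixtures and independent oracles for the test suite.

# Six-sample, five-marker panel whose first two markers form the
# hand-countable diplotypes (11|00) x3, (00|00), (00|01), (01|00).
tiny_panel <- function() {
  H <- rbind(
    c(1, 1, 0, 0, 1),  # s1 hap1
    c(0, 0, 0, 0, 0),  # s1 hap2
    c(1, 1, 0, 1, 0),  # s2 hap1
    c(0, 0, 0, 0, 0),  # s2 hap2
    c(1, 1, 1, 0, 0),  # s3 hap1
    c(0, 0, 0, 0, 1),  # s3 hap2
    c(0, 0, 0, 0, 0),  # s4 hap1
    c(0, 0, 1, 0, 0),  # s4 hap2
    c(0, 0, 0, 1, 0),  # s5 hap1
    c(0, 1, 0, 0, 0),  # s5 hap2
    c(0, 1, 1, 0, 1),  # s6 hap1
    c(0, 0, 0, 0, 0))  # s6 hap2
  phased_panel(H,
               data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L),
                          id = paste0("m", 1:5)),
               paste0("s", 1:6))
}

# Random small panel for property loops (marker-independent alleles).
random_panel <- function(n_samples, n_markers, seed, n_chrom = 1) {
  set.seed(seed)
  H <- matrix(rbinom(2 * n_samples * n_markers * n_chrom, 1, 0.5),
              nrow = 2 * n_samples)
  phased_panel(H,
               data.frame(chrom = rep(as.character(seq_len(n_chrom)), each = n_markers),
                          pos = rep(100L * seq_len(n_markers), n_chrom),
                          id = sprintf("m%d", seq_len(n_markers * n_chrom))),
               sprintf("s%d", seq_len(n_samples)))
}

# Independent brute-force oracle for haplotype counting: explicit
# character-by-character string building and per-sample comparison,
# sharing no code with the package implementation.
oracle_haplotype_counts <- function(panel, chrom, start_marker, k) {
  cols <- which(panel$markers$chrom == chrom)[start_marker:(start_marker + k - 1)]
  n <- length(panel$samples)
  strings <- character(2 * n)
  for (r in seq_len(2 * n)) {
    s <- ""
    for (j in cols) s <- paste0(s, panel$haplotypes[r, j])
    strings[r] <- s
  }
  haps <- sort(unique(strings))
  res <- data.frame(hap = haps, copies = 0L, carriers = 0L, homozygotes = 0L)
  for (i in seq_len(n)) {
    h1 <- strings[2 * i - 1]; h2 <- strings[2 * i]
    for (hi in seq_along(haps)) {
      h <- haps[hi]
      ncop <- (h1 == h) + (h2 == h)
      res$copies[hi] <- res$copies[hi] + ncop
      if (ncop >= 1) res$carriers[hi] <- res$carriers[hi] + 1L
      if (ncop == 2) res$homozygotes[hi] <- res$homozygotes[hi] + 1L
    }
  }
  res$q <- res$copies / (2 * n)
  res
}

# Mating records with exact group totals, for reconstructing printed
# 2x2 contingency tables (days chosen inside the requested bin).
records_from_counts <- function(bin_days, risk_nr, risk_ai, other_nr, other_ai) {
  n <- risk_nr + risk_ai + other_nr + other_ai
  data.frame(
    cow_id = sprintf("c%d", seq_len(n)),
    sire_id = sprintf("b%d", seq_len(n)),
    ai_date = "2015-06-01",
    days_to_2nd_ai = c(rep(NA_integer_, risk_nr), rep(bin_days, risk_ai),
                       rep(NA_integer_, other_nr), rep(bin_days, other_ai)),
    sire_carrier = c(rep(TRUE, risk_nr + risk_ai), rep(FALSE, other_nr + other_ai)),
    cow_carrier = c(rep(TRUE, risk_nr + risk_ai), rep(TRUE, other_nr + other_ai)))
}

# Dosage vector with exact genotype counts (for report-format checks).
dosages_with_counts <- function(n_rr, n_rv, n_vv, samples) {
  g <- c(rep(0L, n_rr), rep(1L, n_rv), rep(2L, n_vv))
  names(g) <- samples
  g
}
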