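#' Phased haplotype panel
#'
#' Container for phased biallelic genotypes: a marker map and, per sample,
#' two haplotype allele vectors coded 0 (reference) / 1 (alternate).
#' Haplotypes are stored as an integer matrix with two consecutive rows
#' per sample (sample i occupies rows 2i-1 and 2i), markers in columns.
#'
#' @param haplotypes integer matrix of 0/1 alleles, `2 * n_samples` rows
#'   (two per sample, consecutive) and one column per marker.
#' @param markers data.frame with columns `chrom`, `pos` (1-based bp,
#'   strictly increasing within chromosome) and `id`.
#' @param samples character vector of sample identifiers.
#' @return an object of class `phased_panel` with elements `haplotypes`,
#'   `markers`, `samples`.
#' @examples
#' H <- matrix(c(1,1, 1,1, 0,0, 0,1), nrow = 4, byrow = TRUE)
#' p <- phased_panel(H, data.frame(chrom = "1", pos = c(100L, 200L),
#'                                 id = c("m1", "m2")), c("s1", "s2"))
#' p
#' @export
phased_panel <- function(haplotypes, markers, samples) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != 2L * length(samples))
    abort("haplotype matrix must have two rows per sample (%d rows for %d samples)",
          nrow(haplotypes), length(samples))
  if (ncol(haplotypes) != nrow(markers))
    abort("haplotype matrix has %d markers but map has %d", ncol(haplotypes), nrow(markers))
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L)))
    abort("haplotype alleles must be 0/1 with no missing values")
  markers$chrom <- as.character(markers$chrom)
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      abort("marker positions must be strictly increasing within chromosome %s", ch)
  }
  structure(list(haplotypes = haplotypes, markers = markers,
                 samples = as.character(samples)),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("phased_panel: %d samples, %d markers on %d chromosome(s)\n",
              length(x$samples), nrow(x$markers), length(unique(x$markers$chrom))))
  invisible(x)
}

#' Number of samples in a phased panel
#' @param panel a [phased_panel()].
#' @return integer sample count.
#' @export
n_samples <- function(panel) length(panel$samples)

# Rows of the haplotype matrix belonging to sample index i (1-based).
sample_rows <- function(i) c(2L * i - 1L, 2L * i)

# Column indices of a chromosome's markers, in map order.
chrom_cols <- function(panel, chrom) which(panel$markers$chrom == as.character(chrom))

#' Haplotype allele strings over a marker window
#'
#' Collapse each haplotype's alleles over a window of consecutive markers
#' (on one chromosome) into a character string, e.g. `"0110"`.
#'
#' @param panel a [phased_panel()].
#' @param chrom chromosome of the window.
#' @param start_marker first marker (1-based index within the chromosome).
#' @param k window size in markers.
#' @return character vector of length `2 * n_samples(panel)`.
#' @export
window_strings <- function(panel, chrom, start_marker, k) {
  cols <- chrom_cols(panel, chrom)
  if (start_marker < 1L || start_marker + k - 1L > length(cols))
    abort("window [%d, %d) outside chromosome %s (%d markers)",
          start_marker, start_marker + k, chrom, length(cols))
  sub <- panel$haplotypes[, cols[start_marker:(start_marker + k - 1L)], drop = FALSE]
  apply(sub, 1L, paste, collapse = "")
}

#' Carriers of a haplotype string in a window
#'
#' @inheritParams window_strings
#' @param hap haplotype allele string (e.g. `"011"`).
#' @return character vector of sample ids carrying at least one copy.
#' @export
haplotype_carriers <- function(panel, chrom, start_marker, k, hap) {
  hs <- window_strings(panel, chrom, start_marker, k)
  hit <- hs == hap
  carrier <- hit[seq(1L, length(hs), by = 2L)] | hit[seq(2L, length(hs), by = 2L)]
  panel$samples[carrier]
}
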