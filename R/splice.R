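#' Extract splice donor and acceptor boundary sequences
#'
#' For every internal exon boundary of every transcript in a GTF, windows
#' are cut from the genome and oriented 5'->3' along the transcript
#' (minus-strand features are reverse-complemented):
#' * donor: last 6 exonic + first 6 intronic bases (12 bp; the
#'   intronic GT sits at window positions 7-8);
#' * acceptor: last 50 intronic + first 2 exonic bases (52 bp; the
#'   intronic AG sits at window positions 49-50).
#'
#' First and last exons contribute only their internal junction;
#' single-exon transcripts contribute none.  Identical boundaries shared
#' by several transcripts are collapsed to one by their genomic key
#' (contig, strand, junction coordinate), so counts are boundaries, not
#' transcript occurrences.  Windows running off a contig end are skipped
#' and counted.
#'
#' @param gtf path to a GTF file, or GTF text (1-based inclusive exon
#'   records with `gene_id`/`transcript_id` attributes).
#' @param genome path to a FASTA file, FASTA text, or a
#'   [Biostrings::DNAStringSet].
#' @return list of class `boundary_set` with `donor` and `acceptor`
#'   character vectors (uppercase), and `skipped` counts.
#' @export
extract_boundaries <- function(gtf, genome) {
  exons <- read_gtf_exons(gtf)
  dna <- load_genome(genome)
  widths <- setNames(Biostrings::width(dna), names(dna))
  missing <- setdiff(unique(exons$chrom), names(dna))
  if (length(missing))
    abort("GTF references sequences absent from the FASTA: %s",
          paste(missing, collapse = ", "))

  donor_key <- list(); acceptor_key <- list()
  skipped <- c(donor = 0L, acceptor = 0L)
  for (tx in split(exons, exons$transcript_id)) {
    if (nrow(tx) < 2L) next
    tx <- tx[order(tx$start), , drop = FALSE]
    chrom <- tx$chrom[1]; strand <- tx$strand[1]
    W <- widths[[chrom]]
    n <- nrow(tx)
    if (strand == "+") {
      # donors at exon ends 1..n-1; acceptors at exon starts 2..n
      for (j in seq_len(n - 1L)) {
        e <- tx$end[j]
        if (e - 5L >= 1L && e + 6L <= W)
          donor_key[[sprintf("%s:+:%d", chrom, e)]] <- c(chrom, e - 5L, e + 6L, "+")
        else skipped["donor"] <- skipped["donor"] + 1L
        s <- tx$start[j + 1L]
        if (s - 50L >= 1L && s + 1L <= W)
          acceptor_key[[sprintf("%s:+:%d", chrom, s)]] <- c(chrom, s - 50L, s + 1L, "+")
        else skipped["acceptor"] <- skipped["acceptor"] + 1L
      }
    } else {
      # transcript runs right-to-left: donors at exon starts 2..n,
      # acceptors at exon ends 1..n-1 (genomic order)
      for (j in 2:n) {
        s <- tx$start[j]
        if (s - 6L >= 1L && s + 5L <= W)
          donor_key[[sprintf("%s:-:%d", chrom, s)]] <- c(chrom, s - 6L, s + 5L, "-")
        else skipped["donor"] <- skipped["donor"] + 1L
      }
      for (j in seq_len(n - 1L)) {
        e <- tx$end[j]
        if (e - 1L >= 1L && e + 50L <= W)
          acceptor_key[[sprintf("%s:-:%d", chrom, e)]] <- c(chrom, e - 1L, e + 50L, "-")
        else skipped["acceptor"] <- skipped["acceptor"] + 1L
      }
    }
  }
  fetch <- function(keys) {
    if (!length(keys)) return(character(0))
    m <- do.call(rbind, keys)
    segs <- Biostrings::DNAStringSet(dna[m[, 1]],
                                     start = as.integer(m[, 2]),
                                     end = as.integer(m[, 3]))
    neg <- m[, 4] == "-"
    if (any(neg)) segs[neg] <- Biostrings::reverseComplement(segs[neg])
    toupper(as.character(segs))
  }
  structure(list(donor = unname(fetch(donor_key)),
                 acceptor = unname(fetch(acceptor_key)),
                 skipped = skipped),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("boundary_set: %d donor, %d acceptor windows (%d skipped)\n",
              length(x$donor), length(x$acceptor), sum(x$skipped)))
  invisible(x)
}

#' Filter boundaries by the GT/AG rule
#'
#' Keeps donor windows whose first two intronic bases (window positions
#' 7-8) are GT and acceptor windows whose last two intronic bases
#' (window positions 49-50) are AG.
#'
#' @param boundaries a `boundary_set` from [extract_boundaries()].
#' @return `boundary_set` with the filtered sequences and a `counts`
#'   element of kept/dropped numbers per class.
#' @export
filter_gt_ag <- function(boundaries) {
  stopifnot(inherits(boundaries, "boundary_set"))
  dk <- substr(boundaries$donor, 7L, 8L) == "GT"
  ak <- substr(boundaries$acceptor, 49L, 50L) == "AG"
  structure(list(donor = boundaries$donor[dk],
                 acceptor = boundaries$acceptor[ak],
                 skipped = boundaries$skipped,
                 counts = c(donor_kept = sum(dk), donor_dropped = sum(!dk),
                            acceptor_kept = sum(ak), acceptor_dropped = sum(!ak))),
            class = "boundary_set")
}

#' Position weight matrix with information content
#'
#' Per-position base frequencies over A/C/G/T for a set of equal-length
#' sequences, with information content `IC_j = 2 + sum_b p_bj log2 p_bj`
#' bits (0 log 0 = 0).  `N` bases are excluded from a position's
#' denominator.  No small-sample correction is applied by default.
#'
#' @param seqs character vector of equal-length sequences, or a
#'   `boundary_set` component.
#' @param small_sample_correction subtract the e(n) = 3 / (2 ln2 n)
#'   miscount correction from each position's information content.
#' @return list of class `pwm`: `freq` (4 x L matrix, rows A/C/G/T),
#'   `ic` (length-L bits), `n_sequences`.
#' @examples
#' build_pwm(c("AC", "AC", "AG", "AT"))
#' @export
build_pwm <- function(seqs, small_sample_correction = FALSE) {
  if (is.list(seqs)) abort("pass a character vector of sequences")
  if (!length(seqs)) abort("empty sequence set")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("sequences must all have the same length")
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  freq <- matrix(0, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in rownames(freq)) if (b %in% rownames(mat)) freq[b, ] <- mat[b, ]
  denom <- colSums(freq)
  if (any(denom == 0)) abort("a position has no non-N bases")
  freq <- sweep(freq, 2L, denom, "/")
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  ic <- 2 + colSums(plogp)
  if (small_sample_correction) ic <- pmax(0, ic - 3 / (2 * log(2) * length(seqs)))
  structure(list(freq = freq, ic = ic, n_sequences = length(seqs)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: %d positions from %d sequences; IC range %.2f-%.2f bits\n",
              ncol(x$freq), x$n_sequences, min(x$ic), max(x$ic)))
  invisible(x)
}

#' Splice-site offset of a variant
#'
#' Signed transcript-oriented distance of a genomic position from the
#' nearest exon edge: `donor+k` is the k-th intronic base downstream of
#' an exon end (so a variant five bases into the intron is `donor+5`),
#' `acceptor-k` the k-th intronic base upstream of an exon start.
#' Positions inside an exon are labelled `exonic` with the distance to
#' the nearest edge.
#'
#' @param pos genomic position (1-based bp).
#' @param exons data.frame of one transcript's exons with `start`, `end`
#'   (1-based inclusive, any row order).
#' @param strand `"+"` or `"-"`.
#' @return list with `label` (e.g. `"donor+5"`), `site` (`"donor"`,
#'   `"acceptor"` or `"exonic"`), `offset`.
#' @export
variant_splice_offset <- function(pos, exons, strand = "+") {
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(pos >= exons$start & pos <= exons$end)) {
    d <- min(abs(pos - c(exons$start, exons$end)))
    return(list(label = "exonic", site = "exonic", offset = d))
  }
  if (pos < exons$start[1] || pos > exons$end[nrow(exons)])
    abort("position outside the transcript span")
  i <- max(which(exons$end < pos))     # intron between exon i and i+1
  left <- exons$end[i]; right <- exons$start[i + 1L]
  if (strand == "+") {
    d_donor <- pos - left; d_acceptor <- right - pos
  } else {
    d_donor <- right - pos; d_acceptor <- pos - left
  }
  if (d_donor <= d_acceptor)
    list(label = sprintf("donor+%d", d_donor), site = "donor", offset = d_donor)
  else
    list(label = sprintf("acceptor-%d", d_acceptor), site = "acceptor",
         offset = d_acceptor)
}
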