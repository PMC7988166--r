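#' Simulate a toy genome and exon annotation
#'
#' Builds a single-contig genome carrying multi-exon genes on both
#' strands, with intron boundaries following the GT/AG rule with a
#' configurable probability.  When a donor is canonical, intronic
#' positions +3..+6 are drawn from a consensus profile (A-rich at +3/+4,
#' G-rich at +5, T at +6, the mammalian U1-pairing signature); canonical
#' acceptors carry a pyrimidine-rich tract upstream of the AG.
#' Non-canonical boundaries are drawn explicitly non-GT (resp. non-AG),
#' so the fraction of boundaries passing [filter_gt_ag()] equals the
#' consensus strength exactly.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene exons per gene (at least 2 to create introns).
#' @param donor_consensus_strength probability that an intron starts GT
#'   (and, independently, ends AG).
#' @param seed integer seed.
#' @param contig contig name in FASTA/GTF.
#' @return list with `fasta` (FASTA text), `gtf` (GTF text, 1-based
#'   inclusive, `gene_id`/`transcript_id` attributes), and `truth`:
#'   `donor_profile`/`acceptor_profile` (per-position base probabilities
#'   used for canonical boundaries), per-intron flags `donor_is_gt`,
#'   `acceptor_is_ag`, and `strand` per gene.
#' @export
simulate_genome_annotation <- function(n_genes, exons_per_gene = 4,
                                       donor_consensus_strength = 1,
                                       seed = 1, contig = "chr1") {
  if (n_genes <= 0 || exons_per_gene <= 0) abort("counts must be positive")
  if (!(donor_consensus_strength >= 0 && donor_consensus_strength <= 1))
    abort("donor_consensus_strength must be in [0, 1]")
  set.seed(derive_seed(seed, "genome"))
  bases <- c("A", "C", "G", "T")
  # consensus composition for canonical boundaries (transcript 5'->3')
  donor_profile <- rbind(
    A = c(0.35, 0.70, 0.05, 0.15),
    C = c(0.15, 0.10, 0.05, 0.20),
    G = c(0.35, 0.10, 0.80, 0.20),
    T = c(0.15, 0.10, 0.10, 0.45))   # intron positions +3..+6
  acceptor_tract <- c(A = 0.10, C = 0.40, G = 0.10, T = 0.40)  # -20..-3

  genome <- character(0)
  gtf <- character(0)
  donor_is_gt <- logical(0); acceptor_is_ag <- logical(0)
  strands <- character(n_genes)
  cursor <- 1L
  non_dinuc <- function(not) {
    repeat {
      d <- sample(bases, 2, replace = TRUE)
      if (paste(d, collapse = "") != not) return(d)
    }
  }
  for (g in seq_len(n_genes)) {
    ex_len <- sample(40:80, exons_per_gene, replace = TRUE)
    in_len <- if (exons_per_gene > 1)
      sample(60:120, exons_per_gene - 1L, replace = TRUE) else integer(0)
    L <- sum(ex_len) + sum(in_len)
    seq_local <- sample(bases, L, replace = TRUE)
    # local exon coordinates in transcript orientation
    ex_start <- cumsum(c(1L, head(ex_len + c(in_len, 0L), -1L)))
    ex_end <- ex_start + ex_len - 1L
    for (j in seq_len(exons_per_gene - 1L)) {
      i_start <- ex_end[j] + 1L
      i_end <- ex_start[j + 1L] - 1L
      gt <- runif(1) < donor_consensus_strength
      ag <- runif(1) < donor_consensus_strength
      donor_is_gt <- c(donor_is_gt, gt)
      acceptor_is_ag <- c(acceptor_is_ag, ag)
      if (gt) {
        seq_local[i_start + 0:1] <- c("G", "T")
        for (o in 2:5)
          seq_local[i_start + o] <- sample(bases, 1, prob = donor_profile[, o - 1L])
      } else {
        seq_local[i_start + 0:1] <- non_dinuc("GT")
      }
      if (ag) {
        seq_local[i_end - 1:0] <- c("A", "G")
        tract <- (i_end - 19L):(i_end - 2L)
        tract <- tract[tract > i_start + 6L]
        if (length(tract))
          seq_local[tract] <- sample(bases, length(tract), replace = TRUE,
                                     prob = acceptor_tract)
      } else {
        seq_local[i_end - 1:0] <- non_dinuc("AG")
      }
    }
    strand <- sample(c("+", "-"), 1)
    strands[g] <- strand
    g0 <- cursor
    if (strand == "+") {
      genome <- c(genome, seq_local)
      gs <- g0 + ex_start - 1L; ge <- g0 + ex_end - 1L
    } else {
      genome <- c(genome, rev(chartr("ACGT", "TGCA", seq_local)))
      gs <- g0 + L - ex_end; ge <- g0 + L - ex_start
    }
    ord <- order(gs)
    gtf <- c(gtf, sprintf(
      '%s\trecscan_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "gene%d"; transcript_id "gene%d.t1";',
      contig, gs[ord], ge[ord], strand, g, g))
    cursor <- g0 + L + 100L
    genome <- c(genome, sample(bases, 100L, replace = TRUE))
  }
  list(fasta = sprintf(">%s\n%s", contig, paste(genome, collapse = "")),
       gtf = paste(gtf, collapse = "\n"),
       truth = list(donor_profile = donor_profile,
                    acceptor_tract = acceptor_tract,
                    donor_is_gt = donor_is_gt,
                    acceptor_is_ag = acceptor_is_ag,
                    strand = strands))
}
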