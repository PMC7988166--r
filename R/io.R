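#' Write a phased panel as VCF v4.2
#'
#' One biallelic record per marker (REF `A`, ALT `C` stand in for the
#' 0/1 allele coding), all genotypes phased (`0|1` style).
#'
#' @param panel a [phased_panel()].
#' @param path output path (`.vcf`, plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  H <- panel$haplotypes
  N <- n_samples(panel)
  odd <- seq(1L, 2L * N, by = 2L)
  G <- matrix(paste0(H[odd, , drop = FALSE], "|", H[odd + 1L, , drop = FALSE]),
              nrow = N)
  gtcols <- apply(G, 2L, paste, collapse = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=recscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t"))
  body <- paste(panel$markers$chrom, panel$markers$pos, panel$markers$id,
                "A", "C", ".", "PASS", ".", "GT", gtcols, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a panel
#'
#' Accepts phased biallelic records only: multi-allelic sites, records
#' with any unphased (`/`) or missing genotype are rejected and counted.
#'
#' @param path VCF file (v4.2 dialect with GT fields).
#' @param verbose log reject counts.
#' @return a [phased_panel()]; attribute `rejected` carries the counts.
#' @export
read_phased_vcf <- function(path, verbose = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt[, -1, drop = FALSE]    # drop FORMAT column
  samples <- colnames(gt)
  gtf_field <- sub(":.*$", "", gt)  # GT is the first FORMAT field
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  unphased <- apply(gtf_field, 1L, function(r)
    any(grepl("/", r[!is.na(r)], fixed = TRUE)))
  miss <- apply(gtf_field, 1L, function(r)
    any(is.na(r) | grepl(".", r, fixed = TRUE)))
  bad <- multi | unphased | miss
  rejected <- c(multiallelic = sum(multi), unphased = sum(unphased & !multi),
                missing = sum(miss & !multi & !unphased))
  if (verbose) for (k in names(rejected)) log_kv(paste0("rejected_", k), rejected[k])
  if (all(bad)) abort("no usable phased biallelic records in %s", path)
  fix <- fix[!bad, , drop = FALSE]
  gtf_field <- gtf_field[!bad, , drop = FALSE]
  a <- substr(gtf_field, 1L, 1L)
  b <- substr(gtf_field, 3L, 3L)
  M <- nrow(gtf_field); N <- length(samples)
  H <- matrix(0L, nrow = 2L * N, ncol = M)
  H[seq(1L, 2L * N, 2L), ] <- as.integer(t(a))
  H[seq(2L, 2L * N, 2L), ] <- as.integer(t(b))
  panel <- phased_panel(H,
                        data.frame(chrom = fix[, "CHROM"],
                                   pos = as.integer(fix[, "POS"]),
                                   id = fix[, "ID"]),
                        samples)
  attr(panel, "rejected") <- rejected
  panel
}

#' Write / read AI mating records
#'
#' CSV with header `cow_id,sire_id,ai_date,days_to_2nd_ai,sire_carrier,
#' cow_carrier`; an empty `days_to_2nd_ai` field means non-return.
#'
#' @param records mating records data.frame (see [simulate_matings()]).
#' @param path CSV path.
#' @return `path` / the records data.frame.
#' @export
write_mating_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_mating_records
#' @export
read_mating_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(cow_id = "character", sire_id = "character",
                                 ai_date = "character"))
  need <- c("cow_id", "sire_id", "ai_date", "days_to_2nd_ai",
            "sire_carrier", "cow_carrier")
  missing <- setdiff(need, names(rec))
  if (length(missing))
    abort("mating CSV lacks column(s): %s", paste(missing, collapse = ", "))
  if (!nrow(rec)) abort("mating CSV %s has no records", path)
  rec$days_to_2nd_ai <- as.integer(rec$days_to_2nd_ai)
  rec$sire_carrier <- as.logical(rec$sire_carrier)
  rec$cow_carrier <- as.logical(rec$cow_carrier)
  rec
}

#' Write / read an annotated variant table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#' `sift`, `polyphen`, then one alt-dosage column (0/1/2, `NA` missing)
#' per sample.
#'
#' @param variants variant table data.frame.
#' @param path TSV path.
#' @return `path` / the variant table.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = c(chrom = "character"))
}

#' Write a risk-region report
#'
#' TSV mirroring the usual haplotype-region table: `Haplotype_ID`,
#' `Chr`, `Start`, `End`, `Length`, `N_markers`,
#' `Risk_haplotype_frequency`, `Expected`, `Observed`, `P_value`,
#' `Q_value`.
#'
#' @param regions a [merge_regions()] result.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_region_report <- function(regions, path) {
  out <- data.frame(
    Haplotype_ID = regions$id, Chr = regions$chrom,
    Start = regions$start_pos, End = regions$end_pos,
    Length = regions$length, N_markers = regions$n_markers,
    Risk_haplotype_frequency = round_half_up(regions$q, 3),
    Expected = round_half_up(regions$exp_hom, 2),
    Observed = regions$obs_hom,
    P_value = signif(regions$p_min, 3),
    Q_value = signif(regions$q_value, 3))
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation truth to JSON
#'
#' @param truth any truth object from the simulators.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

# -- internal format helpers --------------------------------------------

# GTF exon records as a data.frame (chrom, start, end, strand, gene_id,
# transcript_id).  `gtf` may be a path or GTF text.
read_gtf_exons <- function(gtf) {
  path <- gtf
  if (length(gtf) > 1L || grepl("\t", gtf[1], fixed = TRUE)) {
    path <- tempfile(fileext = ".gtf")
    writeLines(gtf, path)
    on.exit(unlink(path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (!length(gr)) abort("GTF contains no exon records")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = S4Vectors::mcols(gr)$gene_id,
             transcript_id = S4Vectors::mcols(gr)$transcript_id,
             stringsAsFactors = FALSE)
}

# Genome as a DNAStringSet from a DNAStringSet, FASTA path or FASTA text.
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  path <- genome
  if (length(genome) > 1L || startsWith(genome[1], ">")) {
    path <- tempfile(fileext = ".fa")
    writeLines(genome, path)
    on.exit(unlink(path))
  }
  Biostrings::readDNAStringSet(path)
}
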