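#' Search interval around a risk region
#'
#' Candidate causative variants can sit megabases outside the mapped
#' haplotype while remaining in LD with it, so the variant search covers
#' the region plus a flank on both sides (default 6 Mbp), clipped at the
#' chromosome start.
#'
#' @param region one row of a [merge_regions()] result (uses `chrom`,
#'   `start_pos`, `end_pos`).
#' @param flank flank size in bp (default 6e6).
#' @return list with `chrom`, `start`, `end` (1-based inclusive bp).
#' @export
search_interval <- function(region, flank = 6e6) {
  if (flank < 0) abort("flank must be >= 0")
  region <- as.list(region[1, , drop = FALSE])
  list(chrom = region$chrom,
       start = max(1, region$start_pos - flank),
       end = region$end_pos + flank)
}

# consequence labels treated as deleterious without a prediction score
deleterious_consequences <- function() {
  c("stop_gained", "frameshift", "stop_lost", "splice_donor",
    "splice_acceptor", "inframe_insertion", "inframe_deletion")
}

# genotype triple from a dosage vector (0/1/2, NA = missing)
dosage_counts <- function(g) {
  genotype_counts(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                  sum(g == 2L, na.rm = TRUE))
}

#' Apply the four candidate-selection criteria to one variant
#'
#' A candidate causative variant for a homozygosity-deficient haplotype
#' must satisfy: (1) no risk-allele homozygotes in the cohort; (2) allele
#' frequency approximately equal to the risk-haplotype frequency; (3) a
#' deleterious annotation; (4) presence (heterozygous or homozygous) in
#' the haplotype carriers.
#'
#' @param genotypes named integer vector of alt-allele dosages (0/1/2,
#'   `NA` missing), names = sample ids.
#' @param consequence consequence label (e.g. `"stop_gained"`,
#'   `"missense"`, `"splice_region"`).
#' @param hap_freq risk-haplotype frequency in (0, 1).
#' @param carriers character vector of haplotype-carrier sample ids.
#' @param freq_tol absolute tolerance for criterion 2 (default 0.05; the
#'   loose tolerance reflects that variants up to about twice the
#'   haplotype frequency are still treated as "approximately equal").
#' @param min_carrier_fraction minimum fraction of (genotyped) carriers
#'   that must carry the variant for criterion 4 (default 1).
#' @param sift,polyphen prediction labels (`"deleterious"` counts toward
#'   criterion 3 for missense variants).
#' @param deleterious_set consequence labels accepted as deleterious
#'   outright.
#' @return list with `criteria` (named logical vector c1..c4), `pass`
#'   (all four), `near_miss` (passes 1, 2 and 4 but not 3 — the
#'   signature of an unannotated splice-disrupting variant),
#'   `allele_freq`, `carrier_fraction`.
#' @export
apply_criteria <- function(genotypes, consequence, hap_freq, carriers,
                           freq_tol = 0.05, min_carrier_fraction = 1,
                           sift = NA, polyphen = NA,
                           deleterious_set = deleterious_consequences()) {
  if (!(hap_freq > 0 && hap_freq < 1)) abort("hap_freq must be in (0, 1)")
  if (all(is.na(genotypes))) abort("all genotypes missing")
  cnt <- dosage_counts(genotypes)
  af <- allele_frequency(cnt, decimals = NULL)
  c1 <- cnt$n_vv == 0L
  c2 <- abs(af - hap_freq) <= freq_tol
  c3 <- consequence %in% deleterious_set ||
    (consequence %in% c("missense", "missense_variant") &&
       (isTRUE(sift == "deleterious") || isTRUE(polyphen == "deleterious")))
  gc <- genotypes[names(genotypes) %in% carriers]
  gc <- gc[!is.na(gc)]
  cf <- if (length(gc)) sum(gc > 0L) / length(gc) else 0
  c4 <- cf >= min_carrier_fraction
  crit <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4)
  list(criteria = crit, pass = all(crit),
       near_miss = c1 && c2 && c4 && !c3,
       allele_freq = af, carrier_fraction = cf)
}

#' Veto a candidate using survivor genotypes
#'
#' A variant proposed as recessive-lethal cannot show live adult
#' homozygotes: genotyping an independent cohort of healthy adults with
#' any risk-allele homozygote rejects the candidate (or flags incomplete
#' penetrance).
#'
#' @param validation_counts [genotype_counts()] from the validation
#'   cohort.
#' @return `TRUE` if the candidate is rejected (homozygotes found).
#' @export
survivor_homozygote_veto <- function(validation_counts) {
  counts <- as_counts(validation_counts)
  if (counts_n(counts) == 0) abort("empty validation cohort")
  counts$n_vv > 0L
}

#' Linkage disequilibrium r-squared between two loci
#'
#' Phased mode (`"haplotype"`): inputs are per-haplotype 0/1 allele
#' vectors and `r^2 = D^2 / (pA(1-pA) pB(1-pB))` with
#' `D = pAB - pA pB` from haplotype counts.  Genotype mode
#' (`"dosage"`): inputs are per-individual dosages and r-squared is the
#' squared Pearson correlation.  Haplotype-vs-variant LD is computed by
#' coding haplotype carriage as a pseudo-marker.  With phased 0/1 input
#' both modes coincide.
#'
#' @param a,b equal-length numeric vectors; 0/1 per haplotype
#'   (`"haplotype"` mode) or 0/1/2 per individual (`"dosage"` mode).
#' @param mode `"haplotype"` or `"dosage"`.
#' @return r-squared in \[0, 1\].
#' @examples
#' a <- c(1,1,1,1, 0,0,0, 0); b <- c(1,1,1,1, 0,0,0, 1)
#' ld_r2(a, b)  # 0.6
#' @export
ld_r2 <- function(a, b, mode = c("haplotype", "dosage")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) abort("vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    abort("monomorphic input: r-squared undefined")
  if (mode == "haplotype") {
    if (!all(c(a, b) %in% c(0, 1))) abort("haplotype mode expects 0/1 alleles")
    pa <- mean(a); pb <- mean(b); pab <- mean(a == 1 & b == 1)
    D <- pab - pa * pb
    D^2 / (pa * (1 - pa) * pb * (1 - pb))
  } else {
    cor(a, b)^2
  }
}

#' Candidate-variant report for a risk region
#'
#' Annotates every variant inside [search_interval()] with its observed
#' and Hardy-Weinberg-expected genotype triples (formatted `obs/exp`
#' as in candidate tables), risk-allele frequency, the four selection
#' criteria, carrier concordance and LD r-squared against the risk
#' haplotype (carriage coded as a pseudo-marker dosage).  Filtering only
#' annotates; rows are never dropped below the pass/fail flag.
#'
#' @param variants variant table from [simulate_variant_table()] or
#'   [read_variant_table()] (columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `sift`, `polyphen`, then one dosage column
#'   per sample).
#' @param region one row of a [merge_regions()] result.
#' @param carriers character vector of carrier sample ids; defaults to
#'   the region's haplotype carriers computed from `panel`.
#' @param panel the [phased_panel()] the region was mapped in (needed for
#'   LD and default carriers; may be `NULL` if `carriers` is given, in
#'   which case `ld_r2_hap` is `NA`).
#' @param flank,freq_tol,min_carrier_fraction see [search_interval()] and
#'   [apply_criteria()].
#' @return data.frame of class `candidate_report`, one row per variant
#'   in the interval, sorted by criteria passed then LD; columns include
#'   `genotype_obs`, `genotype_exp` (`"rr/rv/vv"` strings),
#'   `risk_allele_freq`, `c1`..`c4`, `pass`, `near_miss`,
#'   `carrier_fraction`, `ld_r2_hap`.
#' @export
build_candidate_report <- function(variants, region, carriers = NULL,
                                   panel = NULL, flank = 6e6,
                                   freq_tol = 0.05, min_carrier_fraction = 1) {
  region <- region[1, , drop = FALSE]
  iv <- search_interval(region, flank)
  meta_cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "sift", "polyphen")
  sample_cols <- setdiff(names(variants), meta_cols)
  if (is.null(carriers)) {
    if (is.null(panel)) abort("either carriers or panel must be supplied")
    carriers <- haplotype_carriers(panel, region$chrom, region$start_marker,
                                   region$end_marker - region$start_marker,
                                   region$hap)
  }
  hap_dosage <- NULL
  if (!is.null(panel)) {
    hs <- window_strings(panel, region$chrom, region$start_marker,
                         region$end_marker - region$start_marker)
    hit <- hs == region$hap
    hap_dosage <- hit[seq(1, length(hs), 2)] + hit[seq(2, length(hs), 2)]
    names(hap_dosage) <- panel$samples
  }
  inside <- variants$chrom == iv$chrom & variants$pos >= iv$start & variants$pos <= iv$end
  v <- variants[inside, , drop = FALSE]
  if (!nrow(v)) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      consequence = character(), genotype_obs = character(),
                      genotype_exp = character(), risk_allele_freq = numeric(),
                      c1 = logical(), c2 = logical(), c3 = logical(),
                      c4 = logical(), pass = logical(), near_miss = logical(),
                      carrier_fraction = numeric(), ld_r2_hap = numeric())
    class(out) <- c("candidate_report", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(v)), function(i) {
    g <- unlist(v[i, sample_cols])
    names(g) <- sample_cols
    cr <- apply_criteria(g, v$consequence[i], region$q, carriers,
                         freq_tol = freq_tol,
                         min_carrier_fraction = min_carrier_fraction,
                         sift = v$sift[i], polyphen = v$polyphen[i])
    cnt <- dosage_counts(g)
    ex <- hwe_expected(cnt)$rounded
    r2 <- NA_real_
    if (!is.null(hap_dosage)) {
      gg <- g[names(hap_dosage)]
      r2 <- tryCatch(ld_r2(gg, hap_dosage, mode = "dosage"), error = function(e) NA_real_)
    }
    data.frame(chrom = v$chrom[i], pos = v$pos[i], ref = v$ref[i],
               alt = v$alt[i], gene = v$gene[i], consequence = v$consequence[i],
               genotype_obs = sprintf("%d/%d/%d", cnt$n_rr, cnt$n_rv, cnt$n_vv),
               genotype_exp = sprintf("%d/%d/%d", as.integer(ex[1]),
                                      as.integer(ex[2]), as.integer(ex[3])),
               risk_allele_freq = round_half_up(cr$allele_freq, 3),
               c1 = cr$criteria["c1"], c2 = cr$criteria["c2"],
               c3 = cr$criteria["c3"], c4 = cr$criteria["c4"],
               pass = cr$pass, near_miss = cr$near_miss,
               carrier_fraction = cr$carrier_fraction, ld_r2_hap = r2)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$pass, -ifelse(is.na(out$ld_r2_hap), -1, out$ld_r2_hap))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' Passing candidates from a report
#'
#' @param report a [build_candidate_report()] result.
#' @return the rows passing all four criteria.
#' @export
filter_candidates <- function(report) report[report$pass, , drop = FALSE]
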