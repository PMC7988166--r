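#' Simulate an annotated variant table for a risk region
#'
#' Builds a variant table (one genotype column per panel sample, coded as
#' alt-allele dosage 0/1/2 or `NA`) containing one causal variant riding
#' the risk haplotype — every haplotype carrier is heterozygous, no
#' homozygotes, labelled deleterious — plus decoy variants each violating
#' exactly one of the four candidate-selection criteria:
#' 1. decoy has risk-allele homozygotes;
#' 2. decoy allele frequency far from the haplotype frequency;
#' 3. decoy carries a benign annotation;
#' 4. decoy is absent from half of the haplotype carriers.
#'
#' @param panel a [phased_panel()].
#' @param region one row of a [merge_regions()] result (uses `chrom`,
#'   `start_pos`, `end_pos`, `start_marker`, `end_marker`, `hap`, `q`).
#' @param causal_config optional list overriding causal-variant fields:
#'   `pos`, `consequence` (default `"stop_gained"`), `sift`, `polyphen`,
#'   `extra_het_noncarriers` (heterozygotes added on non-risk
#'   backgrounds, emulating a variant older than the haplotype).
#' @param n_decoys number of decoys (cycling through criteria 1-4).
#' @param seed integer seed.
#' @param include_causal set `FALSE` to generate a decoys-only table.
#' @return list with `variants` (data.frame: `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `consequence`, `sift`, `polyphen`, then one dosage
#'   column per sample) and `truth` (data.frame: `pos`, `role`,
#'   `violates` — the criterion index a decoy breaks, `NA` for the
#'   causal variant).
#' @export
simulate_variant_table <- function(panel, region, causal_config = list(),
                                   n_decoys = 4, seed = 1,
                                   include_causal = TRUE) {
  stopifnot(inherits(panel, "phased_panel"))
  region <- as.list(region[1, , drop = FALSE])
  carriers <- haplotype_carriers(panel, region$chrom, region$start_marker,
                                 region$end_marker - region$start_marker,
                                 region$hap)
  if (!length(carriers)) abort("region has no haplotype carriers in the panel")
  set.seed(derive_seed(seed, "variants"))
  samples <- panel$samples
  N <- length(samples)
  hap_freq <- region$q
  is_carrier <- samples %in% carriers
  non_carriers <- which(!is_carrier)
  bases <- c("A", "C", "G", "T")

  geno_all_carriers_het <- function(extra_noncarrier_hets = 0, n_hom = 0,
                                    carrier_fraction = 1) {
    g <- integer(N)
    idx <- which(is_carrier)
    keep <- idx[seq_len(floor(length(idx) * carrier_fraction))]
    g[keep] <- 1L
    pool <- non_carriers
    if (n_hom > 0) {
      hom <- pool[seq_len(n_hom)]
      g[hom] <- 2L
      pool <- setdiff(pool, hom)
    }
    if (extra_noncarrier_hets > 0)
      g[pool[seq_len(min(extra_noncarrier_hets, length(pool)))]] <- 1L
    g
  }

  rows <- list(); truth <- list()
  add_row <- function(pos, consequence, sift, polyphen, g, role, violates) {
    ra <- sample(bases, 2)
    row <- data.frame(chrom = region$chrom, pos = pos, ref = ra[1], alt = ra[2],
                      gene = sprintf("GENE%d", length(rows) + 1L),
                      consequence = consequence, sift = sift, polyphen = polyphen,
                      stringsAsFactors = FALSE)
    row[samples] <- as.list(g)
    rows[[length(rows) + 1L]] <<- row
    truth[[length(truth) + 1L]] <<- data.frame(pos = pos, role = role,
                                               violates = violates)
  }

  span <- max(region$end_pos - region$start_pos, 2L)
  at <- function(fr) as.integer(region$start_pos + round(fr * span))
  if (include_causal) {
    cc <- utils::modifyList(
      list(pos = at(0.5), consequence = "stop_gained",
           sift = "deleterious", polyphen = "deleterious",
           extra_het_noncarriers = 0),
      causal_config)
    add_row(cc$pos, cc$consequence, cc$sift, cc$polyphen,
            geno_all_carriers_het(extra_noncarrier_hets = cc$extra_het_noncarriers),
            "causal", NA_integer_)
  }
  if (n_decoys > 0) {
    crit <- rep_len(1:4, n_decoys)
    for (i in seq_len(n_decoys)) {
      pos <- at(0.1 + 0.8 * i / (n_decoys + 1))
      switch(crit[i],
        add_row(pos, "stop_gained", "deleterious", "deleterious",
                geno_all_carriers_het(n_hom = max(1L, min(2L, length(non_carriers)))),
                "decoy", 1L),
        add_row(pos, "frameshift", "deleterious", "deleterious",
                geno_all_carriers_het(extra_noncarrier_hets =
                  max(0L, round((hap_freq + 0.2) * 2 * N) - sum(is_carrier))),
                "decoy", 2L),
        add_row(pos, "synonymous", NA_character_, NA_character_,
                geno_all_carriers_het(), "decoy", 3L),
        add_row(pos, "stop_lost", "deleterious", "deleterious",
                geno_all_carriers_het(carrier_fraction = 0.5,
                  extra_noncarrier_hets = ceiling(sum(is_carrier) / 2)),
                "decoy", 4L))
    }
  }
  if (!length(rows)) {
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           gene = character(), consequence = character(),
                           sift = character(), polyphen = character())
    variants[samples] <- lapply(samples, function(s) integer(0))
    return(list(variants = variants,
                truth = data.frame(pos = integer(), role = character(),
                                   violates = integer())))
  }
  variants <- do.call(rbind, rows)
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, truth = do.call(rbind, truth))
}
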