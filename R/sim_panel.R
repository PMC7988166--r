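#' Planted risk haplotype (simulation truth object)
#'
#' Describes a haplotype to embed in a simulated panel: its location, its
#' allele string, the census frequency to aim for, and the fate of its
#' homozygotes.
#'
#' @param chromosome chromosome label (must exist in the panel config).
#' @param span half-open marker-index interval `c(start, end)` within the
#'   chromosome (markers `start` .. `end - 1` belong to the haplotype).
#' @param alleles allele string over the span (e.g. `"0110..."`), or
#'   `NULL` to draw one at random when simulating.
#' @param target_frequency haplotype frequency the *census* panel should
#'   show, in (0, 0.5).  For a lethal haplotype the generator plants the
#'   haplotype at the higher founder frequency that decays to this value
#'   once homozygotes are removed.
#' @param lethality one of `"embryonic"`, `"postnatal"`, `"none"`.
#'   Either form of lethality removes homozygotes before the census of
#'   surviving adults; the label is kept as truth for downstream mating
#'   simulations.
#' @param penetrance probability that a homozygote is lost (default 1,
#'   complete lethality).
#' @return object of class `planted_haplotype`.
#' @export
planted_haplotype <- function(chromosome, span, alleles = NULL,
                              target_frequency = 0.05,
                              lethality = c("embryonic", "postnatal", "none"),
                              penetrance = 1) {
  lethality <- match.arg(lethality)
  if (!(target_frequency > 0 && target_frequency < 0.5))
    abort("target_frequency must be in (0, 0.5)")
  if (!(penetrance >= 0 && penetrance <= 1)) abort("penetrance must be in [0, 1]")
  if (length(span) != 2L || span[2] <= span[1] || span[1] < 1)
    abort("span must be a half-open interval c(start, end) with end > start >= 1")
  if (!is.null(alleles)) {
    if (nchar(alleles) != span[2] - span[1])
      abort("allele string length (%d) must equal span length (%d)",
            nchar(alleles), span[2] - span[1])
    if (grepl("[^01]", alleles)) abort("allele string must contain only 0/1")
  }
  structure(list(chromosome = as.character(chromosome),
                 span = as.integer(span), alleles = alleles,
                 target_frequency = target_frequency,
                 lethality = lethality, penetrance = penetrance),
            class = "planted_haplotype")
}

#' Simulation configuration for a phased panel
#'
#' @param n_samples number of individuals in the census panel.
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers on each chromosome.
#' @param marker_spacing distance between adjacent markers in bp.
#' @param allele_freq_range range of the uniform law for per-marker
#'   alternate-allele frequencies.  The default (0.05, 0.95) mimics an
#'   array panel filtered at minor-allele frequency 0.05.
#' @param risk_haplotypes list of [planted_haplotype()] objects.
#' @param seed integer seed; fully determines the simulated panel.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 4843, n_chromosomes = 1,
                       markers_per_chromosome = 1000,
                       marker_spacing = 50000,
                       allele_freq_range = c(0.05, 0.95),
                       risk_haplotypes = list(), seed = 1) {
  if (n_samples <= 0) abort("n_samples must be positive")
  if (n_chromosomes <= 0 || markers_per_chromosome <= 0)
    abort("chromosome and marker counts must be positive")
  if (!(all(allele_freq_range > 0) && all(allele_freq_range < 1) &&
        allele_freq_range[1] <= allele_freq_range[2]))
    abort("allele_freq_range must be an increasing interval inside (0, 1)")
  chroms <- as.character(seq_len(n_chromosomes))
  for (rh in risk_haplotypes) {
    stopifnot(inherits(rh, "planted_haplotype"))
    if (!rh$chromosome %in% chroms)
      abort("planted haplotype on unknown chromosome %s", rh$chromosome)
    if (rh$span[2] - 1L > markers_per_chromosome)
      abort("planted span [%d, %d) outside chromosome (%d markers)",
            rh$span[1], rh$span[2], markers_per_chromosome)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 marker_spacing = as.integer(marker_spacing),
                 allele_freq_range = allele_freq_range,
                 risk_haplotypes = risk_haplotypes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Founder-pool frequency that yields census frequency q_t after
# homozygote removal with the given penetrance.  Census allele frequency
# of a planted haplotype at founder frequency x, with homozygotes lost at
# rate pi, is x(1 - pi x) / (1 - pi x^2); inverting gives the positive
# root of pi (q_t - 1) x^2 + x - q_t = 0.
founder_frequency <- function(target, penetrance) {
  if (penetrance == 0) return(target)
  a <- penetrance * (target - 1)
  (-1 + sqrt(1 + 4 * a * target)) / (2 * a)
}

#' Simulate a phased survivor panel with planted risk haplotypes
#'
#' Each individual receives two haplotypes drawn independently from a
#' founder pool (random mating).  Background alleles are drawn
#' marker-independently from per-marker frequencies sampled from
#' `allele_freq_range` (no background LD, the simplest null).  Each
#' planted haplotype replaces the spanned markers of a founder haplotype
#' with its allele string, at the founder frequency that makes the
#' *census* frequency match `target_frequency` after lethal-homozygote
#' removal.  Individuals homozygous for a lethal planted allele string
#' are rejected and redrawn with probability `penetrance`, keeping the
#' census size fixed at `n_samples` (a fixed census of survivors).
#'
#' @param config a [sim_config()].
#' @return list with `panel` (a [phased_panel()]) and `truth` (list of
#'   [planted_haplotype()] objects, each completed with its realized
#'   `alleles` string, `founder_frequency` and bp coordinates
#'   `start_pos`/`end_pos`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "panel"))
  N <- config$n_samples
  M <- config$markers_per_chromosome
  chroms <- as.character(seq_len(config$n_chromosomes))
  markers <- data.frame(
    chrom = rep(chroms, each = M),
    pos = rep.int(config$marker_spacing * seq_len(M), config$n_chromosomes),
    id = sprintf("snp_%s_%d", rep(chroms, each = M), rep.int(seq_len(M), config$n_chromosomes)))
  Mtot <- nrow(markers)
  freq <- runif(Mtot, config$allele_freq_range[1], config$allele_freq_range[2])

  truth <- lapply(config$risk_haplotypes, function(rh) {
    if (is.null(rh$alleles)) {
      len <- rh$span[2] - rh$span[1]
      rh$alleles <- paste(rbinom(len, 1, 0.5), collapse = "")
    }
    rh$founder_frequency <- founder_frequency(
      rh$target_frequency,
      if (rh$lethality == "none") 0 else rh$penetrance)
    off <- (match(rh$chromosome, chroms) - 1L) * M
    rh$cols <- off + rh$span[1]:(rh$span[2] - 1L)
    rh$start_pos <- markers$pos[rh$cols[1]]
    rh$end_pos <- markers$pos[rh$cols[length(rh$cols)]]
    rh
  })

  draw_haps <- function(n) {
    # n background haplotypes (column-wise to bound memory), then planted
    # strings stamped in
    H <- matrix(0L, nrow = n, ncol = Mtot)
    for (j in seq_len(Mtot)) H[, j] <- rbinom(n, 1L, freq[j])
    for (rh in truth) {
      hit <- which(rbinom(n, 1, rh$founder_frequency) == 1L)
      if (length(hit))
        H[hit, rh$cols] <- matrix(as.integer(strsplit(rh$alleles, "")[[1]]),
                                  nrow = length(hit), ncol = length(rh$cols),
                                  byrow = TRUE)
    }
    H
  }

  H <- draw_haps(2L * N)
  lethal <- Filter(function(rh) rh$lethality != "none" && rh$penetrance > 0, truth)
  if (length(lethal)) {
    # rejection sampling on individuals: each newly drawn individual that
    # is homozygous for a lethal string is removed with probability
    # penetrance and redrawn; an individual spared once (the surviving
    # 1 - penetrance fraction) is final and never re-tested
    active <- seq_len(N)
    while (length(active)) {
      doomed <- logical(length(active))
      for (rh in lethal) {
        av <- rh$cols
        pat <- as.integer(strsplit(rh$alleles, "")[[1]])
        arows <- as.vector(rbind(2L * active - 1L, 2L * active))
        sub <- H[arows, av, drop = FALSE]
        hitrow <- rowSums(sub == matrix(pat, nrow(sub), length(av),
                                        byrow = TRUE)) == length(av)
        homo <- hitrow[c(TRUE, FALSE)] & hitrow[c(FALSE, TRUE)]
        doomed <- doomed | (homo & runif(length(active)) < rh$penetrance)
      }
      active <- active[doomed]
      if (length(active)) {
        rows <- as.vector(rbind(2L * active - 1L, 2L * active))
        H[rows, ] <- draw_haps(length(rows))
      }
    }
  }

  panel <- phased_panel(H, markers, sprintf("ind_%05d", seq_len(N)))
  list(panel = panel, truth = lapply(truth, function(rh) { rh$cols <- NULL; rh }))
}
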