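# a small lethal panel plus the truth-derived region row used across
# the prioritization tests
prior_fixture <- function(seed = 13) {
  cfg <- sim_config(n_samples = 600, markers_per_chromosome = 60,
                    risk_haplotypes = list(planted_haplotype(
                      "1", c(20, 40), target_frequency = 0.08)),
                    seed = seed)
  sim <- simulate_panel(cfg)
  rh <- sim$truth[[1]]
  carriers <- haplotype_carriers(sim$panel, "1", rh$span[1],
                                 rh$span[2] - rh$span[1], rh$alleles)
  region <- data.frame(chrom = "1", start_pos = rh$start_pos,
                       end_pos = rh$end_pos,
                       start_marker = rh$span[1], end_marker = rh$span[2],
                       hap = rh$alleles,
                       q = length(carriers) / (2 * n_samples(sim$panel)))
  list(panel = sim$panel, region = region, carriers = carriers)
}

test_that("search interval adds the flank and clips at the chromosome start", {
  r <- data.frame(chrom = "5", start_pos = 10e6, end_pos = 12e6)
  iv <- search_interval(r)
  expect_equal(c(iv$start, iv$end), c(4e6, 18e6))
  iv0 <- search_interval(r, flank = 0)
  expect_equal(c(iv0$start, iv0$end), c(10e6, 12e6))
  r2 <- data.frame(chrom = "5", start_pos = 2e6, end_pos = 3e6)
  expect_equal(search_interval(r2)$start, 1)
  expect_error(search_interval(r, flank = -1), "flank")
})

test_that("the planted causal variant passes all four criteria", {
  fx <- prior_fixture()
  tab <- simulate_variant_table(fx$panel, fx$region, n_decoys = 0, seed = 1)
  expect_equal(nrow(tab$variants), 1L)
  rep <- build_candidate_report(tab$variants, fx$region, panel = fx$panel)
  expect_equal(nrow(rep), 1L)
  expect_true(rep$pass)
  expect_equal(nrow(filter_candidates(rep)), 1L)
  expect_equal(rep$carrier_fraction, 1)
  expect_gt(rep$ld_r2_hap, 0.9)
})

test_that("each decoy fails exactly its designated criterion", {
  fx <- prior_fixture()
  tab <- simulate_variant_table(fx$panel, fx$region, n_decoys = 4, seed = 11)
  rep <- build_candidate_report(tab$variants, fx$region, panel = fx$panel)
  expect_equal(nrow(rep), 5L)
  expect_equal(sum(rep$pass), 1L)
  expect_equal(nrow(filter_candidates(rep)), 1L)
  merged <- merge(as.data.frame(rep), tab$truth, by = "pos")
  for (i in seq_len(nrow(merged))) {
    crit <- unlist(merged[i, c("c1", "c2", "c3", "c4")])
    if (merged$role[i] == "causal") {
      expect_true(all(crit))
    } else {
      v <- merged$violates[i]
      expect_false(crit[v])
      expect_true(all(crit[-v]))
    }
  }
})

test_that("a decoys-only table yields no candidates", {
  fx <- prior_fixture()
  tab <- simulate_variant_table(fx$panel, fx$region, n_decoys = 4, seed = 2,
                                include_causal = FALSE)
  rep <- build_candidate_report(tab$variants, fx$region, panel = fx$panel)
  expect_equal(nrow(filter_candidates(rep)), 0L)
})

test_that("a region without carriers is rejected", {
  fx <- prior_fixture()
  bad <- fx$region
  bad$hap <- strrep("2", nchar(fx$region$hap))  # matches no 0/1 haplotype
  expect_error(simulate_variant_table(fx$panel, bad, seed = 1),
               "no haplotype carriers")
})

test_that("criteria arithmetic: frequency tolerance and carrier fraction", {
  samples <- sprintf("s%d", 1:517)
  carriers <- samples[1:22]
  g <- dosages_with_counts(473, 44, 0, samples)   # hets first in carriers
  g[] <- 0L; g[samples[1:44]] <- 1L               # all 22 carriers het + 22 others
  res <- apply_criteria(g, "stop_gained", hap_freq = 22 / 517, carriers = carriers)
  expect_equal(res$allele_freq, 44 / 1034, tolerance = 1e-12)
  expect_true(res$criteria["c2"])   # |0.0426 - 0.0426| within 0.05
  expect_true(res$pass)
  # near-miss: unannotated splice-region variant passing 1, 2, 4
  res2 <- apply_criteria(g, "splice_region", hap_freq = 22 / 517,
                         carriers = carriers)
  expect_false(res2$criteria["c3"])
  expect_true(res2$near_miss)
  # missense needs a deleterious prediction
  res3 <- apply_criteria(g, "missense", hap_freq = 22 / 517, carriers = carriers,
                         sift = "deleterious")
  expect_true(res3$criteria["c3"])
  expect_error(apply_criteria(rep(NA_integer_, 3), "missense", 0.05, carriers),
               "missing")
})

test_that("criteria are monotone in their tolerances", {
  fx <- prior_fixture()
  tab <- simulate_variant_table(fx$panel, fx$region, n_decoys = 8, seed = 5)
  for (i in seq_len(nrow(tab$variants))) {
    g <- unlist(tab$variants[i, -(1:8)])
    strict <- apply_criteria(g, tab$variants$consequence[i], fx$region$q,
                             fx$carriers, freq_tol = 0.02,
                             min_carrier_fraction = 1)
    loose <- apply_criteria(g, tab$variants$consequence[i], fx$region$q,
                            fx$carriers, freq_tol = 0.10,
                            min_carrier_fraction = 0.5)
    if (strict$pass) expect_true(loose$pass)
  }
})

test_that("survivor homozygotes veto a lethal candidate", {
  expect_true(survivor_homozygote_veto(c(2490, 223, 7)))
  expect_false(survivor_homozygote_veto(c(100, 10, 0)))
  expect_error(survivor_homozygote_veto(c(0, 0, 0)), "empty")
})

test_that("LD r2 matches hand computation and correlation oracle", {
  expect_equal(ld_r2(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  # 8 haplotype pairs: AB x4, ab x3, aB x1 -> D = 0.1875, r2 = 0.6
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 1, 1, 0, 0, 0, 1)
  expect_equal(ld_r2(a, b), 0.6, tolerance = 1e-12)
  # haplotype-mode r2 equals squared Pearson correlation for 0/1 input
  set.seed(8)
  x <- rbinom(500, 1, 0.4); y <- ifelse(runif(500) < 0.3, x, rbinom(500, 1, 0.4))
  expect_equal(ld_r2(x, y), cor(x, y)^2, tolerance = 1e-12)
  # symmetry and allele-relabel invariance
  expect_equal(ld_r2(a, b), ld_r2(b, a))
  expect_equal(ld_r2(1 - a, b), ld_r2(a, b), tolerance = 1e-12)
  # independent markers decorrelate
  set.seed(9)
  u <- rbinom(10000, 1, 0.5); v <- rbinom(10000, 1, 0.5)
  expect_lt(ld_r2(u, v), 0.01)
  expect_error(ld_r2(c(0, 0, 0), c(0, 1, 0)), "monomorphic")
})

test_that("phased and dosage r2 agree on random-mating panels", {
  set.seed(10)
  n <- 5000
  h1a <- rbinom(n, 1, 0.3); h2a <- rbinom(n, 1, 0.3)
  h1b <- ifelse(runif(n) < 0.6, h1a, rbinom(n, 1, 0.3))
  h2b <- ifelse(runif(n) < 0.6, h2a, rbinom(n, 1, 0.3))
  r_hap <- ld_r2(c(h1a, h2a), c(h1b, h2b))
  r_dos <- ld_r2(h1a + h2a, h1b + h2b, mode = "dosage")
  expect_lt(abs(r_hap - r_dos), 0.02)
})

test_that("candidate report mirrors printed obs/exp/freq formatting", {
  samples <- sprintf("s%d", 1:517)
  v <- data.frame(chrom = "17", pos = 1000L, ref = "G", alt = "T",
                  gene = "SPLC1", consequence = "splice_region",
                  sift = NA_character_, polyphen = NA_character_)
  v[samples] <- as.list(dosages_with_counts(473, 44, 0, samples))
  region <- data.frame(chrom = "17", start_pos = 500L, end_pos = 2000L, q = 0.0426)
  rep <- build_candidate_report(v, region, carriers = samples[1:22])
  expect_equal(rep$genotype_obs, "473/44/0")
  expect_equal(rep$genotype_exp, "474/42/1")
  expect_equal(rep$risk_allele_freq, 0.043)
})

test_that("report annotates every variant in the interval without dropping", {
  fx <- prior_fixture()
  tab <- simulate_variant_table(fx$panel, fx$region, n_decoys = 6, seed = 3)
  rep <- build_candidate_report(tab$variants, fx$region, panel = fx$panel)
  expect_equal(nrow(rep), nrow(tab$variants))
  far <- tab$variants[1, ]
  far$pos <- fx$region$end_pos + 7e6   # outside the 6 Mbp flank
  rep2 <- build_candidate_report(rbind(tab$variants, far), fx$region,
                                 panel = fx$panel)
  expect_equal(nrow(rep2), nrow(tab$variants))
  empty <- build_candidate_report(tab$variants[0, ], fx$region, panel = fx$panel)
  expect_equal(nrow(empty), 0L)
})
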