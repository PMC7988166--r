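test_that("window enumeration counts follow the closed form", {
  m5 <- data.frame(chrom = "1", pos = 100L * 1:5, id = paste0("m", 1:5))
  expect_equal(nrow(enumerate_windows(m5, 2, 3)), 7L)          # 4 + 3
  m100x2 <- data.frame(chrom = rep(c("1", "2"), each = 100),
                       pos = rep(100L * 1:100, 2), id = sprintf("m%d", 1:200))
  expect_equal(nrow(enumerate_windows(m100x2, 100, 100)), 2L)
  m101 <- data.frame(chrom = "1", pos = 100L * 1:101, id = sprintf("m%d", 1:101))
  expect_equal(nrow(enumerate_windows(m101, 2, 100)),
               sum(102 - (2:100)))                              # 5049
  expect_error(enumerate_windows(m5, 1, 3), "k_min")
})

test_that("haplotype counting matches the hand-counted diplotype example", {
  p <- tiny_panel()
  hc <- haplotype_counts(p, "1", 1, 2)
  row11 <- hc[hc$hap == "11", ]
  expect_equal(row11$copies, 3L)
  expect_equal(row11$q, 0.25)
  expect_equal(row11$carriers, 3L)
  expect_equal(row11$homozygotes, 0L)
  # conservation: copies sum to 2N, frequencies to 1
  expect_equal(sum(hc$copies), 12L)
  expect_equal(sum(hc$q), 1)
})

test_that("an all-homozygous window yields q = 1 and N homozygotes", {
  H <- matrix(0L, nrow = 8, ncol = 3)
  p <- phased_panel(H, data.frame(chrom = "1", pos = c(1L, 2L, 3L),
                                  id = c("a", "b", "c")), paste0("s", 1:4))
  hc <- haplotype_counts(p, "1", 1, 3)
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$q, 1)
  expect_equal(hc$homozygotes, 4L)
})

test_that("haplotype counting agrees with exhaustive enumeration on small panels", {
  for (seed in 1:5) {
    p <- random_panel(10, 10, seed)
    for (win in list(c(1, 2), c(3, 4), c(1, 10), c(6, 5))) {
      got <- haplotype_counts(p, "1", win[1], win[2])
      want <- oracle_haplotype_counts(p, "1", win[1], win[2])
      got <- got[order(got$hap), c("hap", "copies", "carriers", "homozygotes", "q")]
      want <- want[order(want$hap), c("hap", "copies", "carriers", "homozygotes", "q")]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("deficiency test matches its closed form", {
  r <- deficiency_test(0.052, 4843, 0)
  expect_equal(r$exp_hom, 4843 * 0.052^2, tolerance = 1e-12)
  expect_equal(r$exp_hom, 13.1, tolerance = 0.001)
  expect_equal(r$p_deficit, (1 - 0.052^2)^4843, tolerance = 1e-12)
  expect_equal(r$p_deficit, 2.0e-6, tolerance = 0.01)
  expect_equal(deficiency_test(0, 100, 0), list(exp_hom = 0, p_deficit = 1))
  expect_equal(deficiency_test(0.3, 50, 50)$p_deficit, 1)
  expect_error(deficiency_test(1.2, 10, 0), "q must be")
})

test_that("deficiency p at obs = 0 is strictly decreasing in q", {
  qs <- seq(0.02, 0.3, by = 0.02)
  ps <- vapply(qs, function(q) deficiency_test(q, 4843, 0)$p_deficit, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(fdr_adjust(0.01), 0.01)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.5)), "must be in")
})

test_that("scan agrees with the R-path tests on small panels", {
  for (seed in 1:3) {
    p <- random_panel(30, 12, seed)
    got <- scan_haplotypes(p, alpha = 0.9, min_q = 0.05, k_min = 2, k_max = 6)
    # independent recomputation through enumerate/haplotype_counts/deficiency
    min_copies <- ceiling(0.05 * 60)
    wants <- list()
    wins <- enumerate_windows(p, 2, 6)
    for (i in seq_len(nrow(wins))) {
      hc <- haplotype_counts(p, wins$chrom[i], wins$start_marker[i], wins$k[i])
      hc <- hc[hc$copies >= min_copies, , drop = FALSE]
      for (j in seq_len(nrow(hc))) {
        dt <- deficiency_test(hc$q[j], 30, hc$homozygotes[j])
        if (dt$p_deficit < 0.9)
          wants[[length(wants) + 1L]] <- data.frame(
            start_marker = wins$start_marker[i], k = wins$k[i], hap = hc$hap[j],
            q = hc$q[j], n_carriers = hc$carriers[j], obs_hom = hc$homozygotes[j],
            p_deficit = dt$p_deficit)
      }
    }
    want <- do.call(rbind, wants)
    key <- function(d) paste(d$start_marker, d$k, d$hap)
    want <- want[order(key(want)), ]
    gotc <- as.data.frame(got)[order(key(got)), names(want)]
    rownames(want) <- rownames(gotc) <- NULL
    expect_equal(gotc, want, tolerance = 1e-12)
  }
})

test_that("scan with min_q = 1 returns nothing", {
  p <- random_panel(20, 8, 3)
  expect_equal(nrow(scan_haplotypes(p, min_q = 1)), 0L)
})

test_that("deficiency p-values are conservative on null panels", {
  # collect all tested p-values at q >= 0.05 through the R path on
  # independent-marker null panels; empirical cdf must not exceed uniform
  ps <- c()
  for (seed in 11:13) {
    p <- random_panel(400, 30, seed)
    wins <- enumerate_windows(p, 2, 4)
    for (i in seq_len(nrow(wins))) {
      hc <- haplotype_counts(p, "1", wins$start_marker[i], wins$k[i])
      hc <- hc[hc$q >= 0.05, , drop = FALSE]
      ps <- c(ps, deficiency_test(hc$q, 400, hc$homozygotes)$p_deficit)
    }
  }
  for (t in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / length(ps)))
  }
})

test_that("a planted lethal haplotype is recovered at genome-wide stringency", {
  cfg <- sim_config(n_samples = 4843, markers_per_chromosome = 400,
                    risk_haplotypes = list(planted_haplotype("1", c(180, 210),
                                                             target_frequency = 0.05)),
                    seed = 99)
  sim <- simulate_panel(cfg)
  win <- scan_haplotypes(sim$panel)
  expect_gt(nrow(win), 0)
  rh <- sim$truth[[1]]
  overlap <- win$start_pos <= rh$end_pos & win$end_pos >= rh$start_pos
  expect_true(any(overlap))
  reg <- merge_regions(win, prefix = "SIM")
  expect_equal(nrow(reg), 1L)
  expect_true(reg$start_pos <= rh$end_pos && reg$end_pos >= rh$start_pos)
  expect_equal(reg$obs_hom, 0L)
})

test_that("recovery holds in at least 95% of replicate simulations", {
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_samples = 4843, markers_per_chromosome = 250,
                      risk_haplotypes = list(planted_haplotype("1", c(100, 130),
                                                               target_frequency = 0.05)),
                      seed = 5000 + r)
    sim <- simulate_panel(cfg)
    win <- scan_haplotypes(sim$panel)
    rh <- sim$truth[[1]]
    reg <- merge_regions(win, prefix = "SIM")
    ok <- nrow(reg) == 1L &&
      reg$start_pos <= rh$end_pos && reg$end_pos >= rh$start_pos
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})
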