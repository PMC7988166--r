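# hand-built two-exon gene: exon1 1-20, intron 21-80, exon2 81-100
toy_gene <- function(strand = "+") {
  set.seed(400)
  s <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  s[21:22] <- c("G", "T")        # canonical donor
  s[25] <- "G"                   # the +5 donor position
  s[79:80] <- c("A", "G")        # canonical acceptor
  if (strand == "+") {
    fasta <- sprintf(">chrT\n%s", paste(s, collapse = ""))
    gtf <- paste(
      'chrT\ttest\texon\t1\t20\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
      'chrT\ttest\texon\t81\t100\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
      sep = "\n")
  } else {
    # same transcript encoded on the minus strand of the reversed contig
    rc <- rev(chartr("ACGT", "TGCA", s))
    fasta <- sprintf(">chrT\n%s", paste(rc, collapse = ""))
    gtf <- paste(
      'chrT\ttest\texon\t1\t20\t.\t-\t.\tgene_id "g1"; transcript_id "g1.t1";',
      'chrT\ttest\texon\t81\t100\t.\t-\t.\tgene_id "g1"; transcript_id "g1.t1";',
      sep = "\n")
  }
  list(fasta = fasta, gtf = gtf, seq = s)
}

test_that("donor and acceptor windows are cut at the exon junctions", {
  tg <- toy_gene("+")
  b <- extract_boundaries(tg$gtf, tg$fasta)
  expect_length(b$donor, 1)
  expect_length(b$acceptor, 1)
  expect_equal(b$donor, paste(tg$seq[15:26], collapse = ""))     # 6 ex + 6 in
  expect_equal(b$acceptor, paste(tg$seq[31:82], collapse = ""))  # 50 in + 2 ex
  expect_equal(substr(b$donor, 7, 8), "GT")
  expect_equal(substr(b$acceptor, 49, 50), "AG")
})

test_that("minus-strand genes give the identical transcript-oriented windows", {
  bp <- extract_boundaries(toy_gene("+")$gtf, toy_gene("+")$fasta)
  bm <- extract_boundaries(toy_gene("-")$gtf, toy_gene("-")$fasta)
  expect_equal(bm$donor, bp$donor)
  expect_equal(bm$acceptor, bp$acceptor)
})

test_that("fully canonical simulated annotation passes the GT/AG filter", {
  sim <- simulate_genome_annotation(30, exons_per_gene = 3,
                                    donor_consensus_strength = 1, seed = 4)
  b <- extract_boundaries(sim$gtf, sim$fasta)
  expect_equal(length(b$donor), 60L)   # 30 genes x 2 introns, deduplicated
  flt <- filter_gt_ag(b)
  expect_equal(unname(flt$counts["donor_dropped"]), 0L)
  expect_equal(unname(flt$counts["acceptor_dropped"]), 0L)
  expect_true(all(substr(b$donor, 7, 8) == "GT"))
  expect_true(all(substr(b$acceptor, 49, 50) == "AG"))
})

test_that("half-strength consensus retains about half the boundaries", {
  sim <- simulate_genome_annotation(200, exons_per_gene = 4,
                                    donor_consensus_strength = 0.5, seed = 5)
  b <- extract_boundaries(sim$gtf, sim$fasta)
  flt <- filter_gt_ag(b)
  n <- length(b$donor)                 # 600 introns
  kept <- unname(flt$counts["donor_kept"])
  band <- qbinom(c(5e-4, 1 - 5e-4), n, 0.5)
  expect_gte(kept, band[1])
  expect_lte(kept, band[2])
  # the generator records which introns were drawn canonical
  expect_equal(kept, sum(sim$truth$donor_is_gt))
})

test_that("re-encoding the toy genome on the opposite strand leaves PWMs unchanged", {
  sim <- simulate_genome_annotation(25, exons_per_gene = 3,
                                    donor_consensus_strength = 1, seed = 6)
  b1 <- filter_gt_ag(extract_boundaries(sim$gtf, sim$fasta))
  # flip: reverse-complement the contig and mirror all coordinates/strands
  seq <- sub("^>[^\n]*\n", "", sim$fasta)
  L <- nchar(seq)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  g <- read.delim(text = sim$gtf, header = FALSE, quote = "",
                  stringsAsFactors = FALSE)
  g2 <- g
  g2$V4 <- L - g$V5 + 1L
  g2$V5 <- L - g$V4 + 1L
  g2$V7 <- ifelse(g$V7 == "+", "-", "+")
  gtf2 <- do.call(paste, c(unname(as.list(g2)), sep = "\t"))
  b2 <- filter_gt_ag(extract_boundaries(gtf2, sprintf(">chr1\n%s", rc)))
  expect_equal(sort(b1$donor), sort(b2$donor))
  expect_equal(sort(b1$acceptor), sort(b2$acceptor))
  p1 <- build_pwm(b1$donor); p2 <- build_pwm(b2$donor)
  expect_equal(p1$freq, p2$freq)
  expect_equal(p1$ic, p2$ic)
})

test_that("information content follows the entropy formula", {
  p <- build_pwm(rep("ACGT", 10))
  expect_equal(p$ic, rep(2, 4))                       # monomorphic columns
  p2 <- build_pwm(c("AA", "CA", "GA", "TA"))
  expect_equal(p2$ic[1], 0)                           # uniform column
  expect_equal(p2$ic[2], 2)
  p3 <- build_pwm(c("A", "A", "C", "C"))
  expect_equal(p3$ic, 1)                              # 2 - H(0.5, 0.5)
  expect_true(all(colSums(p3$freq) == 1))
  expect_error(build_pwm(character(0)), "empty")
  expect_error(build_pwm(c("AA", "AAA")), "same length")
})

test_that("N bases are excluded from a position's denominator", {
  p <- build_pwm(c("AN", "AC", "AC", "AC"))
  expect_equal(unname(p$freq["C", 2]), 1)
  expect_equal(p$ic[2], 2)
})

test_that("the donor PWM is fixed at the obligate GT after filtering", {
  sim <- simulate_genome_annotation(60, exons_per_gene = 3,
                                    donor_consensus_strength = 0.7, seed = 8)
  flt <- filter_gt_ag(extract_boundaries(sim$gtf, sim$fasta))
  pwm <- build_pwm(flt$donor)
  expect_equal(pwm$ic[7], 2)
  expect_equal(pwm$ic[8], 2)
  expect_equal(unname(pwm$freq["G", 7]), 1)
  expect_equal(unname(pwm$freq["T", 8]), 1)
  # IC is bounded by 2 bits everywhere
  expect_true(all(pwm$ic >= 0 & pwm$ic <= 2 + 1e-12))
  # the planted +5 G consensus dominates that column
  expect_gt(pwm$freq["G", 11], 0.5)
})

test_that("variant splice offsets are transcript-oriented", {
  exons <- data.frame(start = c(1, 81), end = c(20, 100))
  # five bases into the intron after exon 1 (plus strand)
  expect_equal(variant_splice_offset(25, exons, "+")$label, "donor+5")
  expect_equal(variant_splice_offset(21, exons, "+")$label, "donor+1")
  # near the downstream exon it is an acceptor offset
  expect_equal(variant_splice_offset(78, exons, "+")$label, "acceptor-3")
  # minus strand: the donor side of the intron is at the higher-coordinate
  # exon's genomic start
  expect_equal(variant_splice_offset(76, exons, "-")$label, "donor+5")
  expect_equal(variant_splice_offset(80, exons, "-")$label, "donor+1")
  ex <- variant_splice_offset(10, exons, "+")
  expect_equal(ex$label, "exonic")
  expect_equal(ex$offset, 9)
  expect_error(variant_splice_offset(300, exons, "+"), "outside")
})
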