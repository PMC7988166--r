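#' Simulate AI mating records with carrier-dependent early returns
#'
#' Generates artificial-insemination service records for random
#' sire x cow pairs.  Each parent is a haplotype carrier independently
#' with probability `carrier_freq`.  The outcome of a service is either a
#' second AI in one of the standard return bins or a non-return
#' (conception), drawn from `baseline_return`; carrier x carrier (risk)
#' matings receive an additive excess probability `excess_early_loss` of
#' a second AI in `excess_bin`, taken from the non-return mass, which
#' emulates recessive embryonic loss followed by resumed estrus.
#'
#' @param n_records number of mating records.
#' @param carrier_freq probability a sire or cow carries the haplotype.
#' @param baseline_return named numeric vector of per-bin return
#'   probabilities over [return_bins()]; must sum to below 1, the
#'   remainder being the non-return (conception) probability.
#' @param excess_early_loss additive excess return probability for risk
#'   matings (default 0.07).
#' @param excess_bin the bin receiving the excess (default `"30-60"`,
#'   around the blastocyst-loss window).
#' @param seed integer seed.
#' @param n_sires,n_cows pool sizes for id assignment.
#' @return list with `records` (data.frame: `cow_id`, `sire_id`,
#'   `ai_date`, `days_to_2nd_ai` with `NA` for non-return,
#'   `sire_carrier`, `cow_carrier`) and `truth` (the parameters used).
#' @export
simulate_matings <- function(n_records,
                             carrier_freq = 0.10,
                             baseline_return = c("18-29" = 0.10, "30-60" = 0.18,
                                                 "61-90" = 0.05, "91-140" = 0.03,
                                                 "141+" = 0.02),
                             excess_early_loss = 0.07,
                             excess_bin = "30-60",
                             seed = 1,
                             n_sires = max(1L, round(n_records / 100)),
                             n_cows = max(1L, round(n_records / 10))) {
  if (n_records < 0) abort("n_records must be >= 0")
  if (!all(names(baseline_return) %in% return_bins()) || is.null(names(baseline_return)))
    abort("baseline_return must be named with return bins")
  if (any(baseline_return < 0) || any(baseline_return > 1) ||
      !(carrier_freq >= 0 && carrier_freq <= 1) ||
      !(excess_early_loss >= 0 && excess_early_loss <= 1))
    abort("probabilities must be in [0, 1]")
  if (!excess_bin %in% return_bins()) abort("unknown excess_bin '%s'", excess_bin)
  if (sum(baseline_return) + excess_early_loss > 1)
    abort("bin probabilities plus excess sum above 1")
  truth <- list(carrier_freq = carrier_freq, baseline_return = baseline_return,
                excess_early_loss = excess_early_loss, excess_bin = excess_bin)
  cols <- c("cow_id", "sire_id", "ai_date", "days_to_2nd_ai",
            "sire_carrier", "cow_carrier")
  if (n_records == 0) {
    rec <- data.frame(cow_id = character(), sire_id = character(),
                      ai_date = character(), days_to_2nd_ai = integer(),
                      sire_carrier = logical(), cow_carrier = logical())
    return(list(records = rec, truth = truth))
  }
  set.seed(derive_seed(seed, "matings"))
  sire_pool_carrier <- rbinom(n_sires, 1, carrier_freq) == 1L
  cow_pool_carrier <- rbinom(n_cows, 1, carrier_freq) == 1L
  sire <- sample.int(n_sires, n_records, replace = TRUE)
  cow <- sample.int(n_cows, n_records, replace = TRUE)
  sire_carrier <- sire_pool_carrier[sire]
  cow_carrier <- cow_pool_carrier[cow]
  risk <- sire_carrier & cow_carrier

  bins <- return_bins()
  base <- setNames(rep(0, length(bins)), bins)
  base[names(baseline_return)] <- baseline_return
  # outcome categories: the 5 bins, then non-return; risk matings move
  # `excess_early_loss` mass from non-return into the excess bin
  p_other <- c(base, non_return = 1 - sum(base))
  p_risk <- p_other
  p_risk[excess_bin] <- p_risk[excess_bin] + excess_early_loss
  p_risk["non_return"] <- p_risk["non_return"] - excess_early_loss
  u <- runif(n_records)
  outcome <- integer(n_records)
  outcome[!risk] <- findInterval(u[!risk], cumsum(p_other)[-6], left.open = TRUE) + 1L
  outcome[risk] <- findInterval(u[risk], cumsum(p_risk)[-6], left.open = TRUE) + 1L

  # uniform day within the drawn bin
  lo <- c(18L, 30L, 61L, 91L, 141L)
  hi <- c(29L, 60L, 90L, 140L, 280L)
  days <- rep(NA_integer_, n_records)
  ret <- outcome <= length(bins)
  days[ret] <- lo[outcome[ret]] +
    floor(runif(sum(ret)) * (hi[outcome[ret]] - lo[outcome[ret]] + 1L))
  ai_date <- as.Date("2015-01-01") + floor(runif(n_records) * 365)
  rec <- data.frame(
    cow_id = sprintf("cow_%06d", cow),
    sire_id = sprintf("sire_%04d", sire),
    ai_date = as.character(ai_date),
    days_to_2nd_ai = days,
    sire_carrier = sire_carrier,
    cow_carrier = cow_carrier)
  list(records = rec[cols], truth = truth)
}

#' Simulate embryo genotypes from carrier x carrier matings
#'
#' Draws embryo genotypes at 1:2:1 from heterozygote x heterozygote
#' matings; risk-allele homozygotes are removed before observation with
#' probability `loss_before_observation` (recessive loss before the
#' developmental stage at which embryos are recovered and genotyped).
#'
#' @param n_embryos number of embryos conceived.
#' @param loss_before_observation probability a risk homozygote is lost
#'   before observation (default 1).
#' @param seed integer seed.
#' @return a [genotype_counts()] of the observed embryos.
#' @export
simulate_embryos <- function(n_embryos, loss_before_observation = 1, seed = 1) {
  if (n_embryos < 0) abort("n_embryos must be >= 0")
  if (!(loss_before_observation >= 0 && loss_before_observation <= 1))
    abort("loss_before_observation must be in [0, 1]")
  if (n_embryos == 0) return(genotype_counts(0, 0, 0))
  set.seed(derive_seed(seed, "embryos"))
  g <- rmultinom(1, n_embryos, c(1, 2, 1) / 4)[, 1]
  lost <- rbinom(1, g[3], loss_before_observation)
  genotype_counts(g[1], g[2], g[3] - lost)
}
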