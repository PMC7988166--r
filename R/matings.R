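#' Return-interval bins
#'
#' The interval from first artificial insemination (AI) to a second AI is
#' grouped into the standard bins used for embryonic-mortality analysis:
#' 18-29, 30-60, 61-90, 91-140 and 141+ days (141 days to parturition).
#' A return before day 18 does not indicate conception failure of the
#' first service and is excluded.
#'
#' @return character vector of bin labels, in order.
#' @export
return_bins <- function() c("18-29", "30-60", "61-90", "91-140", "141+")

#' Bin a days-to-second-AI interval
#'
#' @param days integer vector of days from first to second AI (`NA` for
#'   cows with no second AI, i.e. non-return).
#' @return character vector: a bin label, `"excluded"` for days < 18, or
#'   `"non_return"` for `NA`.
#' @examples
#' bin_return_interval(c(29, 30, 61, 15, NA))
#' @export
bin_return_interval <- function(days) {
  if (any(!is.na(days) & days < 0)) abort("days_to_second_AI must be non-negative")
  out <- rep("non_return", length(days))
  d <- !is.na(days)
  out[d] <- as.character(cut(days[d], breaks = c(18, 30, 61, 91, 141, Inf),
                             labels = return_bins(), right = FALSE))
  out[d & days < 18] <- "excluded"
  out
}

#' Classify a mating by carrier status
#'
#' A mating is a *risk* mating only when both the sire and the cow carry
#' the haplotype of interest; every other pair is *other*.
#'
#' @param sire_carrier,cow_carrier logical vectors.
#' @return character vector, `"risk"` or `"other"` (`NA` when either
#'   status is unknown).
#' @export
classify_mating <- function(sire_carrier, cow_carrier) {
  ifelse(is.na(sire_carrier) | is.na(cow_carrier), NA_character_,
         ifelse(sire_carrier & cow_carrier, "risk", "other"))
}

#' Embryonic-mortality contrast for one return-interval bin
#'
#' Builds the 2x2 table (risk vs other mating) x (second AI within `bin`
#' vs no second AI at all) and computes the bin-specific embryonic
#' mortality percentage, `100 * secondAI / (non_return + secondAI)`, for
#' each group with a chi-square test of association (no continuity
#' correction).  Records whose second AI falls in another bin (or before
#' day 18) are excluded; records with unknown carrier status are dropped
#' with a count.
#'
#' @param records data.frame with columns `days_to_2nd_ai` (`NA` for
#'   non-return), `sire_carrier`, `cow_carrier`.
#' @param bin one of [return_bins()].
#' @param correct logical, apply Yates continuity correction.
#' @param fisher logical, use Fisher's exact test instead of chi-square.
#' @param other_bins how records returning in a different bin enter the
#'   2x2: `"exclude"` (default; the bin contrasts returned-in-bin vs
#'   conceived) or `"non_return"` (pool them with the
#'   no-return-in-this-bin side).
#' @return list of class `mortality_table`: `bin`, counts
#'   (`risk_non_return`, `risk_second_ai`, `other_non_return`,
#'   `other_second_ai`), `mortality_risk`/`mortality_other` (integer
#'   percent), `chi2`, `p`, `n_dropped_unknown`.  The test is skipped
#'   (`chi2`/`p` are `NA`, with a warning) when any expected cell is < 1.
#' @examples
#' \dontrun{
#' mortality_contrast(records, "30-60")
#' }
#' @export
mortality_contrast <- function(records, bin, correct = FALSE, fisher = FALSE,
                               other_bins = c("exclude", "non_return")) {
  if (!bin %in% return_bins()) abort("unknown bin '%s'", bin)
  other_bins <- match.arg(other_bins)
  cls <- classify_mating(records$sire_carrier, records$cow_carrier)
  dropped <- sum(is.na(cls))
  keep <- !is.na(cls)
  records <- records[keep, , drop = FALSE]
  cls <- cls[keep]
  b <- bin_return_interval(records$days_to_2nd_ai)
  if (other_bins == "non_return")
    b[b %in% setdiff(return_bins(), bin)] <- "non_return"
  use <- b %in% c(bin, "non_return")
  cls <- cls[use]
  outcome <- factor(b[use], levels = c("non_return", bin))
  grp <- factor(cls, levels = c("risk", "other"))
  tab <- table(grp, outcome)
  pct <- function(nr, ai) if (nr + ai > 0) round_half_up(100 * ai / (nr + ai)) else NA_real_
  res <- list(
    bin = bin,
    risk_non_return = tab["risk", "non_return"],
    risk_second_ai = tab["risk", bin],
    other_non_return = tab["other", "non_return"],
    other_second_ai = tab["other", bin],
    mortality_risk = pct(tab["risk", "non_return"], tab["risk", bin]),
    mortality_other = pct(tab["other", "non_return"], tab["other", bin]),
    chi2 = NA_real_, p = NA_real_,
    n_dropped_unknown = dropped
  )
  exp_cells <- outer(rowSums(tab), colSums(tab)) / max(1, sum(tab))
  if (sum(tab) > 0 && all(exp_cells >= 1)) {
    if (fisher) {
      ft <- fisher.test(tab)
      res$p <- ft$p.value
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = correct))
      res$chi2 <- unname(ct$statistic)
      res$p <- ct$p.value
    }
  } else {
    warning("expected cell below 1; association test skipped", call. = FALSE)
  }
  class(res) <- "mortality_table"
  res
}

#' @export
print.mortality_table <- function(x, ...) {
  cat(sprintf("Embryonic mortality, 2nd AI at %s days\n", x$bin))
  cat(sprintf("  risk  matings: non-return %d, 2nd AI %d, mortality %s%%\n",
              x$risk_non_return, x$risk_second_ai, x$mortality_risk))
  cat(sprintf("  other matings: non-return %d, 2nd AI %d, mortality %s%%\n",
              x$other_non_return, x$other_second_ai, x$mortality_other))
  if (!is.na(x$p)) cat(sprintf("  chi2 = %.3f, P = %.4g\n", x$chi2, x$p))
  invisible(x)
}
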