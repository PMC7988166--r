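#' Enumerate sliding windows over a panel
#'
#' Yields every within-chromosome window of each size from `k_min` to
#' `k_max`, stepping the start by `step` markers.  No window crosses a
#' chromosome boundary; sizes exceeding a chromosome's marker count are
#' skipped for that chromosome with a log note.
#'
#' @param panel a [phased_panel()], or a marker map data.frame with a
#'   `chrom` column.
#' @param k_min,k_max window sizes in SNPs (defaults 2 and 100).
#' @param step start increment in markers.
#' @param verbose emit log notes for skipped sizes.
#' @return data.frame with columns `chrom`, `start_marker` (1-based,
#'   within chromosome), `k`.
#' @examples
#' m <- data.frame(chrom = "1", pos = 1:5 * 100L, id = paste0("m", 1:5))
#' nrow(enumerate_windows(m, 2, 3))  # 4 + 3 = 7
#' @export
enumerate_windows <- function(panel, k_min = 2, k_max = 100, step = 1, verbose = FALSE) {
  if (!(k_min >= 2 && k_min <= k_max)) abort("need 2 <= k_min <= k_max")
  markers <- if (inherits(panel, "phased_panel")) panel$markers else panel
  out <- list()
  for (ch in unique(markers$chrom)) {
    m <- sum(markers$chrom == ch)
    if (k_max > m && verbose)
      log_kv("skipped_sizes", sprintf("chrom=%s k>%d", ch, m))
    for (k in k_min:min(k_max, m)) {
      starts <- seq.int(1L, m - k + 1L, by = step)
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start_marker = starts, k = k)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start_marker = integer(), k = integer()))
  do.call(rbind, out)
}

#' Haplotype counts in one window
#'
#' Tabulates every distinct haplotype allele string in a window: copy
#' number, frequency, carriers (samples with at least one copy) and
#' homozygotes (samples whose two haplotypes are both the string).
#'
#' @inheritParams window_strings
#' @return data.frame with columns `hap`, `copies`, `q`, `carriers`,
#'   `homozygotes`, sorted by decreasing copies.
#' @export
haplotype_counts <- function(panel, chrom, start_marker, k) {
  hs <- window_strings(panel, chrom, start_marker, k)
  a <- hs[seq(1L, length(hs), by = 2L)]
  b <- hs[seq(2L, length(hs), by = 2L)]
  haps <- sort(unique(hs))
  copies <- as.integer(table(factor(hs, levels = haps)))
  carriers <- vapply(haps, function(h) sum(a == h | b == h), integer(1))
  homs <- vapply(haps, function(h) sum(a == h & b == h), integer(1))
  out <- data.frame(hap = haps, copies = copies, q = copies / length(hs),
                    carriers = unname(carriers), homozygotes = unname(homs))
  out[order(-out$copies, out$hap), , drop = FALSE]
}

#' Binomial homozygote-deficiency test
#'
#' Under random mating, a haplotype at frequency `q` in a census of `N`
#' individuals is expected in `N q^2` homozygotes.  The deficiency
#' p-value is the lower-tail binomial probability of seeing at most the
#' observed number: `P(X <= obs_hom)`, `X ~ Binomial(N, q^2)`.
#'
#' @param q haplotype frequency in \[0, 1\].
#' @param N census size (individuals).
#' @param obs_hom observed homozygote count.
#' @return list with `exp_hom = N * q^2` and `p_deficit`.
#' @examples
#' deficiency_test(0.052, 4843, 0)  # exp ~ 13.1, p ~ 2e-6
#' @export
deficiency_test <- function(q, N, obs_hom) {
  if (any(q < 0 | q > 1)) abort("q must be in [0, 1]")
  if (any(obs_hom > N)) abort("obs_hom cannot exceed N")
  list(exp_hom = N * q^2, p_deficit = pbinom(obs_hom, N, q^2))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order (empty input gives empty output).
#' @export
fdr_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Genome-wide haplotype homozygosity-deficiency scan
#'
#' Slides windows of `k_min`..`k_max` consecutive SNPs across every
#' chromosome of a phased panel and tests each haplotype with frequency
#' at least `min_q` for homozygote deficiency ([deficiency_test()]).
#' Returns the windows significant at `alpha`, each annotated with its
#' Benjamini-Hochberg q-value computed over *all* performed tests
#' (panel-wide, across chromosomes and window sizes).
#'
#' @param panel a [phased_panel()].
#' @param alpha raw p-value significance threshold (default `1e-4`).
#' @param min_q minimum haplotype frequency to test (default 0.01).
#' @param k_min,k_max window sizes in SNPs.
#' @param step start increment in markers.
#' @param verbose emit progress/log lines.
#' @return data.frame of class `window_tests` with one row per
#'   significant (window, haplotype) pair: `chrom`, `start_marker`,
#'   `end_marker` (half-open marker indices within the chromosome), `k`,
#'   `start_pos`, `end_pos` (1-based inclusive bp), `hap`, `q`,
#'   `n_carriers`, `obs_hom`, `exp_hom`, `p_deficit`, `q_value`.
#'   Attributes: `n_tests`, `n_windows`, `markers` (the panel's map),
#'   `N` (census size).
#' @export
scan_haplotypes <- function(panel, alpha = 1e-4, min_q = 0.01,
                            k_min = 2, k_max = 100, step = 1, verbose = FALSE) {
  stopifnot(inherits(panel, "phased_panel"))
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  N <- n_samples(panel)
  chroms <- unique(panel$markers$chrom)
  p_all <- list(); recs <- list(); n_windows <- 0; offset <- 0L
  for (ch in chroms) {
    cols <- chrom_cols(panel, ch)
    if (length(cols) < k_min) next
    H <- panel$haplotypes[, cols, drop = FALSE]
    res <- .scan_chrom_cpp(H, as.integer(k_min), as.integer(min(k_max, length(cols))),
                           as.integer(step), min_q, alpha)
    p_all[[ch]] <- res$p_all
    n_windows <- n_windows + res$n_windows
    if (length(res$start)) {
      pos <- panel$markers$pos[cols]
      recs[[ch]] <- data.frame(
        chrom = ch,
        start_marker = res$start,
        end_marker = res$start + res$k,          # half-open
        k = res$k,
        start_pos = pos[res$start],
        end_pos = pos[res$start + res$k - 1L],
        hap = vapply(seq_along(res$start), function(i) {
          paste(H[res$rep_row[i], res$start[i]:(res$start[i] + res$k[i] - 1L)],
                collapse = "")
        }, character(1)),
        q = res$copies / (2 * N),
        n_carriers = res$carriers,
        obs_hom = res$hom,
        exp_hom = N * (res$copies / (2 * N))^2,
        p_deficit = res$p,
        test_idx = res$test_idx + offset
      )
    }
    offset <- offset + length(res$p_all)
    if (verbose) log_kv(sprintf("chrom_%s_tests", ch), length(res$p_all))
  }
  p_vec <- unlist(p_all, use.names = FALSE)
  if (length(recs)) {
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    qv <- fdr_adjust(p_vec)
    out$q_value <- qv[out$test_idx]
    out$test_idx <- NULL
    out <- out[order(match(out$chrom, chroms), out$start_marker, out$k), , drop = FALSE]
  } else {
    out <- data.frame(chrom = character(), start_marker = integer(),
                      end_marker = integer(), k = integer(),
                      start_pos = integer(), end_pos = integer(),
                      hap = character(), q = numeric(), n_carriers = integer(),
                      obs_hom = integer(), exp_hom = numeric(),
                      p_deficit = numeric(), q_value = numeric())
  }
  if (verbose) {
    log_kv("n_tests", length(p_vec))
    log_kv("n_significant_windows", nrow(out))
  }
  structure(out, n_tests = length(p_vec), n_windows = n_windows,
            markers = panel$markers, N = N,
            class = c("window_tests", "data.frame"))
}

#' Merge significant windows into risk regions
#'
#' Windows whose genomic intervals overlap on the same chromosome are
#' merged transitively (via [IRanges::reduce()]); each merged region is
#' reported with the statistics of its most significant constituent
#' window and named `<prefix>_<chrom>`, with `_1`, `_2` suffixes when a
#' chromosome holds more than one region.
#'
#' A called risk region must be supported by at least `min_windows`
#' overlapping significant windows.  A genuine recessive haplotype
#' spanning L markers is rediscovered by on the order of L^2/2
#' overlapping windows of different sizes and offsets (hundreds, for
#' the 6-157-marker regions typical of such scans), whereas a chance
#' homozygote-free haplotype lineage in a null panel is supported by
#' one or two windows; the support threshold separates the two regimes
#' by two orders of magnitude in either direction.
#'
#' @param windows a `window_tests` data.frame from [scan_haplotypes()]
#'   (or any data.frame with its columns).
#' @param markers marker map used to count markers per merged span;
#'   defaults to the map attached by [scan_haplotypes()].
#' @param prefix region-name prefix (default `"HAP"`).
#' @param min_windows minimum number of overlapping significant windows
#'   supporting a called region (default 10); 1 keeps every merged
#'   interval.
#' @param max_q optional Benjamini-Hochberg q-value gate: only windows
#'   with q-value at or below `max_q` enter region calling (default
#'   `Inf`, i.e. every window in `windows`).
#' @return data.frame with columns `id`, `chrom`, `start_pos`, `end_pos`,
#'   `length` (`end - start`, the convention of haplotype-region tables),
#'   `n_markers`, `n_windows`, plus `q`, `n_carriers`, `obs_hom`,
#'   `exp_hom`, `p_min`, `q_value`, `hap`, `start_marker`, `end_marker`
#'   taken from the best window.
#' @export
merge_regions <- function(windows, markers = attr(windows, "markers"),
                          prefix = "HAP", min_windows = 10, max_q = Inf) {
  empty <- data.frame(id = character(), chrom = character(),
                      start_pos = integer(), end_pos = integer(),
                      length = integer(), n_markers = integer(),
                      n_windows = integer(), q = numeric(),
                      n_carriers = integer(), obs_hom = integer(),
                      exp_hom = numeric(), p_min = numeric(),
                      q_value = numeric(), hap = character(),
                      start_marker = integer(), end_marker = integer())
  if (!nrow(windows)) return(empty)
  windows <- windows[windows$q_value <= max_q, , drop = FALSE]
  if (!nrow(windows)) return(empty)
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = w$start_pos, end = w$end_pos)
    red <- IRanges::reduce(ir)
    hit <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    for (j in seq_along(red)) {
      wj <- w[hit == j, , drop = FALSE]
      best <- wj[which.min(wj$p_deficit), , drop = FALSE]
      sp <- IRanges::start(red)[j]; ep <- IRanges::end(red)[j]
      nm <- if (is.null(markers)) NA_integer_ else
        sum(markers$chrom == ch & markers$pos >= sp & markers$pos <= ep)
      out[[length(out) + 1L]] <- data.frame(
        id = NA_character_, chrom = ch, start_pos = sp, end_pos = ep,
        length = ep - sp, n_markers = nm, n_windows = nrow(wj),
        q = best$q, n_carriers = best$n_carriers, obs_hom = best$obs_hom,
        exp_hom = best$exp_hom, p_min = best$p_deficit, q_value = best$q_value,
        hap = best$hap, start_marker = best$start_marker,
        end_marker = best$end_marker)
    }
  }
  out <- do.call(rbind, out)
  out <- out[out$n_windows >= min_windows, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(match(out$chrom, unique(windows$chrom)), out$start_pos), , drop = FALSE]
  per_chrom <- as.integer(table(out$chrom)[as.character(out$chrom)])
  idx <- stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along)
  out$id <- ifelse(per_chrom > 1L,
                   sprintf("%s_%s_%d", prefix, out$chrom, idx),
                   sprintf("%s_%s", prefix, out$chrom))
  rownames(out) <- NULL
  out
}
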