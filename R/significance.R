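#' Per-window maximum XP-EHH summary
#'
#' Tiles each contig with non-overlapping windows (default 50 kb, the last
#' window truncated at the contig end), keeps windows containing at least one
#' scored SNP, and summarizes each by the maximum normalized score among its
#' SNPs. The literal maximum is used, so a window whose scores are all
#' negative is summarized by its least-negative value; set
#' `positive_only = TRUE` to drop windows with no positive score instead.
#'
#' @param scores data.frame from [xpehh_scores()] (needs `contig`, `pos`,
#'   `z`); rows with `NA` z are ignored.
#' @param contig_lengths named numeric vector of contig lengths.
#' @param window_bp window size (default 50000).
#' @param positive_only drop windows whose maximum is not positive.
#' @return data.frame: `contig`, `start`, `end` (0-based half-open),
#'   `n_snps`, `max_score`.
#' @export
window_max_scores <- function(scores, contig_lengths, window_bp = 50000,
                              positive_only = FALSE) {
  scores <- scores[!is.na(scores$z), , drop = FALSE]
  out <- do.call(rbind, lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(0, len - 1, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    sc <- scores[scores$contig == ctg, , drop = FALSE]
    idx <- findInterval(sc$pos - 1L, starts)
    n <- tabulate(idx, nbins = length(starts))
    mx <- rep(NA_real_, length(starts))
    if (nrow(sc)) {
      agg <- tapply(sc$z, factor(idx, seq_along(starts)), max)
      mx[!is.na(agg)] <- agg[!is.na(agg)]
    }
    data.frame(contig = ctg, start = starts, end = ends, n_snps = n,
               max_score = mx, stringsAsFactors = FALSE)
  }))
  out <- out[out$n_snps > 0L, , drop = FALSE]
  if (positive_only) out <- out[out$max_score > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin windows by SNP density
#'
#' Windows are grouped by their SNP counts in increments of `bin_width`
#' (default 500), with every window holding `pool_from` (default 1000) or
#' more SNPs pooled into a single top bin: bins are `[1, 500)`, `[500, 1000)`
#' and `[1000, Inf)` under the defaults. Each window falls in exactly one
#' bin.
#'
#' @param windows data.frame from [window_max_scores()] (`n_snps >= 1`).
#' @param bin_width SNP-count increment per bin.
#' @param pool_from SNP count at and above which windows share one bin.
#' @return the input with an integer `bin_id` column
#'   (`floor(n_snps / bin_width)`, capped at `pool_from / bin_width`).
#' @export
bin_windows_by_snp_count <- function(windows, bin_width = 500,
                                     pool_from = 1000) {
  stopifnot(all(windows$n_snps >= 1L))
  windows$bin_id <- pmin(windows$n_snps %/% bin_width,
                         pool_from %/% bin_width)
  windows
}

#' SNP-density-binned empirical p-values
#'
#' Within each SNP-density bin, the empirical p-value of window `i` is the
#' fraction of windows in the bin whose summary statistic is strictly greater
#' than window `i`'s: `p_i = #{j in bin : s_j > s_i} / |bin|`. The window
#' itself never counts, so the top window of every bin has `p = 0`, and tied
#' windows share the same p. An optional `(r + 1) / (n + 1)` correction
#' (where `r` is the strict-dominance count) avoids exact zeros but is off by
#' default.
#'
#' @param windows data.frame with `max_score` and `bin_id` columns.
#' @param add_one apply the `(r + 1) / (n + 1)` pseudo-count correction.
#' @return the input with an `empirical_p` column.
#' @export
binned_empirical_pvalues <- function(windows, add_one = FALSE) {
  p <- rep(NA_real_, nrow(windows))
  for (b in unique(windows$bin_id)) {
    in_bin <- which(windows$bin_id == b)
    s <- windows$max_score[in_bin]
    # strict-dominance count via ranks: r_i = #{j: s_j > s_i}
    r <- length(s) - rank(s, ties.method = "max")
    p[in_bin] <- if (add_one) (r + 1) / (length(s) + 1) else r / length(s)
  }
  windows$empirical_p <- p
  windows
}

#' Windows significant under the empirical-p rule
#'
#' @param windows data.frame with `empirical_p` (and `max_score`) columns.
#' @param alpha significance level; windows with `empirical_p < alpha`
#'   (strict) are returned.
#' @return the significant rows, sorted by `empirical_p` then by `max_score`
#'   descending.
#' @export
significant_windows <- function(windows, alpha = 0.005) {
  sig <- windows[!is.na(windows$empirical_p) & windows$empirical_p < alpha, ,
                 drop = FALSE]
  sig[order(sig$empirical_p, -sig$max_score), , drop = FALSE]
}

#' Full window-significance stage for XP-EHH scores
#'
#' @param scores data.frame from [xpehh_scores()].
#' @param contig_lengths named numeric vector.
#' @param window_bp window size in bp.
#' @param bin_width,pool_from see [bin_windows_by_snp_count()].
#' @param alpha significance level (strict).
#' @param positive_only see [window_max_scores()].
#' @return data.frame of windows with `max_score`, `bin_id`, `empirical_p`
#'   and a logical `significant` column.
#' @export
xpehh_window_significance <- function(scores, contig_lengths,
                                      window_bp = 50000, bin_width = 500,
                                      pool_from = 1000, alpha = 0.005,
                                      positive_only = FALSE) {
  w <- window_max_scores(scores, contig_lengths, window_bp, positive_only)
  w <- bin_windows_by_snp_count(w, bin_width, pool_from)
  w <- binned_empirical_pvalues(w)
  w$significant <- w$empirical_p < alpha
  w
}
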