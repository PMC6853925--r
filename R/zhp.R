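#' Parameters for the pooled-heterozygosity (ZHp) scan
#'
#' Defaults: 150 kb windows with 50% overlap, sites with minor allele
#' frequency below 0.05 removed before pooling, windows with fewer than 10
#' SNPs dropped, and candidate windows called at ZHp strictly below -3.5.
#'
#' @param window_bp window span in bp.
#' @param overlap_fraction fractional overlap between consecutive windows
#'   (0 gives abutting windows; must be < 1).
#' @param min_snps minimum SNPs for a window to be retained.
#' @param maf_min sites with MAF < this value are removed before Hp.
#' @param zhp_threshold candidate windows satisfy `zhp < zhp_threshold`.
#' @return a `zhp_params` list.
#' @export
zhp_params <- function(window_bp = 150000, overlap_fraction = 0.5,
                       min_snps = 10, maf_min = 0.05,
                       zhp_threshold = -3.5) {
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1, min_snps >= 1)
  structure(list(window_bp = window_bp, overlap_fraction = overlap_fraction,
                 min_snps = min_snps, maf_min = maf_min,
                 zhp_threshold = zhp_threshold),
            class = "zhp_params")
}

#' Overlapping sliding windows over a set of contigs
#'
#' Windows are anchored at position 0 of each contig and advance by
#' `window_bp * (1 - overlap_fraction)`; the final window is truncated at the
#' contig end. A contig shorter than the window yields a single truncated
#' window. Coordinates are 0-based half-open.
#'
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @param window_bp window span in bp.
#' @param overlap_fraction fractional overlap in [0, 1).
#' @return data.frame: `contig`, `start`, `end`.
#' @export
make_sliding_windows <- function(contig_lengths, window_bp = 150000,
                                 overlap_fraction = 0.5) {
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1)
  step <- window_bp * (1 - overlap_fraction)
  out <- do.call(rbind, lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    # enough windows that the last one reaches the contig end; a contig
    # shorter than the window yields a single truncated window
    n_win <- max(1, ceiling((len - window_bp) / step) + 1)
    starts <- step * (seq_len(n_win) - 1)
    data.frame(contig = ctg, start = starts,
               end = pmin(starts + window_bp, len),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pooled heterozygosity of one window
#'
#' Hp = 2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ) + sum(nMIN))^2, the sums taken
#' over the SNPs whose position lies in the window. Hp depends only on the
#' major/minor split at each site, so it is invariant to swapping ref/alt
#' labels, and attains its maximum 0.5 when the summed major and minor counts
#' are equal.
#'
#' @param count_table an [allele_count_table()] (already restricted to sites
#'   passing the MAF filter).
#' @param window list or one-row data.frame with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param params a [zhp_params()].
#' @return one-row data.frame: window coordinates, `n_snps`, `sum_nmaj`,
#'   `sum_nmin`, `hp`, `retained` (FALSE when `n_snps < min_snps`).
#' @export
window_hp <- function(count_table, window, params = zhp_params()) {
  inw <- count_table$contig == window$contig &
    count_table$pos - 1L >= window$start & count_table$pos - 1L < window$end
  smaj <- sum(count_table$n_maj[inw])
  smin <- sum(count_table$n_min[inw])
  tot <- smaj + smin
  data.frame(contig = window$contig, start = window$start, end = window$end,
             n_snps = sum(inw), sum_nmaj = smaj, sum_nmin = smin,
             hp = if (tot > 0) 2 * smaj * smin / tot^2 else NA_real_,
             retained = sum(inw) >= params$min_snps,
             stringsAsFactors = FALSE)
}

#' Z-transform window Hp values genome-wide
#'
#' ZHp = (Hp - mean(Hp)) / sd(Hp), mean and sample standard deviation
#' (denominator n - 1) taken over all retained windows genome-wide.
#'
#' @param hp_windows data.frame from the Hp stage; only rows with
#'   `retained == TRUE` receive a score.
#' @return the input with a `zhp` column (`NA` for dropped windows).
#' @export
zhp_scores <- function(hp_windows) {
  ret <- hp_windows$retained & !is.na(hp_windows$hp)
  if (sum(ret) < 2L) stop("need at least 2 retained windows")
  m <- mean(hp_windows$hp[ret])
  s <- stats::sd(hp_windows$hp[ret])
  if (s == 0) stop("all retained windows have identical Hp; ZHp undefined")
  hp_windows$zhp <- ifelse(ret, (hp_windows$hp - m) / s, NA_real_)
  hp_windows
}

#' Candidate windows in the extreme low tail of ZHp
#'
#' @param hp_windows data.frame with a `zhp` column.
#' @param threshold windows with `zhp < threshold` (strict) are returned.
#' @return the candidate rows, sorted by `zhp` ascending.
#' @export
extreme_zhp_windows <- function(hp_windows, threshold = -3.5) {
  cand <- hp_windows[!is.na(hp_windows$zhp) & hp_windows$zhp < threshold, ,
                     drop = FALSE]
  cand[order(cand$zhp), , drop = FALSE]
}

#' Full pooled-heterozygosity scan for one population
#'
#' Convenience wrapper: computes the population's allele-count table, removes
#' sites with MAF below `params$maf_min`, evaluates Hp in 50%-overlapping
#' sliding windows, Z-transforms over retained windows, and flags candidates.
#'
#' @param panel a `genotype_panel`.
#' @param population population label.
#' @param params a [zhp_params()].
#' @return data.frame of windows with `hp`, `zhp`, and `candidate` columns.
#' @export
zhp_scan <- function(panel, population, params = zhp_params()) {
  ct <- allele_count_table(panel, population)
  n <- ct$n_maj + ct$n_min
  maf <- ifelse(n > 0, ct$n_min / n, 0)
  ct <- ct[maf >= params$maf_min, , drop = FALSE]
  wins <- make_sliding_windows(panel$contig_lengths, params$window_bp,
                               params$overlap_fraction)
  hp <- do.call(rbind, lapply(seq_len(nrow(wins)), function(i) {
    window_hp(ct, wins[i, ], params)
  }))
  hp <- zhp_scores(hp)
  hp$candidate <- !is.na(hp$zhp) & hp$zhp < params$zhp_threshold
  hp
}
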