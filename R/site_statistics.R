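#' Per-site allele and genotype counts for one population
#'
#' Counts are taken over the called genotypes of the requested population
#' only. `n_maj`/`n_min` are the major/minor allele counts used by the pooled
#' heterozygosity statistic; on a tie (`n_ref == n_alt`) the reference allele
#' is counted as major, which leaves every downstream statistic unchanged
#' because they are symmetric in major/minor.
#'
#' @param panel a `genotype_panel`.
#' @param population population label present in the panel's map.
#' @return data.frame with one row per site: `contig`, `pos`, `n_ref`,
#'   `n_alt`, `n_maj`, `n_min`, `n_het`, `n_hom_ref`, `n_hom_alt`,
#'   `n_called` (called diploid genotypes).
#' @export
allele_count_table <- function(panel, population) {
  g <- panel$genotypes[pop_rows(panel, population), , drop = FALSE]
  n_called <- colSums(!is.na(g))
  n_alt <- colSums(g, na.rm = TRUE)
  n_ref <- 2L * n_called - n_alt
  data.frame(
    contig = panel$sites$contig,
    pos = panel$sites$pos,
    n_ref = n_ref,
    n_alt = n_alt,
    n_maj = pmax(n_ref, n_alt),
    n_min = pmin(n_ref, n_alt),
    n_het = colSums(g == 1L, na.rm = TRUE),
    n_hom_ref = colSums(g == 0L, na.rm = TRUE),
    n_hom_alt = colSums(g == 2L, na.rm = TRUE),
    n_called = n_called,
    stringsAsFactors = FALSE
  )
}

#' Transition/transversion ratio
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' (A<->G, C<->T); every other ref/alt base pair is a transversion. The
#' classification partitions every biallelic SNP into exactly one class.
#'
#' @param x either a `genotype_panel` (classified from its ref/alt columns)
#'   or a numeric vector/list with elements `transitions` and `transversions`
#'   (pre-tabulated counts, e.g. from a published SNP summary table).
#' @return list with `n_transitions`, `n_transversions`, `ratio` (full
#'   precision; `NA` when there are no transversions) and `ratio_2dp`
#'   (rounded to 2 decimals, as quoted in summaries).
#' @export
tstv_ratio <- function(x) {
  if (inherits(x, "genotype_panel")) {
    ts <- sum(is_transition(x$sites$ref, x$sites$alt))
    tv <- nrow(x$sites) - ts
  } else {
    x <- as.list(x)
    ts <- as.numeric(x$transitions)
    tv <- as.numeric(x$transversions)
  }
  ratio <- if (tv == 0) NA_real_ else ts / tv
  list(n_transitions = ts, n_transversions = tv,
       ratio = ratio,
       ratio_2dp = if (is.na(ratio)) NA_real_ else round(ratio, 2))
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Sites fixed for the non-reference allele in a population
#'
#' A site is fixed iff every sample of the population has a called genotype
#' and every genotype is homozygous alternate (dosage 2). Sites with any
#' missing genotype are excluded (strict complete-case rule); the number of
#' such near-miss sites is reported via `message()`.
#'
#' @param panel a `genotype_panel`.
#' @param population population label.
#' @return logical vector, one entry per panel site.
#' @export
detect_fixed_sites <- function(panel, population) {
  g <- panel$genotypes[pop_rows(panel, population), , drop = FALSE]
  all_called <- colSums(is.na(g)) == 0L
  all_hom_alt <- colSums(g == 2L, na.rm = TRUE) == nrow(g) - colSums(is.na(g))
  near_miss <- sum(all_hom_alt & !all_called & colSums(!is.na(g)) > 0)
  if (near_miss > 0) {
    message("detect_fixed_sites: ", near_miss,
            " site(s) homozygous-alt in all called samples but with missing",
            " genotypes; excluded by the strict rule")
  }
  all_called & all_hom_alt & nrow(g) > 0
}

#' Allele frequency from genotype frequencies
#'
#' Converts published genotype frequencies at a biallelic site into the
#' frequency of the focal allele: `freq = f(hom) + f(het)/2`.
#'
#' @param genotype_freqs named numeric vector with elements `hom` (homozygous
#'   for the focal allele), optionally `het`, and optionally `hom_other`;
#'   absent classes default to 0.
#' @param tol tolerance on `sum(freqs) == 1` (table rounding), default 0.02.
#' @return the focal-allele frequency.
#' @export
allele_freq_from_genotypes <- function(genotype_freqs, tol = 0.02) {
  f <- c(hom = 0, het = 0, hom_other = 0)
  f[names(genotype_freqs)] <- genotype_freqs
  if (abs(sum(f) - 1) > tol) {
    stop("genotype frequencies sum to ", sum(f), ", outside 1 +/- ", tol)
  }
  unname(f["hom"] + f["het"] / 2)
}

#' Per-population segregating-site sets and shared/unique tallies
#'
#' A site belongs to a population's segregating set iff its alt-allele count
#' is positive there. For every population pair the tallies
#' `|A only|`, `|B only|` and `|A intersect B|` are reported.
#'
#' @param panel a `genotype_panel`.
#' @param populations character vector of two or more population labels.
#' @return list with `sets` (named list of logical per-site membership) and
#'   `pairs` (data.frame: `pop_a`, `pop_b`, `a_only`, `b_only`, `shared`).
#' @export
population_snp_sets <- function(panel, populations) {
  stopifnot(length(populations) >= 2L)
  sets <- lapply(populations, function(p) {
    allele_count_table(panel, p)$n_alt > 0L
  })
  names(sets) <- populations
  combs <- utils::combn(populations, 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    a <- sets[[combs[1, k]]]
    b <- sets[[combs[2, k]]]
    data.frame(pop_a = combs[1, k], pop_b = combs[2, k],
               a_only = sum(a & !b), b_only = sum(!a & b),
               shared = sum(a & b), stringsAsFactors = FALSE)
  }))
  list(sets = sets, pairs = pairs)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site pi is the unbiased pairwise heterozygosity
#' `2 * n_ref * n_alt / (n * (n - 1))` with `n` the number of called alleles
#' at the site (sites with `n < 2` are skipped). Window pi is the sum of
#' per-site pi over the SNPs in the window divided by the full window length
#' in bp (invariant positions count in the denominator, the convention of
#' standard VCF diversity tools). Windows tile each contig without overlap;
#' the final window is truncated at the contig end.
#'
#' @param panel a `genotype_panel` with known contig lengths.
#' @param population population label.
#' @param window_bp window length in bp (default 10000).
#' @return data.frame of windows: `contig`, `start`, `end` (0-based
#'   half-open), `n_snps`, `pi`; attribute `"mean_pi"` holds the mean
#'   diversity over windows weighted by window length.
#' @export
windowed_pi <- function(panel, population, window_bp = 10000) {
  ct <- allele_count_table(panel, population)
  n <- ct$n_ref + ct$n_alt
  site_pi <- ifelse(n >= 2, 2 * ct$n_ref * ct$n_alt / (n * (n - 1)), NA_real_)
  usable <- !is.na(site_pi)

  out <- do.call(rbind, lapply(names(panel$contig_lengths), function(ctg) {
    len <- panel$contig_lengths[[ctg]]
    starts <- seq(0, len - 1, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    on_ctg <- usable & ct$contig == ctg
    # site at 1-based pos p lies in 0-based half-open window [s, e) iff
    # s < p <= e
    idx <- findInterval(ct$pos[on_ctg] - 1L, starts)
    data.frame(
      contig = ctg, start = starts, end = ends,
      n_snps = tabulate(idx, nbins = length(starts)),
      pi = as.numeric(tapply(site_pi[on_ctg], factor(idx, seq_along(starts)),
                             sum, default = 0)) / (ends - starts),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  w <- out$end - out$start
  attr(out, "mean_pi") <- sum(out$pi * w) / sum(w)
  out
}

#' One-line per-population SNP summary
#'
#' @param panel a `genotype_panel`.
#' @param population population label.
#' @return data.frame with `population`, `n_snps` (segregating in the
#'   population), `ts`, `tv`, `tstv`, `het`, `hom_alt`, `fixed`.
#' @export
population_summary <- function(panel, population) {
  ct <- allele_count_table(panel, population)
  seg <- ct$n_alt > 0L
  sub <- subset_sites(panel, which(seg))
  tt <- tstv_ratio(sub)
  data.frame(
    population = population,
    n_snps = sum(seg),
    ts = tt$n_transitions,
    tv = tt$n_transversions,
    tstv = tt$ratio_2dp,
    het = sum(ct$n_het),
    hom_alt = sum(ct$n_hom_alt),
    fixed = sum(detect_fixed_sites(panel, population)),
    stringsAsFactors = FALSE
  )
}
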