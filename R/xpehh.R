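#' Parameters for the XP-EHH scan
#'
#' @param stop_cutoff EHH level at which haplotype extension stops and the
#'   integral is truncated (default 0.05).
#' @param min_haplotypes minimum phased haplotypes required per population.
#' @param exclude_truncated drop cores whose extension hit a contig end
#'   before EHH decayed below `stop_cutoff` from the normalization (they are
#'   still reported, flagged, with `z = NA`).
#' @return an `xpehh_params` list.
#' @export
xpehh_params <- function(stop_cutoff = 0.05, min_haplotypes = 4,
                         exclude_truncated = TRUE) {
  stopifnot(stop_cutoff > 0, stop_cutoff < 1, min_haplotypes >= 2)
  structure(list(stop_cutoff = stop_cutoff,
                 min_haplotypes = min_haplotypes,
                 exclude_truncated = exclude_truncated),
            class = "xpehh_params")
}

#' Extended haplotype homozygosity decay from a core SNP
#'
#' Haplotypes are grouped by their allele string over the interval from the
#' core out to each flanking marker (the core allele included); EHH at a
#' marker is the probability that two randomly drawn haplotypes are identical
#' over that interval, `sum(choose(n_g, 2)) / choose(n, 2)`. EHH is 1 at the
#' core (distance 0) and non-increasing with distance.
#'
#' The returned curve records only markers at which EHH actually drops (a
#' marker that splits no haplotype group — e.g. a monomorphic site — adds no
#' point), so the integral over the curve is invariant to inserting
#' uninformative markers. Extension stops once EHH falls below `stop_cutoff`
#' (the sub-cutoff point is recorded for interpolation) or at the end of the
#' marker list, in which case `truncated` is `TRUE`.
#'
#' @param haplotypes 0/1 matrix, haplotypes in rows, sites in columns
#'   (columns in position order).
#' @param positions bp position of each column.
#' @param core_index column index of the core SNP.
#' @param direction `"left"` or `"right"`.
#' @param stop_cutoff EHH stop level.
#' @return list with `core_index`, `direction`, `distance` (bp from core,
#'   starting at 0), `pos`, `ehh` (starting at 1), `truncated`.
#' @export
ehh_curve <- function(haplotypes, positions, core_index,
                      direction = c("right", "left"), stop_cutoff = 0.05) {
  direction <- match.arg(direction)
  n <- nrow(haplotypes)
  if (n < 2L) stop("need at least 2 haplotypes")
  markers <- if (direction == "right") {
    seq_len(ncol(haplotypes))[-seq_len(core_index)]
  } else {
    rev(seq_len(core_index - 1L))
  }
  g <- haplotypes[, core_index]
  dist <- 0
  ehh <- 1
  pos <- positions[core_index]
  prev <- 1
  truncated <- TRUE
  denom <- n * (n - 1) / 2
  for (m in markers) {
    g <- match(g * 2L + haplotypes[, m], unique(g * 2L + haplotypes[, m]))
    cnt <- tabulate(g)
    e <- sum(cnt * (cnt - 1) / 2) / denom
    if (e < prev) {
      dist <- c(dist, abs(positions[m] - positions[core_index]))
      pos <- c(pos, positions[m])
      ehh <- c(ehh, e)
      prev <- e
    }
    if (e < stop_cutoff) {
      truncated <- FALSE
      break
    }
  }
  list(core_index = core_index, direction = direction,
       distance = dist, pos = pos, ehh = ehh, truncated = truncated)
}

# Trapezoidal area under one EHH decay curve out to the point where it
# crosses `cutoff` (linearly interpolated); integrates the full recorded
# extent when the curve never crosses (truncated side). An optional `bound`
# in bp caps the integration range (used for pooled-population shared
# bounds), with the curve value at the bound linearly interpolated.
ehh_area <- function(dist, ehh, cutoff, bound = Inf) {
  stopifnot(length(dist) == length(ehh))
  if (length(dist) < 2L) return(0)
  # clip at the bp bound first
  if (is.finite(bound) && bound < dist[length(dist)]) {
    i <- which(dist > bound)[1]
    frac <- (bound - dist[i - 1]) / (dist[i] - dist[i - 1])
    e_at <- ehh[i - 1] + frac * (ehh[i] - ehh[i - 1])
    dist <- c(dist[seq_len(i - 1)], bound)
    ehh <- c(ehh[seq_len(i - 1)], e_at)
  }
  below <- which(ehh < cutoff)
  if (length(below)) {
    i <- below[1]
    if (i == 1L) return(0)
    x_cross <- dist[i - 1] + (ehh[i - 1] - cutoff) / (ehh[i - 1] - ehh[i]) *
      (dist[i] - dist[i - 1])
    dist <- c(dist[seq_len(i - 1)], x_cross)
    ehh <- c(ehh[seq_len(i - 1)], cutoff)
  }
  if (length(dist) < 2L) return(0)
  sum(diff(dist) * (utils::head(ehh, -1) + utils::tail(ehh, -1)) / 2)
}

#' Integrated EHH (iHH) from a pair of decay curves
#'
#' Trapezoidal area under EHH versus physical distance, both directions
#' summed. Each side is integrated out to the first point where its EHH falls
#' below `cutoff`, with the crossing distance interpolated linearly; a side
#' that never decays below the cutoff (contig end reached) contributes its
#' full recorded area and marks the result truncated. A side with no flanking
#' markers contributes 0.
#'
#' @param left_curve,right_curve curves from [ehh_curve()] sharing a core.
#' @param cutoff integration stop level (default 0.05).
#' @return list with `ihh` (bp x EHH units) and `truncated`.
#' @export
integrate_ihh <- function(left_curve, right_curve, cutoff = 0.05) {
  stopifnot(left_curve$core_index == right_curve$core_index)
  area <- ehh_area(left_curve$distance, left_curve$ehh, cutoff) +
    ehh_area(right_curve$distance, right_curve$ehh, cutoff)
  list(ihh = area,
       truncated = left_curve$truncated || right_curve$truncated)
}

#' Cross-population XP-EHH scores for every core SNP
#'
#' For each core SNP, EHH decay is computed separately in the observed and
#' reference populations over all haplotypes of each population. Integration
#' bounds are shared: both populations are integrated out to the distance at
#' which the EHH of the pooled sample (all haplotypes of both populations)
#' drops below `stop_cutoff`, interpolated linearly. The raw score is
#' `ln(iHH_obs / iHH_ref)`; z-scores are normalized to mean 0 and sample
#' standard deviation 1 over all non-truncated, finite raw scores. Cores
#' whose pooled extension hits a contig end before decaying below the cutoff
#' are flagged `truncated` and, by default, excluded from the normalization
#' (`z = NA`).
#'
#' @param panel a phased `genotype_panel` (see [pseudo_phase()] for unphased
#'   input).
#' @param obs_pop population scanned for sweeps (numerator).
#' @param ref_pop reference population (denominator).
#' @param params an [xpehh_params()].
#' @param normalize compute z-scores (default); set `FALSE` to return raw
#'   log-ratios only (`z = NA`), e.g. for degenerate inputs with constant
#'   raw score.
#' @return data.frame: `contig`, `pos`, `ihh_obs`, `ihh_ref`, `raw`, `z`,
#'   `truncated`, one row per polymorphic core SNP.
#' @export
xpehh_scores <- function(panel, obs_pop, ref_pop, params = xpehh_params(),
                         normalize = TRUE) {
  if (is.null(panel$haplotypes)) {
    stop("panel is unphased; phase the data or apply pseudo_phase() first")
  }
  rows_obs <- pop_hap_rows(panel, obs_pop)
  rows_ref <- pop_hap_rows(panel, ref_pop)
  if (length(rows_obs) < params$min_haplotypes ||
      length(rows_ref) < params$min_haplotypes) {
    stop("fewer than ", params$min_haplotypes, " haplotypes in a population")
  }
  out <- do.call(rbind, lapply(unique(panel$sites$contig), function(ctg) {
    on_ctg <- which(panel$sites$contig == ctg)
    h <- panel$haplotypes[, on_ctg, drop = FALSE]
    pos <- panel$sites$pos[on_ctg]
    poly <- which(colSums(h) > 0L & colSums(h) < nrow(h))
    if (!length(poly)) return(NULL)
    sc <- .xpehh_scan_cpp(h, as.numeric(pos), poly, rows_obs, rows_ref,
                          params$stop_cutoff)
    data.frame(contig = ctg, pos = pos[poly], ihh_obs = sc[, 1],
               ihh_ref = sc[, 2],
               raw = ifelse(sc[, 1] > 0 & sc[, 2] > 0,
                            log(sc[, 1] / sc[, 2]), NA_real_),
               truncated = sc[, 3] > 0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!normalize) {
    out$z <- NA_real_
    return(out)
  }
  scored <- is.finite(out$raw) &
    (!params$exclude_truncated | !out$truncated)
  if (sum(scored) < 2L) stop("fewer than 2 scorable cores")
  m <- mean(out$raw[scored])
  s <- stats::sd(out$raw[scored])
  if (s == 0) stop("raw XP-EHH scores are constant; z undefined")
  out$z <- ifelse(scored, (out$raw - m) / s, NA_real_)
  out
}

# One core: walk out in each direction updating pooled and per-population
# haplotype groupings together, record drops of the POOLED curve, then
# integrate each population's EHH out to the pooled cutoff crossing.
xpehh_one_core <- function(h, pos, core, rows_obs, rows_ref, cutoff) {
  side <- function(direction) {
    markers <- if (direction == "right") {
      seq_len(ncol(h))[-seq_len(core)]
    } else {
      rev(seq_len(core - 1L))
    }
    n_all <- nrow(h)
    pair_frac <- function(g) {
      cnt <- tabulate(g)
      sum(cnt * (cnt - 1)) / 2
    }
    d_all <- n_all * (n_all - 1) / 2
    d_obs <- length(rows_obs) * (length(rows_obs) - 1) / 2
    d_ref <- length(rows_ref) * (length(rows_ref) - 1) / 2
    g <- match(h[, core], unique(h[, core]))
    dist <- 0
    e_all <- 1
    e_obs <- 1
    e_ref <- 1
    prev <- 1
    truncated <- TRUE
    for (m in markers) {
      key <- g * 2L + h[, m]
      g <- match(key, unique(key))
      e <- pair_frac(g) / d_all
      if (e < prev) {
        dist <- c(dist, abs(pos[m] - pos[core]))
        e_all <- c(e_all, e)
        e_obs <- c(e_obs, pair_frac(match(g[rows_obs],
                                          unique(g[rows_obs]))) / d_obs)
        e_ref <- c(e_ref, pair_frac(match(g[rows_ref],
                                          unique(g[rows_ref]))) / d_ref)
        prev <- e
      }
      if (e < cutoff) {
        truncated <- FALSE
        break
      }
    }
    list(dist = dist, e_all = e_all, e_obs = e_obs, e_ref = e_ref,
         truncated = truncated)
  }

  total <- function(s) {
    # shared bound: distance where the pooled curve crosses the cutoff
    bound <- Inf
    below <- which(s$e_all < cutoff)
    if (length(below)) {
      i <- below[1]
      bound <- s$dist[i - 1] +
        (s$e_all[i - 1] - cutoff) / (s$e_all[i - 1] - s$e_all[i]) *
        (s$dist[i] - s$dist[i - 1])
    }
    list(obs = ehh_area(s$dist, s$e_obs, cutoff = 0, bound = bound),
         ref = ehh_area(s$dist, s$e_ref, cutoff = 0, bound = bound),
         truncated = s$truncated)
  }
  L <- total(side("left"))
  R <- total(side("right"))
  ihh_obs <- L$obs + R$obs
  ihh_ref <- L$ref + R$ref
  list(ihh_obs = ihh_obs, ihh_ref = ihh_ref,
       raw = if (ihh_obs > 0 && ihh_ref > 0) log(ihh_obs / ihh_ref)
             else NA_real_,
       truncated = L$truncated || R$truncated)
}

#' Deterministic pseudo-phasing of an unphased panel
#'
#' Assigns the two alleles of each heterozygous genotype to the sample's two
#' haplotypes uniformly at random under a caller-supplied seed (missing
#' genotypes become homozygous reference). This destroys true haplotype
#' structure beyond what linkage in the genotypes implies and is intended
#' only to make the haplotype machinery runnable on unphased input; results
#' on pseudo-phased data underestimate long-range homozygosity.
#'
#' @param panel a `genotype_panel` without haplotypes.
#' @param seed integer seed making the assignment reproducible.
#' @return the panel with a `haplotypes` matrix.
#' @export
pseudo_phase <- function(panel, seed) {
  if (!is.null(panel$haplotypes)) return(panel)
  g <- panel$genotypes
  g[is.na(g)] <- 0L
  n <- nrow(g)
  h <- matrix(0L, nrow = 2L * n, ncol = ncol(g))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  flip <- matrix(stats::runif(length(g)) < 0.5, nrow = n)
  a1 <- (g == 2L) | (g == 1L & flip)
  a2 <- (g == 2L) | (g == 1L & !flip)
  h[seq(1L, 2L * n, 2L), ] <- as.integer(a1)
  h[seq(2L, 2L * n, 2L), ] <- as.integer(a2)
  panel$genotypes <- g
  panel$haplotypes <- h
  validate_panel(panel)
  panel
}
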