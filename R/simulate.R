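#' Parameters for the two-population forward simulator
#'
#' The simulator produces phased diploid panels for two diverged populations
#' by transparent forward-in-time evolution: a single founder pool
#' accumulates mutations and recombines for the first half of
#' `n_generations` (shared burn-in), then two copies of the pool evolve
#' independently for the second half, creating divergence by drift. One
#' crossover per meiosis is placed uniformly (with probability
#' `min(1, recombination_rate * contig_length)`), which generates the
#' linkage structure the haplotype scans rely on. Defaults describe the
#' condition used throughout this package's analyses: one 2 Mb contig,
#' 12 + 10 diploid samples (an isolated island population versus a larger
#' managed one), and rates scaled up so that a desk-size contig carries
#' roughly one SNP per kb.
#'
#' @param n_samples named integer vector: diploid sample count per
#'   population; names are the population labels.
#' @param contig_length numeric vector of contig lengths in bp (named, or
#'   auto-named `chr1`, `chr2`, ...).
#' @param n_generations total generations (first half shared burn-in, second
#'   half independent evolution).
#' @param mutation_rate per bp per generation per haplotype.
#' @param recombination_rate per bp per generation (one uniform crossover per
#'   meiosis with probability `rate * length`, capped at 1).
#' @param founder_haplotypes haplotype pool size per population (must be at
#'   least `2 * max(n_samples)`).
#' @param seed integer seed; identical parameters and seed give identical
#'   output.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_samples = c(island = 12, mainland = 10),
                       contig_length = 2e6,
                       n_generations = 400,
                       mutation_rate = 3e-6,
                       recombination_rate = 5e-7,
                       founder_haplotypes = 40,
                       seed = 1) {
  if (is.null(names(contig_length))) {
    names(contig_length) <- paste0("chr", seq_along(contig_length))
  }
  stopifnot(length(n_samples) == 2, !is.null(names(n_samples)),
            mutation_rate >= 0, recombination_rate >= 0,
            founder_haplotypes >= 2 * max(n_samples))
  structure(list(n_samples = n_samples, contig_length = contig_length,
                 n_generations = n_generations,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 founder_haplotypes = founder_haplotypes, seed = seed),
            class = "sim_params")
}

# Evolve a haplotype pool one generation: random-mating reproduction with at
# most one uniform crossover per offspring, then Poisson mutation at fresh
# positions drawn from `draw_pos`, then pruning of lost (all-ancestral)
# columns. H has haplotypes in rows; P holds (unsorted) column positions.
evolve_generation <- function(H, P, L, mu, rho, draw_pos) {
  n <- nrow(H)
  p1 <- sample.int(n, n, replace = TRUE)
  p2 <- sample.int(n, n, replace = TRUE)
  cross <- stats::runif(n) < min(1, rho * L)
  u <- ifelse(cross, stats::runif(n, 0, L), Inf)
  child <- H[p2, , drop = FALSE]
  if (length(P)) {
    mask <- outer(u, P, ">")          # TRUE: inherit from parent 1
    A <- H[p1, , drop = FALSE]
    child[mask] <- A[mask]
  }
  k <- stats::rpois(1, n * mu * L)
  if (k > 0) {
    newcols <- matrix(0L, n, k)
    newcols[cbind(sample.int(n, k, replace = TRUE), seq_len(k))] <- 1L
    child <- cbind(child, newcols)
    P <- c(P, draw_pos(k))
  }
  seg <- colSums(child) > 0L
  list(H = child[, seg, drop = FALSE], P = P[seg])
}

#' Simulate a neutral two-population phased panel
#'
#' Runs the forward model of [sim_params()] on every contig, samples
#' `2 * n_samples` haplotypes per population from the final pools, pairs them
#' into diploid individuals, and assembles a phased [genotype_panel()] over
#' the union of sites segregating in the sample. Reference alleles are the
#' ancestral state; ref/alt bases are drawn with a 2:1 transition bias so
#' the synthetic panel shows a realistic genome-wide Ts/Tv ratio. QUAL and
#' QD/MQ/FS INFO metrics are synthesized within passing ranges
#' (`contaminate_fraction` plants sites with failing metrics to exercise the
#' hard filters).
#'
#' @param params a [sim_params()].
#' @param contaminate_fraction fraction of sites given a failing QD/MQ/FS or
#'   QUAL value (default 0).
#' @return a phased `genotype_panel`.
#' @export
simulate_neutral_panel <- function(params, contaminate_fraction = 0) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(params$seed)

  pops <- names(params$n_samples)
  n_hap_out <- 2L * params$n_samples
  per_contig <- lapply(names(params$contig_length), function(ctg) {
    L <- params$contig_length[[ctg]]
    used <- new.env(parent = emptyenv())
    used$taken <- logical(L)
    draw_pos <- function(k) {
      out <- integer(0)
      while (length(out) < k) {
        cand <- sample.int(L, k - length(out), replace = TRUE)
        cand <- unique(cand[!used$taken[cand]])
        used$taken[cand] <- TRUE
        out <- c(out, cand)
      }
      out
    }
    g_burn <- params$n_generations %/% 2L
    g_split <- params$n_generations - g_burn
    pool <- list(H = matrix(0L, params$founder_haplotypes, 0), P = integer(0))
    for (i in seq_len(g_burn)) {
      pool <- evolve_generation(pool$H, pool$P, L, params$mutation_rate,
                                params$recombination_rate, draw_pos)
    }
    final <- lapply(pops, function(p) {
      branch <- pool
      for (i in seq_len(g_split)) {
        branch <- evolve_generation(branch$H, branch$P, L,
                                    params$mutation_rate,
                                    params$recombination_rate, draw_pos)
      }
      rows <- sample.int(nrow(branch$H), n_hap_out[[p]])
      list(H = branch$H[rows, , drop = FALSE], P = branch$P)
    })
    names(final) <- pops

    # union of positions segregating in either population's sample
    seg_pos <- sort(unique(unlist(lapply(final, function(f) {
      f$P[colSums(f$H) > 0L]
    }))))
    if (!length(seg_pos)) return(NULL)
    hap <- matrix(0L, sum(n_hap_out), length(seg_pos))
    offset <- 0L
    for (p in pops) {
      idx <- match(final[[p]]$P, seg_pos)
      keep <- !is.na(idx)
      hap[offset + seq_len(n_hap_out[[p]]), idx[keep]] <-
        final[[p]]$H[, keep, drop = FALSE]
      offset <- offset + n_hap_out[[p]]
    }
    list(contig = ctg, pos = seg_pos, hap = hap)
  })
  per_contig <- Filter(Negate(is.null), per_contig)
  if (!length(per_contig)) {
    stop("simulation produced zero segregating sites; increase ",
         "mutation_rate or n_generations")
  }

  hap <- do.call(cbind, lapply(per_contig, `[[`, "hap"))
  n_site <- ncol(hap)
  # haplotypes are stacked per population; consecutive row pairs form the
  # diploid individuals, matching the panel's 2s-1/2s convention
  dosage <- hap[seq(1L, nrow(hap), 2L), , drop = FALSE] +
    hap[seq(2L, nrow(hap), 2L), , drop = FALSE]

  ref <- sample(c("A", "C", "G", "T"), n_site, replace = TRUE)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  is_ts <- stats::runif(n_site) < 2 / 3
  alt <- ifelse(is_ts, transition[ref],
                vapply(ref, function(b) sample(transversions[[b]], 1),
                       character(1)))

  qual <- round(stats::runif(n_site, 100, 1000), 2)
  qd <- round(stats::runif(n_site, 10, 30), 2)
  mq <- round(stats::runif(n_site, 50, 60), 2)
  fs <- round(stats::runif(n_site, 0, 20), 3)
  if (contaminate_fraction > 0) {
    bad <- which(stats::runif(n_site) < contaminate_fraction)
    which_metric <- sample(4, length(bad), replace = TRUE)
    qd[bad[which_metric == 1]] <- round(stats::runif(sum(which_metric == 1),
                                                     0, 4.9), 2)
    mq[bad[which_metric == 2]] <- round(stats::runif(sum(which_metric == 2),
                                                     10, 39.9), 2)
    fs[bad[which_metric == 3]] <- round(stats::runif(sum(which_metric == 3),
                                                     201, 400), 2)
    qual[bad[which_metric == 4]] <- round(stats::runif(sum(which_metric == 4),
                                                       1, 29.9), 2)
  }

  sites <- data.frame(
    contig = rep(vapply(per_contig, `[[`, character(1), "contig"),
                 vapply(per_contig, function(x) length(x$pos), integer(1))),
    pos = unlist(lapply(per_contig, `[[`, "pos")),
    id = ".",
    ref = unname(ref), alt = unname(alt),
    qual = qual, qd = qd, mq = mq, fs = fs,
    stringsAsFactors = FALSE
  )
  sample_ids <- unlist(lapply(pops, function(p) {
    sprintf("%s_%02d", p, seq_len(params$n_samples[[p]]))
  }))
  pop_map <- stats::setNames(rep(pops, params$n_samples), sample_ids)
  genotype_panel(sites, dosage, sample_ids, pop_map,
                 params$contig_length, haplotypes = hap)
}

#' Inject a hard selective sweep into a phased panel
#'
#' Copies one donor haplotype's alleles over the interval
#' `[core_pos - halo, core_pos + halo]` (clipped to the contig) into a
#' fraction `carrier_freq` of the target population's haplotypes, chosen by
#' seeded sampling. This produces the sweep signal the scans look for — a
#' long shared haplotype at high frequency with locally depressed
#' heterozygosity — together with an exact truth interval.
#'
#' @param panel a phased `genotype_panel`.
#' @param population population receiving the sweep.
#' @param core_pos sweep core position (bp, 1-based).
#' @param carrier_freq fraction of the population's haplotypes carrying the
#'   sweep haplotype, in (0, 1].
#' @param halo half-width in bp of the copied haplotype.
#' @param contig contig carrying the sweep (default: first contig).
#' @param seed seed for the carrier choice.
#' @return list with `panel` (modified) and `truth`: a list with `contig`,
#'   `start`, `end` (0-based half-open, clipped), `population`,
#'   `carrier_haplotypes` (row indices).
#' @export
inject_sweep <- function(panel, population, core_pos, carrier_freq = 0.9,
                         halo = 150000, contig = names(panel$contig_lengths)[1],
                         seed = 1) {
  if (is.null(panel$haplotypes)) stop("panel must be phased")
  stopifnot(carrier_freq > 0, carrier_freq <= 1)
  L <- panel$contig_lengths[[contig]]
  stopifnot(core_pos >= 1, core_pos <= L)
  lo <- core_pos - halo
  hi <- core_pos + halo
  if (lo < 1 || hi > L) {
    message("inject_sweep: halo clipped to contig bounds")
    lo <- max(1, lo)
    hi <- min(L, hi)
  }
  in_halo <- which(panel$sites$contig == contig &
                     panel$sites$pos >= lo & panel$sites$pos <= hi)
  rows <- pop_hap_rows(panel, population)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  donor <- sample(rows, 1)
  n_carrier <- max(1L, round(carrier_freq * length(rows)))
  carriers <- sample(rows, n_carrier)

  h <- panel$haplotypes
  h[carriers, in_halo] <- rep(h[donor, in_halo], each = length(carriers))
  panel$haplotypes <- h
  # re-derive dosages for the affected samples
  panel$genotypes <- h[seq(1L, nrow(h), 2L), , drop = FALSE] +
    h[seq(2L, nrow(h), 2L), , drop = FALSE]
  rownames(panel$genotypes) <- panel$sample_ids
  validate_panel(panel)
  truth <- list(contig = contig, start = lo - 1, end = hi,
                population = population, carrier_haplotypes = sort(carriers))
  list(panel = panel, truth = truth)
}

#' Build the default sweep fixture
#'
#' One 2 Mb contig, 12 + 10 diploids, a hard sweep in the island population
#' at the contig midpoint with carrier frequency 0.9 and a 150 kb halo.
#' Everything is deterministic in `seed`.
#'
#' @param seed integer seed.
#' @param contaminate_fraction passed to [simulate_neutral_panel()].
#' @return list with `panel`, `truth` and the `params` used.
#' @export
simulate_sweep_fixture <- function(seed = 1, contaminate_fraction = 0) {
  params <- sim_params(seed = seed)
  panel <- simulate_neutral_panel(params, contaminate_fraction)
  sw <- inject_sweep(panel, population = names(params$n_samples)[1],
                     core_pos = 1e6, carrier_freq = 0.9, halo = 150000,
                     seed = seed + 1000L)
  c(sw, list(params = params))
}

#' Export a simulated fixture to disk
#'
#' Writes the panel as a plain-text VCF, the population map, a truth BED
#' (one record per sweep), a synthetic gene-interval BED (30 kb genes tiled
#' every 50 kb on each contig) and a JSON manifest holding the simulation
#' parameters and seed, from which the fixture can be regenerated
#' byte-identically.
#'
#' @param panel a `genotype_panel`.
#' @param truth truth list from [inject_sweep()], or `NULL` for a neutral
#'   panel (empty truth BED).
#' @param out_dir output directory (created if absent).
#' @param params the [sim_params()] used (stored in the manifest).
#' @return named character vector of the file paths written.
#' @export
export_fixture <- function(panel, truth, out_dir, params = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(out_dir, "panel.vcf"),
    popmap = file.path(out_dir, "popmap.txt"),
    truth = file.path(out_dir, "truth.bed"),
    genes = file.path(out_dir, "genes.bed"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_vcf(panel, paths[["vcf"]])
  writeLines(paste(panel$sample_ids, panel$pop_map[panel$sample_ids],
                   sep = "\t"), paths[["popmap"]])
  if (is.null(truth)) {
    writeLines(character(0), paths[["truth"]])
  } else {
    writeLines(paste(truth$contig,
                     format(truth$start, scientific = FALSE, trim = TRUE),
                     format(truth$end, scientific = FALSE, trim = TRUE),
                     paste0("sweep_", truth$population), sep = "\t"),
               paths[["truth"]])
  }
  genes <- synthetic_genes(panel$contig_lengths)
  writeLines(paste(genes$contig,
                   format(genes$start, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$gene_id, sep = "\t"), paths[["genes"]])
  params_out <- unclass(params)
  if (!is.null(params_out$n_samples)) {
    # named vectors serialize to JSON arrays; store them as objects
    params_out$n_samples <- as.list(params_out$n_samples)
    params_out$contig_length <- as.list(params_out$contig_length)
  }
  manifest <- list(params = params_out, truth = truth,
                   n_sites = n_sites(panel))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' Synthetic gene annotation tiled along contigs
#'
#' One 30 kb gene every 50 kb, named `<contig>_g<k>`; purely synthetic
#' intervals used to exercise gene-overlap reporting on simulated data.
#'
#' @param contig_lengths named numeric vector.
#' @return data.frame: `contig`, `start`, `end` (0-based half-open),
#'   `gene_id`, `strand`.
#' @export
synthetic_genes <- function(contig_lengths) {
  out <- do.call(rbind, lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(10000, len - 40000, by = 50000)
    data.frame(contig = ctg, start = starts, end = starts + 30000,
               gene_id = sprintf("%s_g%03d", ctg, seq_along(starts)),
               strand = rep(c("+", "-"), length.out = length(starts)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
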