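#' Configuration for a full selection-scan run
#'
#' @param vcf input VCF path (ignored when `panel` is supplied directly to
#'   [run_pipeline()]).
#' @param popmap population-map path.
#' @param known_sites optional known-sites file for the novel/known report.
#' @param genes optional gene-interval BED/GFF3 for region annotation.
#' @param obs_pop,ref_pop populations scanned/used as reference; default:
#'   first and second label of the population map, in order of appearance.
#' @param filters a [filter_config()].
#' @param zhp a [zhp_params()].
#' @param xpehh an [xpehh_params()].
#' @param sig_window_bp,sig_bin_width,sig_pool_from,sig_alpha
#'   window-significance settings (see [xpehh_window_significance()]).
#' @param pi_window_bp nucleotide-diversity window size.
#' @param out_dir output directory.
#' @param seed seed recorded in the run summary and used for any stochastic
#'   step (pseudo-phasing).
#' @return a `run_config` list.
#' @export
run_config <- function(vcf = NULL, popmap = NULL, known_sites = NULL,
                       genes = NULL, obs_pop = NULL, ref_pop = NULL,
                       filters = filter_config(), zhp = zhp_params(),
                       xpehh = xpehh_params(), sig_window_bp = 50000,
                       sig_bin_width = 500, sig_pool_from = 1000,
                       sig_alpha = 0.005, pi_window_bp = 10000,
                       out_dir = "sweepscan_out", seed = 1) {
  structure(list(vcf = vcf, popmap = popmap, known_sites = known_sites,
                 genes = genes, obs_pop = obs_pop, ref_pop = ref_pop,
                 filters = filters, zhp = zhp, xpehh = xpehh,
                 sig_window_bp = sig_window_bp, sig_bin_width = sig_bin_width,
                 sig_pool_from = sig_pool_from, sig_alpha = sig_alpha,
                 pi_window_bp = pi_window_bp, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full selection-scan pipeline
#'
#' Stages, in order: read (or take) the panel; apply hard site filters;
#' per-population site statistics (Ts/Tv, het/hom, fixed sites, windowed
#' nucleotide diversity, shared/unique sites, optional known/novel report);
#' ZHp scan of the observed population; XP-EHH scan of observed versus
#' reference; 50 kb window significance with SNP-density-binned empirical
#' p-values; candidate-region merging with gene annotation and gene-level
#' method overlap. All tables are written as TSV under `config$out_dir`
#' together with a JSON run summary of the counts at every stage and a
#' Manhattan-ready table.
#'
#' @param config a [run_config()].
#' @param panel optionally a ready-made `genotype_panel` (skips the VCF
#'   stage).
#' @return invisibly, a list with the panel, every stage table, and the run
#'   summary.
#' @export
run_pipeline <- function(config, panel = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  summary <- list(seed = config$seed)

  if (is.null(panel)) {
    if (is.null(config$vcf) || is.null(config$popmap)) {
      stop("config error: vcf and popmap are required when no panel is given")
    }
    panel <- read_vcf(config$vcf, config$popmap)
  }
  pops <- unique(unname(panel$pop_map[panel$sample_ids]))
  obs <- if (is.null(config$obs_pop)) pops[1] else config$obs_pop
  ref <- if (is.null(config$ref_pop)) pops[2] else config$ref_pop
  summary$populations <- list(observed = obs, reference = ref)
  summary$sites_in <- n_sites(panel)

  ## stage: hard filters
  panel <- apply_site_filters(panel, config$filters)
  summary$filter_counts <- as.list(attr(panel, "filter_counts"))
  summary$sites_filtered <- n_sites(panel)
  write_vcf(panel, out("filtered.vcf"))

  ## stage: site statistics
  pop_stats <- do.call(rbind, lapply(c(obs, ref), function(p) {
    population_summary(panel, p)
  }))
  write_table(pop_stats, out("population_summary.tsv"))
  sets <- population_snp_sets(panel, c(obs, ref))
  write_table(sets$pairs, out("snp_set_tallies.tsv"))
  pi_obs <- windowed_pi(panel, obs, config$pi_window_bp)
  write_table(pi_obs, out("pi_windows.tsv"))
  summary$mean_pi <- attr(pi_obs, "mean_pi")
  summary$tstv <- pop_stats$tstv[1]
  if (!is.null(config$known_sites)) {
    kn <- classify_known_novel(panel, read_known_sites(config$known_sites))
    summary$known_novel <- kn[c("known_count", "novel_count",
                                "novel_fraction")]
  }

  ## stage: ZHp scan
  zhp <- zhp_scan(panel, obs, config$zhp)
  write_table(zhp, out("zhp_windows.tsv"))
  summary$zhp <- list(windows = nrow(zhp), retained = sum(zhp$retained),
                      candidates = sum(zhp$candidate, na.rm = TRUE))

  ## stage: XP-EHH scan
  xp <- xpehh_scores(panel, obs, ref, config$xpehh)
  write_table(xp, out("xpehh_scores.tsv"))
  summary$xpehh <- list(cores = nrow(xp),
                        truncated = sum(xp$truncated),
                        scored = sum(!is.na(xp$z)))

  ## stage: window significance
  sig <- xpehh_window_significance(xp, panel$contig_lengths,
                                   config$sig_window_bp,
                                   config$sig_bin_width,
                                   config$sig_pool_from, config$sig_alpha)
  write_table(sig, out("xpehh_windows.tsv"))
  summary$significance <- list(windows = nrow(sig),
                               significant = sum(sig$significant))

  ## stage: candidate regions + genes
  reg_zhp <- merge_regions(zhp[zhp$candidate %in% TRUE, , drop = FALSE],
                           method = "zhp")
  reg_xp <- merge_regions(sig[sig$significant, , drop = FALSE],
                          method = "xpehh")
  regions <- rbind(reg_zhp, reg_xp)
  write_regions_bed(regions, out("candidate_regions.bed"))
  summary$regions <- list(zhp = nrow(reg_zhp), xpehh = nrow(reg_xp))
  if (!is.null(config$genes)) {
    genes <- read_gene_intervals(config$genes)
    gz <- genes_in_regions(reg_zhp, genes)
    gx <- genes_in_regions(reg_xp, genes)
    ov <- method_overlap(gz$genes, gx$genes)
    write_table(rbind(gz$per_region, gx$per_region), out("region_genes.tsv"))
    summary$genes <- list(zhp = length(gz$genes), xpehh = length(gx$genes),
                          shared = ov$n_shared)
  }

  ## Manhattan-ready table: one row per scored item of each method
  manhattan <- rbind(
    data.frame(method = "zhp", contig = zhp$contig,
               pos = (zhp$start + zhp$end) / 2, statistic = zhp$zhp,
               neg_log10_p = NA_real_, stringsAsFactors = FALSE),
    data.frame(method = "xpehh", contig = sig$contig,
               pos = (sig$start + sig$end) / 2, statistic = sig$max_score,
               neg_log10_p = ifelse(sig$empirical_p > 0,
                                    -log10(sig$empirical_p), Inf),
               stringsAsFactors = FALSE)
  )
  write_table(manhattan, out("manhattan.tsv"))

  jsonlite::write_json(summary, out("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(panel = panel, pop_stats = pop_stats, pi = pi_obs,
                 zhp = zhp, xpehh = xp, windows = sig, regions = regions,
                 summary = summary))
}

#' Neutral-control false-positive assessment
#'
#' Simulates sweep-free two-population panels (default: three 2 Mb contigs,
#' 12 + 10 diploids, one simulation per seed), runs the XP-EHH scan and the
#' SNP-density-binned empirical-p rule on each, and reports the fraction of
#' 50 kb windows called significant. Under the empirical-p counting rule the
#' best window of each bin always has p = 0, so the attainable floor is
#' about one window per bin per genome; with 120 windows per replicate the
#' expected neutral fraction is ~1/120.
#'
#' @param seeds integer vector of simulation seeds (one replicate each).
#' @param contig_length contig lengths (bp) per replicate genome.
#' @param alpha significance level for the empirical-p rule.
#' @return data.frame with one row per seed (`seed`, `windows`,
#'   `significant`, `fraction`); attribute `"mean_fraction"` holds the
#'   average fraction over seeds.
#' @export
neutral_control <- function(seeds = 1:20, contig_length = rep(2e6, 3),
                            alpha = 0.005) {
  rows <- lapply(seeds, function(s) {
    params <- sim_params(contig_length = contig_length, seed = s)
    panel <- simulate_neutral_panel(params)
    xp <- xpehh_scores(panel, names(params$n_samples)[1],
                       names(params$n_samples)[2])
    sig <- xpehh_window_significance(xp, panel$contig_lengths,
                                     alpha = alpha)
    data.frame(seed = s, windows = nrow(sig),
               significant = sum(sig$significant),
               fraction = mean(sig$significant))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_fraction") <- mean(out$fraction)
  out
}
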