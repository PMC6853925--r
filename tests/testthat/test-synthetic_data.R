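small_params <- function(seed, L = 3e5, gens = 120) {
  sim_params(n_samples = c(island = 6, mainland = 5),
             contig_length = L, n_generations = gens,
             founder_haplotypes = 20, seed = seed)
}

test_that("the simulator is deterministic in parameters and seed", {
  p1 <- simulate_neutral_panel(small_params(seed = 2))
  p2 <- simulate_neutral_panel(small_params(seed = 2))
  expect_identical(p1$sites, p2$sites)
  expect_identical(p1$haplotypes, p2$haplotypes)
  p3 <- simulate_neutral_panel(small_params(seed = 3))
  expect_false(identical(p1$sites$pos, p3$sites$pos))
  # and it does not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(simulate_neutral_panel(small_params(seed = 2)))
  expect_identical(runif(3), before)
})

test_that("zero mutation rate fails with actionable advice", {
  pr <- small_params(seed = 1)
  pr$mutation_rate <- 0
  expect_error(simulate_neutral_panel(pr), "mutation_rate")
})

test_that("simulated panels satisfy every container invariant", {
  p <- simulate_neutral_panel(small_params(seed = 5))
  expect_silent(validate_panel(p))
  expect_true(all(diff(p$sites$pos) > 0))
  expect_gt(n_sites(p), 50)
  # INFO metrics synthesized in passing ranges by default: the QD/MQ/FS/QUAL
  # sub-filters remove nothing (fixed-derived sites may still fail the MAF
  # screen, so only the metric counts are asserted)
  f <- suppressMessages(apply_site_filters(p, filter_config()))
  counts <- attr(f, "filter_counts")
  expect_equal(unname(counts[c("qd", "mq", "fs", "qual")]), rep(0L, 4))
})

test_that("sweep injection depresses local heterozygosity and records truth", {
  fx <- sweep_fixture()
  tr <- fx$truth
  expect_equal(tr$start, 1e6 - 150000 - 1)
  expect_equal(tr$end, 1e6 + 150000)

  ct <- allele_count_table(fx$panel, "island")
  n <- ct$n_ref + ct$n_alt
  het_exp <- 2 * ct$n_ref * ct$n_alt / (n * n)   # expected heterozygosity
  inside <- ct$pos > tr$start & ct$pos <= tr$end
  expect_lt(mean(het_exp[inside]), mean(het_exp[!inside]))

  # carrier_freq 1: all island haplotypes identical across the halo
  pr <- small_params(seed = 8)
  panel <- simulate_neutral_panel(pr)
  sw <- inject_sweep(panel, "island", core_pos = 1.5e5, carrier_freq = 1,
                     halo = 50000, seed = 9)
  rows <- seq_len(12)  # 6 diploids
  halo_sites <- which(sw$panel$sites$pos >= 1e5 &
                        sw$panel$sites$pos <= 2e5)
  h <- sw$panel$haplotypes[rows, halo_sites, drop = FALSE]
  expect_true(all(apply(h, 2, function(col) length(unique(col)) == 1)))

  # a halo larger than the contig is clipped, with a message
  expect_message(
    sw2 <- inject_sweep(panel, "island", core_pos = 1000, carrier_freq = 0.9,
                        halo = 5e5, seed = 9),
    "clipped")
  expect_equal(sw2$truth$start, 0)
  expect_equal(sw2$truth$end, 3e5)
})

test_that("exported fixtures regenerate byte-identically and re-read cleanly", {
  dir <- withr::local_tempdir()
  pr <- small_params(seed = 12)
  panel <- simulate_neutral_panel(pr)
  sw <- inject_sweep(panel, "island", core_pos = 1.5e5, seed = 13,
                     halo = 50000)
  paths <- export_fixture(sw$panel, sw$truth, file.path(dir, "a"), pr)

  # regenerate from the manifest parameters
  man <- jsonlite::read_json(paths[["manifest"]])
  pr2 <- sim_params(n_samples = unlist(man$params$n_samples),
                    contig_length = unlist(man$params$contig_length),
                    n_generations = man$params$n_generations,
                    mutation_rate = man$params$mutation_rate,
                    recombination_rate = man$params$recombination_rate,
                    founder_haplotypes = man$params$founder_haplotypes,
                    seed = man$params$seed)
  panel2 <- simulate_neutral_panel(pr2)
  sw2 <- inject_sweep(panel2, "island", core_pos = 1.5e5, seed = 13,
                      halo = 50000)
  paths2 <- export_fixture(sw2$panel, sw2$truth, file.path(dir, "b"), pr2)
  for (f in c("vcf", "popmap", "truth", "genes", "manifest")) {
    expect_identical(readLines(paths2[[f]]), readLines(paths[[f]]))
  }

  # truth BED has exactly one record for one sweep
  expect_length(readLines(paths[["truth"]]), 1L)

  # the emitted VCF re-read by the I/O layer passes all panel invariants
  back <- read_vcf(paths[["vcf"]], paths[["popmap"]])
  expect_silent(validate_panel(back))
  expect_equal(back$sites$pos, sw$panel$sites$pos)
  expect_equal(unname(back$genotypes), unname(sw$panel$genotypes))
})

test_that("allele-frequency spectrum is self-consistent across seeds", {
  means <- vapply(1:10, function(s) {
    p <- simulate_neutral_panel(small_params(seed = 100 + s, L = 2e5,
                                             gens = 100))
    mean(sweepscan:::site_maf(p$genotypes))
  }, numeric(1))
  obs <- mean(sweepscan:::site_maf(
    simulate_neutral_panel(small_params(seed = 200, L = 2e5,
                                        gens = 100))$genotypes))
  se <- sd(means) * sqrt(1 + 1 / length(means))
  expect_lt(abs(obs - mean(means)), 3 * se)
})
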