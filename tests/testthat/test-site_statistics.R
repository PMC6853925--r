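test_that("allele counts match a brute-force tally over individual alleles", {
  p <- tiny_panel()
  ct <- allele_count_table(p, "P1")
  # sample s1, s2 are P1: dosages from the haplotype rows 1:4
  expect_equal(ct$n_ref + ct$n_alt, rep(4L, 5))
  expect_true(all(ct$n_maj >= ct$n_min))

  # direct examples: genotypes {0,2} and {1,1}
  g <- rbind(c(0L, 1L), c(2L, 1L))
  ids <- c("a", "b")
  sites <- data.frame(contig = "chr1", pos = c(1L, 2L), id = ".",
                      ref = "A", alt = "G", qual = 1, qd = 1, mq = 50,
                      fs = 1, stringsAsFactors = FALSE)
  q <- genotype_panel(sites, g, ids, c(a = "X", b = "X"), c(chr1 = 10))
  ct <- allele_count_table(q, "X")
  expect_equal(ct$n_ref, c(2L, 2L))
  expect_equal(ct$n_alt, c(2L, 2L))
  expect_equal(ct$n_het, c(0L, 2L))

  # randomized brute force: tally alleles one genotype at a time
  set.seed(11)
  g <- matrix(sample(c(0:2, NA), 200, replace = TRUE), nrow = 10)
  ids <- sprintf("s%02d", 1:10)
  sites <- data.frame(contig = "chr1", pos = seq_len(20) * 5L, id = ".",
                      ref = "A", alt = "G", qual = 1, qd = 1, mq = 50,
                      fs = 1, stringsAsFactors = FALSE)
  q <- genotype_panel(sites, g, ids, stats::setNames(rep("X", 10), ids),
                      c(chr1 = 200))
  ct <- allele_count_table(q, "X")
  for (j in seq_len(20)) {
    alleles <- unlist(lapply(g[, j], function(d) {
      if (is.na(d)) NULL else c(rep(1L, d), rep(0L, 2 - d))
    }))
    expect_equal(ct$n_alt[j], sum(alleles == 1L))
    expect_equal(ct$n_ref[j], sum(alleles == 0L))
  }
  expect_error(allele_count_table(q, "nope"), "zero samples")
})

test_that("transition/transversion classification partitions all base pairs", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- sweepscan:::is_transition(pairs$ref, pairs$alt)
  expect_equal(sum(cls), 4L)       # A>G, G>A, C>T, T>C
  expect_equal(sum(!cls), 8L)      # every other pair is a transversion

  one_tv <- list(transitions = 0, transversions = 1)
  expect_equal(tstv_ratio(one_tv)$ratio, 0)
  expect_true(is.na(tstv_ratio(list(transitions = 3,
                                    transversions = 0))$ratio))

  # panel of the 4 pair classes {A>G, C>T, A>C, G>T} -> (2, 2, 1.0)
  sites <- data.frame(contig = "chr1", pos = c(1L, 2L, 3L, 4L), id = ".",
                      ref = c("A", "C", "A", "G"),
                      alt = c("G", "T", "C", "T"),
                      qual = 1, qd = 1, mq = 50, fs = 1,
                      stringsAsFactors = FALSE)
  p <- genotype_panel(sites, matrix(1L, 1, 4), "s1", c(s1 = "X"),
                      c(chr1 = 10))
  tt <- tstv_ratio(p)
  expect_equal(tt$n_transitions, 2L)
  expect_equal(tt$n_transversions, 2L)
  expect_equal(tt$ratio, 1.0)
})

test_that("fixed-site detection requires complete homozygous-alt calls", {
  make <- function(dosages) {
    n <- length(dosages)
    ids <- sprintf("s%02d", seq_len(n))
    sites <- data.frame(contig = "chr1", pos = 100L, id = ".", ref = "C",
                        alt = "T", qual = 1, qd = 1, mq = 50, fs = 1,
                        stringsAsFactors = FALSE)
    genotype_panel(sites, matrix(as.integer(dosages), ncol = 1), ids,
                   stats::setNames(rep("X", n), ids), c(chr1 = 1000))
  }
  expect_true(detect_fixed_sites(make(rep(2, 12)), "X"))
  expect_false(detect_fixed_sites(make(c(rep(2, 11), 1)), "X"))
  expect_message(
    res <- detect_fixed_sites(make(c(rep(2, 11), NA)), "X"),
    "strict rule")
  expect_false(res)
})

test_that("genotype frequencies convert to allele frequencies", {
  expect_equal(allele_freq_from_genotypes(c(hom = 0.9, het = 0.1)), 0.95)
  expect_equal(allele_freq_from_genotypes(c(hom = 1.0)), 1.0)
  expect_equal(allele_freq_from_genotypes(
    c(hom = 0.25, het = 0.5, hom_other = 0.25)), 0.5)
  # published tables are rounded; a small excess is tolerated
  expect_equal(allele_freq_from_genotypes(c(hom = 0.42, het = 0.42,
                                            hom_other = 0.17)), 0.63)
  expect_error(allele_freq_from_genotypes(c(hom = 0.5, het = 0.1)),
               "sum to")
})

test_that("segregating-site sets match brute-force set algebra", {
  p <- tiny_panel()
  res <- population_snp_sets(p, c("P1", "P2"))
  # brute force from the genotype matrix
  g1 <- p$genotypes[1:2, , drop = FALSE]
  g2 <- p$genotypes[3, , drop = FALSE]
  a <- colSums(g1, na.rm = TRUE) > 0
  b <- colSums(g2, na.rm = TRUE) > 0
  expect_equal(res$sets$P1, unname(a))
  expect_equal(res$sets$P2, unname(b))
  expect_equal(res$pairs$a_only, sum(a & !b))
  expect_equal(res$pairs$b_only, sum(!a & b))
  expect_equal(res$pairs$shared, sum(a & b))

  # identical populations -> empty unique sets
  res2 <- population_snp_sets(p, c("P1", "P1"))
  expect_equal(res2$pairs$a_only, 0L)
  expect_equal(res2$pairs$b_only, 0L)
})

test_that("windowed pi equals exhaustive pairwise enumeration", {
  # one site, 4 haplotypes, counts 2/2: pi = 2*2*2/(4*3) = 2/3
  hap <- rbind(c(0L), c(0L), c(1L), c(1L))
  p <- panel_from_haps(hap, pos = 500, pop_of_sample = c("X", "X"),
                       contig_len = 10000)
  pw <- windowed_pi(p, "X", window_bp = 10000)
  expect_equal(pw$pi, (2 / 3) / 10000)
  expect_equal(pw$pi, 6.667e-5, tolerance = 1e-4)
  expect_equal(pw$pi * 10000, pi_brute(c(0, 0, 1, 1)))

  # monomorphic window
  hap0 <- matrix(0L, 4, 1)
  hap0[1, 1] <- 1L  # keep site biallelic in the sample, then count P2 only
  p2 <- panel_from_haps(rbind(hap0, matrix(0L, 2, 1)), pos = 500,
                        pop_of_sample = c("X", "X", "Y"),
                        contig_len = 10000)
  expect_equal(windowed_pi(p2, "Y", 10000)$pi, 0)

  # equal split maximizes per-site pi for fixed n (brute force over splits)
  n <- 8
  pis <- vapply(0:n, function(k) {
    2 * k * (n - k) / (n * (n - 1))
  }, numeric(1))
  expect_equal(which.max(pis) - 1, n / 2)

  # random small panel: window pi from exhaustive pair enumeration
  set.seed(3)
  hap <- matrix(rbinom(10 * 6, 1, 0.4), nrow = 10)
  keep <- colSums(hap) > 0 & colSums(hap) < 10
  hap <- hap[, keep, drop = FALSE]
  pos <- sort(sample(1:9999, ncol(hap)))
  p3 <- panel_from_haps(hap, pos, rep("X", 5), contig_len = 10000)
  pw <- windowed_pi(p3, "X", 10000)
  oracle <- sum(apply(hap, 2, pi_brute)) / 10000
  expect_equal(pw$pi, oracle, tolerance = 1e-12)
  # mean diversity is the length-weighted window average
  expect_equal(attr(pw, "mean_pi"), oracle, tolerance = 1e-12)
})
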