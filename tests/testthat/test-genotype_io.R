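test_that("VCF round trip preserves every panel field and is byte-stable", {
  p <- tiny_panel()
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "p.vcf")
  pm <- file.path(dir, "popmap.txt")
  writeLines(paste(p$sample_ids, p$pop_map[p$sample_ids]), pm)

  write_vcf(p, vcf)
  p2 <- read_vcf(vcf, pm)
  expect_equal(p2$sites, p$sites)
  expect_equal(unname(p2$genotypes), unname(p$genotypes))
  expect_equal(p2$haplotypes, p$haplotypes)
  expect_equal(p2$sample_ids, p$sample_ids)
  expect_equal(p2$contig_lengths, p$contig_lengths)

  vcf2 <- file.path(dir, "p2.vcf")
  write_vcf(p2, vcf2)
  expect_identical(readLines(vcf2), readLines(vcf))

  # phased panels are written with '|'
  expect_true(any(grepl("\\d\\|\\d", readLines(vcf))))
})

test_that("non-SNP and multiallelic records are dropped with a count", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "mixed.vcf")
  pm <- file.path(dir, "popmap.txt")
  writeLines(c("s1 P1", "s2 P2"), pm)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tAT\tA\t50\tPASS\t.\tGT\t0/1\t0/0",   # indel
    "chr1\t300\t.\tC\tT\t50\tPASS\t.\tGT\t1/1\t0/1",
    "chr1\t400\t.\tG\tA,C\t50\tPASS\t.\tGT\t0/1\t0/0",  # multiallelic
    "chr1\t500\t.\tT\tC\t50\tPASS\t.\tGT\t0/0\t1/1"
  ), vcf)
  expect_message(p <- read_vcf(vcf, pm), "dropped 2")
  expect_equal(n_sites(p), 3L)
  expect_equal(p$sites$pos, c(100L, 300L, 500L))
  expect_null(p$haplotypes)  # unphased input
})

test_that("a VCF sample missing from the population map names the sample", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "p.vcf")
  pm <- file.path(dir, "popmap.txt")
  p <- tiny_panel()
  write_vcf(p, vcf)
  writeLines(c("s1 P1", "s2 P1"), pm)  # s3 missing
  expect_error(read_vcf(vcf, pm), "s3")
})

test_that("hard filters apply the documented thresholds conjunctively", {
  base <- tiny_panel()
  # boundary site: QD=5, MQ=40, FS=200, QUAL=30, full call rate, MAF 0.5
  s <- base$sites
  s$qd <- c(5, 4.9, NA, 12, 12)
  s$mq <- c(40, 60, 60, 60, 60)
  s$fs <- c(200, 1, 1, 1, 201)
  s$qual <- c(30, 100, 100, 29.9, 100)
  base$sites <- s
  g <- matrix(1L, nrow = 3, ncol = 5)  # MAF 0.5 everywhere, call rate 1
  base$genotypes <- g
  rownames(base$genotypes) <- base$sample_ids
  base$haplotypes <- NULL

  f <- suppressMessages(apply_site_filters(base, filter_config()))
  # site 1: all boundary values pass; site 2: QD < 5 fails; site 3: missing
  # QD passes its sub-filter; site 4: QUAL < 30 fails; site 5: FS > 200 fails
  expect_equal(f$sites$pos, base$sites$pos[c(1, 3)])
})

test_that("MAF boundary: one minor allele in 82 passes, zero is removed", {
  n_samp <- 41  # 82 alleles
  g <- matrix(0L, nrow = n_samp, ncol = 2)
  g[1, 1] <- 1L   # site 1: minor count 1, MAF 1/82 = 0.0122 > 0.01
  # site 2 monomorphic: MAF 0 <= 0.01, removed
  ids <- sprintf("s%02d", 1:n_samp)
  sites <- data.frame(contig = "chr1", pos = c(10L, 20L), id = ".",
                      ref = "A", alt = "G", qual = 100, qd = 20, mq = 55,
                      fs = 1, stringsAsFactors = FALSE)
  p <- genotype_panel(sites, g, ids, stats::setNames(rep("P1", n_samp), ids),
                      c(chr1 = 1000))
  f <- suppressMessages(apply_site_filters(p, filter_config()))
  expect_equal(f$sites$pos, 10L)
})

test_that("filtering is idempotent and order-free (conjunctive per site)", {
  p <- suppressMessages(simulate_neutral_panel(
    sim_params(contig_length = 3e5, n_generations = 120, seed = 7),
    contaminate_fraction = 0.2))
  once <- suppressMessages(apply_site_filters(p, filter_config()))
  twice <- suppressMessages(apply_site_filters(once, filter_config()))
  expect_equal(twice$sites, once$sites)
  expect_equal(twice$genotypes, once$genotypes)
  expect_lt(n_sites(once), n_sites(p))  # contamination was removed
})

test_that("known/novel classification counts and fraction are consistent", {
  p <- tiny_panel()
  all_keys <- paste0(p$sites$contig, ":", p$sites$pos)

  res <- classify_known_novel(p, character(0))
  expect_equal(res$novel_fraction, 1.0)
  res <- classify_known_novel(p, all_keys)
  expect_equal(res$novel_fraction, 0.0)
  res <- classify_known_novel(p, all_keys[1:2])
  expect_equal(res$known_count + res$novel_count, n_sites(p))
  expect_equal(res$novel_fraction, round(3 / 5, 4))
  expect_error(classify_known_novel(subset_sites(p, integer(0)),
                                    all_keys), "empty")
})

test_that("known-site lists load from two-column text and from VCF", {
  dir <- withr::local_tempdir()
  txt <- file.path(dir, "known.txt")
  writeLines(c("chr1\t1000", "chr1\t5000", "chr1\t5000"), txt)
  expect_equal(read_known_sites(txt), c("chr1:1000", "chr1:5000"))

  vcf <- file.path(dir, "known.vcf")
  write_vcf(tiny_panel(), vcf)
  expect_equal(length(read_known_sites(vcf)), 5L)
})
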