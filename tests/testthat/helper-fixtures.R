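# Shared fixtures and independent brute-force oracles.

# Small hand-built phased panel: 3 samples in 2 populations, 5 sites on one
# 100 kb contig. Haplotype rows 2s-1/2s belong to sample s.
tiny_panel <- function() {
  hap <- rbind(
    c(0L, 1L, 0L, 1L, 1L),
    c(0L, 0L, 0L, 1L, 0L),
    c(1L, 0L, 0L, 1L, 1L),
    c(0L, 0L, 1L, 1L, 0L),
    c(0L, 1L, 0L, 0L, 1L),
    c(0L, 0L, 0L, 1L, 1L)
  )
  dosage <- hap[c(1, 3, 5), ] + hap[c(2, 4, 6), ]
  sites <- data.frame(
    contig = "chr1", pos = c(1000L, 5000L, 20000L, 50000L, 90000L),
    id = ".", ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "C"),
    qual = c(500, 60, 35.5, 900, 250.25),
    qd = c(12, 25.5, 8, 19, 30), mq = c(55, 58, 60, 45, 50.5),
    fs = c(0.5, 3, 10, 1.25, 0), stringsAsFactors = FALSE
  )
  genotype_panel(sites, dosage, c("s1", "s2", "s3"),
                 c(s1 = "P1", s2 = "P1", s3 = "P2"),
                 c(chr1 = 1e5), haplotypes = hap)
}

# Build a panel from an explicit haplotype matrix (one contig, all samples in
# the populations given by `pop_of_sample`).
panel_from_haps <- function(hap, pos, pop_of_sample,
                            contig_len = max(pos) + 1000) {
  hap <- matrix(as.integer(hap), nrow = nrow(hap))
  n <- nrow(hap) / 2
  dosage <- hap[seq(1, nrow(hap), 2), , drop = FALSE] +
    hap[seq(2, nrow(hap), 2), , drop = FALSE]
  ids <- sprintf("s%02d", seq_len(n))
  sites <- data.frame(
    contig = "chr1", pos = as.integer(pos), id = ".",
    ref = rep("A", length(pos)), alt = rep("G", length(pos)),
    qual = 100, qd = 20, mq = 55, fs = 1, stringsAsFactors = FALSE
  )
  genotype_panel(sites, dosage, ids,
                 stats::setNames(pop_of_sample, ids),
                 c(chr1 = contig_len), haplotypes = hap)
}

# The default study fixture is expensive; build it once per test run.
.fixture_env <- new.env(parent = emptyenv())
sweep_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    .fixture_env$fx <- suppressMessages(simulate_sweep_fixture(seed = 1))
  }
  .fixture_env$fx
}
xpehh_on_fixture <- function() {
  if (is.null(.fixture_env$xp)) {
    fx <- sweep_fixture()
    .fixture_env$xp <- xpehh_scores(fx$panel, "island", "mainland")
  }
  .fixture_env$xp
}

# --- independent oracles -------------------------------------------------

# Pairwise-difference nucleotide diversity at one site: exhaustive pair
# enumeration over the allele vector.
pi_brute <- function(alleles) {
  n <- length(alleles)
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# EHH at marker m (inclusive) from core c: fraction of haplotype pairs with
# identical allele strings over the spanned columns, by direct comparison.
ehh_brute <- function(hap, core, m) {
  cols <- min(core, m):max(core, m)
  key <- apply(hap[, cols, drop = FALSE], 1, paste, collapse = "")
  n <- length(key)
  pairs <- utils::combn(n, 2)
  mean(key[pairs[1, ]] == key[pairs[2, ]])
}

# Pooled heterozygosity from per-site major/minor counts, summed by hand.
hp_brute <- function(nmaj, nmin) {
  2 * sum(nmaj) * sum(nmin) / (sum(nmaj) + sum(nmin))^2
}
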