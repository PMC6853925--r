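test_that("EHH decay matches exhaustive pair enumeration", {
  # two identical pairs at the first flanking marker: EHH = 2/C(4,2) = 1/3
  hap <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L))
  cv <- ehh_curve(hap, positions = c(100, 200), core_index = 1,
                  direction = "right", stop_cutoff = 0.05)
  expect_equal(cv$ehh, c(1, 1 / 3))
  expect_equal(cv$ehh[2], ehh_brute(hap, 1, 2))

  # all haplotypes identical: EHH stays 1 everywhere (and truncates)
  same <- matrix(0L, 6, 5)
  cv <- ehh_curve(same, positions = 1:5 * 100, core_index = 3, "right")
  expect_true(all(cv$ehh == 1))
  expect_true(cv$truncated)

  # all distinct at the first flanking marker: EHH = 0 there
  hap <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  cv <- ehh_curve(hap, positions = c(100, 200), core_index = 1, "right")
  expect_equal(cv$ehh[length(cv$ehh)], 0)
  expect_false(cv$truncated)

  expect_error(ehh_curve(matrix(0L, 1, 3), 1:3, 1, "right"), "2 haplotypes")
})

test_that("EHH is non-increasing and equals the brute-force pair fraction", {
  set.seed(9)
  for (rep in 1:5) {
    hap <- matrix(rbinom(12 * 15, 1, 0.5), nrow = 12)
    pos <- sort(sample(1:5000, 15))
    core <- sample(2:14, 1)
    for (dir in c("left", "right")) {
      cv <- ehh_curve(hap, pos, core, dir, stop_cutoff = 0)
      expect_true(all(diff(cv$ehh) <= 1e-12))
      expect_equal(cv$ehh[1], 1)
      # every recorded point agrees with direct string comparison
      for (k in seq_along(cv$pos)[-1]) {
        m <- which(pos == cv$pos[k])
        expect_equal(cv$ehh[k], ehh_brute(hap, core, m))
      }
    }
  }
})

test_that("iHH integration has the documented closed forms", {
  rect <- function(dir) list(core_index = 1, direction = dir,
                             distance = c(0, 1000), pos = c(0, 1000),
                             ehh = c(1, 1), truncated = TRUE)
  res <- integrate_ihh(rect("left"), rect("right"))
  expect_equal(res$ihh, 2000)
  expect_true(res$truncated)

  tri <- function(dir) list(core_index = 1, direction = dir,
                            distance = c(0, 1000), pos = c(0, 1000),
                            ehh = c(1, 0), truncated = FALSE)
  res <- integrate_ihh(tri("left"), tri("right"), cutoff = 0.05)
  # trapezoid to the interpolated 0.05 crossing at 950 bp, per side
  expect_equal(res$ihh, 2 * (1 + 0.05) / 2 * 950)
  expect_false(res$truncated)
  # as the cutoff vanishes the full triangle area is recovered
  expect_equal(integrate_ihh(tri("left"), tri("right"), cutoff = 0)$ihh,
               2 * 500)

  # zero-length flank contributes nothing
  edge <- list(core_index = 1, direction = "left", distance = 0, pos = 0,
               ehh = 1, truncated = TRUE)
  expect_equal(integrate_ihh(edge, tri("right"), cutoff = 0)$ihh, 500)
})

test_that("iHH is invariant to inserting a monomorphic marker", {
  set.seed(13)
  hap <- matrix(rbinom(10 * 12, 1, 0.5), nrow = 10)
  pos <- seq(100, 1200, by = 100)
  core <- 4
  base <- integrate_ihh(ehh_curve(hap, pos, core, "left", 0.05),
                        ehh_curve(hap, pos, core, "right", 0.05))
  hap2 <- cbind(hap[, 1:6], 0L, hap[, 7:12])
  pos2 <- c(pos[1:6], 650, pos[7:12])
  with_mono <- integrate_ihh(ehh_curve(hap2, pos2, core, "left", 0.05),
                             ehh_curve(hap2, pos2, core, "right", 0.05))
  expect_equal(with_mono$ihh, base$ihh, tolerance = 1e-12)
})

test_that("XP-EHH raw scores are zero for identical populations and
           antisymmetric under swapping", {
  set.seed(17)
  haps_one_pop <- matrix(rbinom(12 * 30, 1, 0.5), nrow = 12)
  hap <- rbind(haps_one_pop, haps_one_pop)  # two identical populations
  keep <- colSums(hap) > 0 & colSums(hap) < 24
  hap <- hap[, keep, drop = FALSE]
  pos <- sort(sample(1:60000, ncol(hap)))
  p <- panel_from_haps(hap, pos, rep(c("A", "B"), each = 6),
                       contig_len = 65000)
  xp <- xpehh_scores(p, "A", "B", xpehh_params(exclude_truncated = FALSE),
                     normalize = FALSE)
  expect_true(all(abs(xp$raw) < 1e-12, na.rm = TRUE))

  # antisymmetry on a panel where the populations differ
  fx <- sweep_fixture()
  sub <- subset_sites(fx$panel,
                      which(fx$panel$sites$pos > 9e5 &
                              fx$panel$sites$pos < 1.1e6))
  sub$contig_lengths <- c(chr1 = 2e6)
  ab <- xpehh_scores(sub, "island", "mainland",
                     xpehh_params(exclude_truncated = FALSE))
  ba <- xpehh_scores(sub, "mainland", "island",
                     xpehh_params(exclude_truncated = FALSE))
  expect_equal(ba$raw, -ab$raw, tolerance = 1e-10)
})

test_that("compiled per-core scan agrees with the plain-R reference", {
  set.seed(23)
  for (rep in 1:4) {
    hap <- matrix(rbinom(16 * 40, 1, 0.5), nrow = 16)
    keep <- colSums(hap) > 0 & colSums(hap) < 16
    hap <- hap[, keep, drop = FALSE]
    pos <- sort(sample(1:20000, ncol(hap)))
    rows_obs <- 1:8
    rows_ref <- 9:16
    cores <- seq(2, ncol(hap) - 1, by = 3)
    cpp <- sweepscan:::.xpehh_scan_cpp(hap, as.numeric(pos), cores,
                                       rows_obs, rows_ref, 0.05)
    for (i in seq_along(cores)) {
      ref <- sweepscan:::xpehh_one_core(hap, pos, cores[i], rows_obs,
                                        rows_ref, 0.05)
      expect_equal(cpp[i, 1], ref$ihh_obs, tolerance = 1e-10)
      expect_equal(cpp[i, 2], ref$ihh_ref, tolerance = 1e-10)
      expect_equal(cpp[i, 3] > 0, ref$truncated)
    }
  }
})

test_that("unphased panels are rejected with a pseudo-phasing hint", {
  p <- tiny_panel()
  p$haplotypes <- NULL
  expect_error(xpehh_scores(p, "P1", "P2"), "pseudo_phase")
  pp <- pseudo_phase(p, seed = 4)
  expect_false(is.null(pp$haplotypes))
  expect_identical(pseudo_phase(p, seed = 4)$haplotypes, pp$haplotypes)
})

test_that("the strongest XP-EHH core lies in the sweep on the fixture", {
  fx <- sweep_fixture()
  xp <- xpehh_on_fixture()
  top <- xp$pos[which.max(xp$z)]
  expect_gt(top, fx$truth$start)
  expect_lte(top, fx$truth$end)
})
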