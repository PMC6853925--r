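#' Construct a genotype panel
#'
#' A `genotype_panel` is the in-memory container used by every scan in this
#' package: an ordered table of biallelic SNP sites, an integer dosage matrix
#' (samples x sites, alt-allele dosage 0/1/2, `NA` = missing), optionally a
#' phased haplotype matrix (2 x samples rows, 0/1 alleles), a sample-to-
#' population map, and per-contig lengths.
#'
#' Positions are 1-based (VCF convention). All window arithmetic elsewhere in
#' the package uses 0-based half-open intervals; conversion happens at I/O
#' boundaries only.
#'
#' @param sites data.frame with columns `contig`, `pos`, `id`, `ref`, `alt`,
#'   `qual`, `qd`, `mq`, `fs`. `id` may be `"."`; `qd`/`mq`/`fs` may be `NA`
#'   where the caller has no INFO metrics.
#' @param genotypes integer matrix, `n_samples x n_sites`, entries in
#'   `{0, 1, 2, NA}` (alt-allele dosage).
#' @param sample_ids character vector of sample names (rows of `genotypes`).
#' @param pop_map named character vector mapping sample id to population label.
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param haplotypes optional integer matrix, `2*n_samples x n_sites`, entries
#'   in `{0, 1}`; rows `2s - 1` and `2s` are the two phased haplotypes of
#'   sample `s`.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, genotypes, sample_ids, pop_map,
                           contig_lengths, haplotypes = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- sample_ids
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
  }
  sites$contig <- as.character(sites$contig)
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  panel <- structure(
    list(
      sites = sites,
      genotypes = genotypes,
      haplotypes = haplotypes,
      sample_ids = as.character(sample_ids),
      pop_map = pop_map,
      contig_lengths = contig_lengths
    ),
    class = "genotype_panel"
  )
  validate_panel(panel)
  panel
}

#' Validate the invariants of a genotype panel
#'
#' Checks that positions are strictly increasing within each contig, that all
#' sites are biallelic SNPs (single distinct bases), that every sample has a
#' population label, and — when phased haplotypes are present — that dosages
#' equal the sum of the two haplotype alleles at every non-missing entry.
#'
#' @param panel a `genotype_panel`.
#' @return `panel`, invisibly; stops with an informative error on violation.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  s <- panel$sites
  req <- c("contig", "pos", "id", "ref", "alt", "qual", "qd", "mq", "fs")
  missing_cols <- setdiff(req, names(s))
  if (length(missing_cols)) {
    stop("sites table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(s) != ncol(panel$genotypes)) {
    stop("genotype matrix has ", ncol(panel$genotypes),
         " columns but sites table has ", nrow(s), " rows")
  }
  if (nrow(panel$genotypes) != length(panel$sample_ids)) {
    stop("genotype matrix rows do not match sample_ids")
  }
  bases <- c("A", "C", "G", "T")
  bad <- !(s$ref %in% bases) | !(s$alt %in% bases) | s$ref == s$alt
  if (any(bad)) {
    stop("non-biallelic-SNP site(s) at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  for (ctg in unique(s$contig)) {
    p <- s$pos[s$contig == ctg]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on contig ", ctg)
    }
  }
  unmapped <- setdiff(panel$sample_ids, names(panel$pop_map))
  if (length(unmapped)) {
    stop("sample(s) without population label: ",
         paste(unmapped, collapse = ", "))
  }
  g <- panel$genotypes
  if (any(!is.na(g) & !(g %in% 0:2))) stop("dosages must be in {0,1,2,NA}")
  if (!is.null(panel$haplotypes)) {
    h <- panel$haplotypes
    if (nrow(h) != 2L * nrow(g)) {
      stop("haplotype matrix must have 2 rows per sample")
    }
    if (any(!(h %in% 0:1))) stop("haplotype alleles must be in {0,1}")
    hd <- h[seq(1L, nrow(h), by = 2L), , drop = FALSE] +
      h[seq(2L, nrow(h), by = 2L), , drop = FALSE]
    ok <- is.na(g) | g == hd
    if (!all(ok)) stop("dosage != sum of phased alleles at some entries")
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  pops <- table(x$pop_map[x$sample_ids])
  cat("genotype_panel:", nrow(x$sites), "sites,",
      length(x$sample_ids), "samples (",
      paste(sprintf("%s=%d", names(pops), as.integer(pops)), collapse = ", "),
      ")\n")
  cat("  contigs:", paste(sprintf("%s(%g bp)", names(x$contig_lengths),
                                  x$contig_lengths), collapse = ", "), "\n")
  cat("  phased haplotypes:", if (is.null(x$haplotypes)) "absent" else "present",
      "\n")
  invisible(x)
}

#' Number of sites in a panel
#' @param panel a `genotype_panel`.
#' @return integer site count.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Subset a panel to a set of sites
#'
#' @param panel a `genotype_panel`.
#' @param keep logical or integer index over sites.
#' @return a `genotype_panel` restricted to the selected sites, in order.
#' @export
subset_sites <- function(panel, keep) {
  panel$sites <- panel$sites[keep, , drop = FALSE]
  rownames(panel$sites) <- NULL
  panel$genotypes <- panel$genotypes[, keep, drop = FALSE]
  if (!is.null(panel$haplotypes)) {
    panel$haplotypes <- panel$haplotypes[, keep, drop = FALSE]
  }
  panel
}

#' Row indices of a population's samples
#' @keywords internal
pop_rows <- function(panel, population) {
  rows <- which(panel$pop_map[panel$sample_ids] == population)
  if (!length(rows)) stop("population '", population, "' has zero samples")
  rows
}

#' Haplotype-row indices of a population's samples (phased panels)
#' @keywords internal
pop_hap_rows <- function(panel, population) {
  rows <- pop_rows(panel, population)
  sort(c(2L * rows - 1L, 2L * rows))
}
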