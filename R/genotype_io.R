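#' Read a multi-sample VCF into a genotype panel
#'
#' Parses a VCF 4.x file with [vcfR::read.vcfR()], keeps only biallelic SNP
#' records (single-base REF and ALT), and builds the dosage matrix from the GT
#' field. When every retained genotype is phased (`|` separator) the phased
#' haplotype matrix is populated as well; otherwise haplotypes are absent.
#' Multiallelic and non-SNP records are dropped with a message reporting the
#' count.
#'
#' @param path VCF file (plain text or bgzip/gzip).
#' @param pop_map_path two-column whitespace-delimited text file
#'   (sample id, population label).
#' @return a [genotype_panel()].
#' @export
read_vcf <- function(path, pop_map_path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  pop_map <- read_pop_map(pop_map_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  unmapped <- setdiff(samples, names(pop_map))
  if (length(unmapped)) {
    stop("sample(s) in VCF absent from population map: ",
         paste(unmapped, collapse = ", "))
  }

  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT, fixed = TRUE)
  is_snp[is.na(is_snp)] <- FALSE
  n_dropped <- sum(!is_snp)
  if (n_dropped > 0) {
    message("read_vcf: dropped ", n_dropped,
            " multiallelic/non-SNP record(s)")
  }
  fix <- fix[is_snp, , drop = FALSE]
  if (!nrow(fix)) stop("no biallelic SNP records in ", path)

  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))[is_snp]
  }
  sites <- data.frame(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    qd = info_num("QD"),
    mq = info_num("MQ"),
    fs = info_num("FS"),
    stringsAsFactors = FALSE
  )

  gt_raw <- v@gt[is_snp, -1, drop = FALSE]
  gt_field <- sub(":.*$", "", t(gt_raw))   # samples x sites
  ok <- gt_field %in% c(".", "./.", ".|.",
                        "0/0", "0/1", "1/0", "1/1",
                        "0|0", "0|1", "1|0", "1|1")
  if (any(!ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt_field[!ok][1], "' at ",
         sites$contig[bad[2]], ":", sites$pos[bad[2]],
         " sample ", samples[bad[1]])
  }
  dosage <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(sites))
  dosage[gt_field %in% c("0/0", "0|0")] <- 0L
  dosage[gt_field %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt_field %in% c("1/1", "1|1")] <- 2L

  called <- !(gt_field %in% c(".", "./.", ".|."))
  phased <- grepl("|", gt_field, fixed = TRUE)
  haplotypes <- NULL
  if (all(phased[called]) && all(called)) {
    a1 <- as.integer(substr(gt_field, 1L, 1L))
    a2 <- as.integer(substr(gt_field, 3L, 3L))
    haplotypes <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(sites))
    haplotypes[seq(1L, nrow(haplotypes), 2L), ] <- a1
    haplotypes[seq(2L, nrow(haplotypes), 2L), ] <- a2
  }

  contig_lengths <- vcf_contig_lengths(v@meta)
  seen <- unique(sites$contig)
  absent <- setdiff(seen, names(contig_lengths))
  if (length(absent)) {
    # no ##contig header: fall back to the last observed position
    ends <- vapply(absent, function(ctg) max(sites$pos[sites$contig == ctg]),
                   numeric(1))
    contig_lengths <- c(contig_lengths, stats::setNames(ends, absent))
  }

  genotype_panel(sites, dosage, samples, pop_map,
                 contig_lengths[seen], haplotypes = haplotypes)
}

vcf_contig_lengths <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(stats::setNames(numeric(0), character(0)))
  ids <- sub(".*ID=([^,>]+).*", "\\1", ln)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
  stats::setNames(lens, ids)[!is.na(lens)]
}

#' Read a sample-to-population map
#'
#' @param path two-column whitespace-delimited text (sample, population); no
#'   header.
#' @return named character vector, sample id -> population label.
#' @export
read_pop_map <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  stats::setNames(as.character(tab$population), as.character(tab$sample))
}

#' Read a known-sites list
#'
#' Accepts either a two-column whitespace-delimited text file (contig, pos) or
#' a VCF; returns the unique set of `contig:pos` keys used by
#' [classify_known_novel()].
#'
#' @param path file path.
#' @return character vector of unique `"contig:pos"` keys.
#' @export
read_known_sites <- function(path) {
  if (!file.exists(path)) stop("known-sites file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    keys <- paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])
  } else {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    keys <- paste0(tab[[1]], ":", tab[[2]])
  }
  unique(keys)
}

#' Hard-filter configuration for site-level QC
#'
#' Defaults mirror a GATK-style hard-filter recipe: sites fail when
#' QD < 5.0, MQ < 40.0, FS > 200.0 or QUAL < 30.0, and are additionally
#' removed when call rate < 0.9 or minor allele frequency <= 0.01 (MAF over
#' all samples pooled, missing alleles ignored).
#'
#' @param qd_min minimum quality-by-depth.
#' @param mq_min minimum RMS mapping quality.
#' @param fs_max maximum Fisher-strand phred score.
#' @param qual_min minimum site QUAL.
#' @param call_rate_min minimum fraction of samples with a called genotype.
#' @param maf_min_exclusive sites with MAF <= this value are removed.
#' @return a `filter_config` list.
#' @export
filter_config <- function(qd_min = 5.0, mq_min = 40.0, fs_max = 200.0,
                          qual_min = 30.0, call_rate_min = 0.9,
                          maf_min_exclusive = 0.01) {
  cfg <- list(qd_min = qd_min, mq_min = mq_min, fs_max = fs_max,
              qual_min = qual_min, call_rate_min = call_rate_min,
              maf_min_exclusive = maf_min_exclusive)
  stopifnot(all(vapply(cfg, is.finite, logical(1))),
            call_rate_min >= 0, call_rate_min <= 1,
            maf_min_exclusive >= 0, maf_min_exclusive <= 1)
  structure(cfg, class = "filter_config")
}

#' Apply hard site filters to a panel
#'
#' A site is retained only if it passes every sub-filter. A missing INFO
#' metric (`NA` QD/MQ/FS/QUAL) passes its own sub-filter: absence of the
#' metric is not evidence of failure. Call rate is the fraction of samples
#' with a called genotype; MAF is computed over all samples pooled, counting
#' non-missing alleles only. Per-filter removal counts are reported via
#' `message()` and attached as attribute `"filter_counts"`.
#'
#' @param panel a `genotype_panel`.
#' @param config a [filter_config()].
#' @param population optional population label: restrict the call-rate/MAF
#'   computation to that population's samples (INFO filters are unaffected).
#' @return the filtered `genotype_panel`.
#' @export
apply_site_filters <- function(panel, config = filter_config(),
                               population = NULL) {
  if (n_sites(panel) == 0L) stop("empty panel")
  s <- panel$sites
  g <- panel$genotypes
  if (!is.null(population)) g <- g[pop_rows(panel, population), , drop = FALSE]

  pass_na <- function(x, ok) is.na(x) | ok
  pass <- cbind(
    qd = pass_na(s$qd, s$qd >= config$qd_min),
    mq = pass_na(s$mq, s$mq >= config$mq_min),
    fs = pass_na(s$fs, s$fs <= config$fs_max),
    qual = pass_na(s$qual, s$qual >= config$qual_min),
    call_rate = colMeans(!is.na(g)) >= config$call_rate_min,
    maf = site_maf(g) > config$maf_min_exclusive
  )
  keep <- rowSums(!pass) == 0L
  removed <- colSums(!pass)
  message("apply_site_filters: ", sum(!keep), "/", length(keep),
          " sites removed (",
          paste(sprintf("%s=%d", names(removed), removed), collapse = ", "),
          "); missing INFO metrics pass their sub-filter")
  out <- subset_sites(panel, keep)
  attr(out, "filter_counts") <- c(removed,
                                  total_removed = sum(!keep),
                                  retained = sum(keep))
  out
}

#' Pooled minor allele frequency per site
#' @param g dosage matrix (samples x sites).
#' @return numeric vector of MAF values (0 when no alleles called).
#' @keywords internal
site_maf <- function(g) {
  n_alt <- colSums(g, na.rm = TRUE)
  n_called <- 2 * colSums(!is.na(g))
  p <- ifelse(n_called > 0, n_alt / n_called, 0)
  pmin(p, 1 - p)
}

#' Classify panel sites as known or novel
#'
#' A site is known iff its `contig:pos` key appears in the known-site set
#' (e.g. a dbSNP extract); all other sites are novel.
#'
#' @param panel a `genotype_panel` (non-empty).
#' @param known_sites character vector of `"contig:pos"` keys, e.g. from
#'   [read_known_sites()].
#' @return list with `known` (logical per site), `known_count`,
#'   `novel_count`, and `novel_fraction` (novel/total, rounded to 4 decimals).
#' @export
classify_known_novel <- function(panel, known_sites) {
  if (n_sites(panel) == 0L) stop("empty panel")
  keys <- paste0(panel$sites$contig, ":", panel$sites$pos)
  known <- keys %in% known_sites
  c(list(known = known),
    known_novel_summary(sum(known), sum(!known)))
}

#' Known/novel count arithmetic
#'
#' @param known_count number of sites found in the known set.
#' @param novel_count number of sites absent from the known set.
#' @return list with the counts and `novel_fraction` = novel/total rounded to
#'   4 decimals.
#' @export
known_novel_summary <- function(known_count, novel_count) {
  total <- known_count + novel_count
  if (total == 0) stop("no sites")
  list(known_count = known_count, novel_count = novel_count,
       novel_fraction = round(novel_count / total, 4))
}

#' Write a genotype panel as VCF 4.2
#'
#' Emits a plain-text VCF with `##contig` headers, QD/MQ/FS INFO keys where
#' present, and GT genotypes (phased `|` when the panel carries haplotypes,
#' `/` otherwise). The formatting is canonical, so write-read-write is
#' byte-identical.
#'
#' @param panel a `genotype_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  s <- panel$sites
  num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g", digits = 6))
  info <- apply(cbind(QD = num(s$qd), MQ = num(s$mq), FS = num(s$fs)), 1L,
                function(row) {
                  row <- row[!is.na(row)]
                  if (!length(row)) "." else
                    paste(names(row), row, sep = "=", collapse = ";")
                })
  phased <- !is.null(panel$haplotypes)
  if (phased) {
    h <- panel$haplotypes
    a1 <- h[seq(1L, nrow(h), 2L), , drop = FALSE]
    a2 <- h[seq(2L, nrow(h), 2L), , drop = FALSE]
    gt <- matrix(paste0(a1, "|", a2), nrow = nrow(a1))
  } else {
    g <- panel$genotypes
    gt <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
    gt[!is.na(g) & g == 0L] <- "0/0"
    gt[!is.na(g) & g == 1L] <- "0/1"
    gt[!is.na(g) & g == 2L] <- "1/1"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(panel$contig_lengths),
            as.integer(panel$contig_lengths)),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand phred p\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  body <- paste(s$contig, s$pos, s$id, s$ref, s$alt,
                ifelse(is.na(s$qual), ".", num(s$qual)), "PASS", info, "GT",
                apply(gt, 2L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a table of results as TSV
#'
#' @param rows a data.frame.
#' @param path output file; written tab-separated with a header line.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
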