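#' Merge significant windows into candidate regions
#'
#' Overlapping or book-ended (exactly adjacent) windows from one method are
#' merged into maximal regions; the best statistic among a region's source
#' windows is carried along (minimum for ZHp, maximum for XP-EHH). Merging is
#' idempotent and independent of input order.
#'
#' @param windows data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and a statistic column.
#' @param method label recorded on the output (`"zhp"`, `"xpehh"`, ...); also
#'   selects the direction of "best": `"zhp"` keeps the minimum statistic,
#'   anything else the maximum.
#' @param stat_col name of the statistic column (default `"zhp"` when
#'   `method == "zhp"`, else `"max_score"`).
#' @return data.frame of non-overlapping regions: `contig`, `start`, `end`,
#'   `method`, `n_windows`, `best_stat`.
#' @export
merge_regions <- function(windows, method = "xpehh",
                          stat_col = if (method == "zhp") "zhp"
                                     else "max_score") {
  if (nrow(windows) == 0L) {
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), method = character(),
                      n_windows = integer(), best_stat = numeric(),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = windows$contig,
    ranges = IRanges::IRanges(start = windows$start + 1, end = windows$end)
  )
  merged <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(merged)$revmap
  stat <- windows[[stat_col]]
  pick <- if (method == "zhp") min else max
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = GenomicRanges::end(merged),
    method = method,
    n_windows = lengths(revmap),
    best_stat = vapply(revmap, function(i) pick(stat[i]), numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene intervals from BED or GFF3
#'
#' BED input (0-based half-open, gene id in column 4) and GFF3 input (1-based
#' inclusive, converted on read; gene id from the `ID` or `gene_id`
#' attribute) both yield the package's internal 0-based half-open
#' convention. For GFF3, rows of type `gene` are used when present.
#'
#' @param path BED (`.bed`) or GFF3 (`.gff`, `.gff3`) file.
#' @return data.frame: `contig`, `start`, `end` (0-based half-open),
#'   `gene_id`, `strand`.
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) stop("gene file not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) {
    if ("type" %in% names(md) && any(md$type == "gene")) {
      keep <- md$type == "gene"
      gr <- gr[keep]
      md <- md[keep, , drop = FALSE]
    }
    ids <- if ("ID" %in% names(md) && !all(is.na(md$ID))) md$ID
           else if ("gene_id" %in% names(md)) md$gene_id
           else as.character(seq_along(gr))
  } else {
    ids <- if ("name" %in% names(md)) md$name else as.character(seq_along(gr))
  }
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    gene_id = as.character(ids),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Genes overlapping candidate regions
#'
#' A gene is reported for a region iff the two intervals share at least 1 bp
#' (book-ended intervals do not overlap); strand is ignored. Contigs present
#' in the regions but absent from the annotation trigger a warning and yield
#' zero genes.
#'
#' @param regions data.frame from [merge_regions()].
#' @param gene_intervals data.frame from [read_gene_intervals()] (0-based
#'   half-open).
#' @return list with `per_region` (data.frame: region coordinates +
#'   comma-separated `genes`) and `genes` (unique gene ids, duplicates
#'   collapsed).
#' @export
genes_in_regions <- function(regions, gene_intervals) {
  missing_ctg <- setdiff(unique(regions$contig),
                         unique(gene_intervals$contig))
  if (length(missing_ctg)) {
    warning("contig(s) absent from gene annotation: ",
            paste(missing_ctg, collapse = ", "))
  }
  if (nrow(regions) == 0L) {
    return(list(per_region = cbind(regions, genes = character(0)),
                genes = character(0)))
  }
  lv <- union(unique(regions$contig), unique(gene_intervals$contig))
  r_gr <- GenomicRanges::GRanges(factor(regions$contig, lv),
                                 IRanges::IRanges(regions$start + 1,
                                                  regions$end))
  g_gr <- GenomicRanges::GRanges(factor(gene_intervals$contig, lv),
                                 IRanges::IRanges(gene_intervals$start + 1,
                                                  gene_intervals$end))
  hits <- GenomicRanges::findOverlaps(r_gr, g_gr, minoverlap = 1L)
  per <- vapply(seq_len(nrow(regions)), function(i) {
    ids <- gene_intervals$gene_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
    paste(unique(ids), collapse = ",")
  }, character(1))
  uniq <- unique(gene_intervals$gene_id[S4Vectors::subjectHits(hits)])
  list(per_region = cbind(regions, genes = per, stringsAsFactors = FALSE),
       genes = uniq)
}

#' Gene-level overlap between two scan methods
#'
#' @param genes_a,genes_b character vectors of gene ids (e.g. the `genes`
#'   element of [genes_in_regions()] for each method).
#' @return list with `shared`, `a_only`, `b_only` (character vectors) and the
#'   corresponding counts `n_shared`, `n_a_only`, `n_b_only`.
#' @export
method_overlap <- function(genes_a, genes_b) {
  genes_a <- unique(genes_a)
  genes_b <- unique(genes_b)
  shared <- intersect(genes_a, genes_b)
  list(shared = shared,
       a_only = setdiff(genes_a, genes_b),
       b_only = setdiff(genes_b, genes_a),
       n_shared = length(shared),
       n_a_only = length(setdiff(genes_a, genes_b)),
       n_b_only = length(setdiff(genes_b, genes_a)))
}

#' Write regions as BED
#'
#' @param regions data.frame with `contig`, `start`, `end` and optionally
#'   `method`/`best_stat` (written as name/score columns).
#' @param path output BED file (0-based half-open, as BED requires).
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  name <- if ("method" %in% names(regions)) regions$method else "."
  score <- if ("best_stat" %in% names(regions)) {
    formatC(regions$best_stat, format = "g", digits = 6)
  } else "0"
  lines <- paste(regions$contig, format(regions$start, scientific = FALSE,
                                        trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 name, score, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
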