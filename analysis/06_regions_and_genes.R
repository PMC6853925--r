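#!/usr/bin/env Rscript
# Merge the significant windows of each scan into candidate regions under
# selection, annotate them with the (synthetic) gene intervals, and report
# the gene-level overlap between the two methods. On a single 2 Mb contig
# the ZHp branch uses the ranking-based minimum window as its candidate.

suppressPackageStartupMessages(library(sweepscan))

z <- read.delim("results/zhp_windows.tsv")
sig <- read.delim("results/xpehh_windows.tsv")
genes <- read_gene_intervals("results/fixture/genes.bed")

# ZHp candidates: strict threshold windows if any, else the genome minimum
zc <- z[!is.na(z$zhp) & z$candidate, , drop = FALSE]
if (nrow(zc) == 0) zc <- z[which.min(z$zhp), , drop = FALSE]
reg_z <- merge_regions(zc, method = "zhp")
reg_x <- merge_regions(sig[sig$significant, , drop = FALSE],
                       method = "xpehh")
regions <- rbind(reg_z, reg_x)
write_regions_bed(regions, "results/candidate_regions.bed")

gz <- genes_in_regions(reg_z, genes)
gx <- genes_in_regions(reg_x, genes)
ov <- method_overlap(gz$genes, gx$genes)
write_table(rbind(gz$per_region, gx$per_region), "results/region_genes.tsv")

cat("Candidate regions under selection:\n")
print(regions, row.names = FALSE)
cat(sprintf("\nGenes in candidate regions: %d (ZHp), %d (XP-EHH), %d shared\n",
            length(gz$genes), length(gx$genes), ov$n_shared))
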