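#!/usr/bin/env Rscript
# Summarize XP-EHH scores over non-overlapping 50 kb windows by the maximum
# score, bin windows by SNP density (increments of 500 SNPs, >= 1000 pooled),
# and assign within-bin empirical p-values (fraction of windows with a
# strictly greater statistic). Windows with p < 0.005 are significant.

suppressPackageStartupMessages(library(sweepscan))

panel <- read_vcf("results/fixture/panel.vcf", "results/fixture/popmap.txt")
panel <- apply_site_filters(panel, filter_config())
xp <- read.delim("results/xpehh_scores.tsv")

sig <- xpehh_window_significance(xp, panel$contig_lengths)
write_table(sig, "results/xpehh_windows.tsv")

truth <- read.table("results/fixture/truth.bed",
                    col.names = c("contig", "start", "end", "name"))
hits <- sig[sig$significant, , drop = FALSE]
cat(sprintf("%d windows with >= 1 scored SNP; %d significant at p < 0.005\n",
            nrow(sig), nrow(hits)))
if (nrow(hits)) {
  print(hits, row.names = FALSE)
  cat("Significant window overlapping truth:",
      any(hits$start < truth$end & hits$end > truth$start), "\n")
}
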