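#!/usr/bin/env Rscript
# Simulate the study condition: a 2 Mb contig carrying a hard selective
# sweep (150 kb halo, carrier frequency 0.9) in a small isolated population
# of 12 diploids, alongside a 10-diploid reference population, and export
# the panel with its truth annotation. Everything downstream (02-06) works
# off these files.

suppressPackageStartupMessages(library(sweepscan))

seed <- 1
out_dir <- "results/fixture"

fx <- simulate_sweep_fixture(seed = seed)
paths <- export_fixture(fx$panel, fx$truth, out_dir, fx$params)

cat("Simulated panel:", n_sites(fx$panel), "biallelic SNPs,",
    length(fx$panel$sample_ids), "samples on a",
    sprintf("%.1f Mb", sum(fx$panel$contig_lengths) / 1e6), "contig\n")
cat("Sweep truth interval:", fx$truth$contig,
    sprintf("[%d, %d)", fx$truth$start, fx$truth$end),
    "in population", fx$truth$population, "\n")
cat("Files written:\n")
cat(paste(" -", paths, collapse = "\n"), "\n")
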