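---
title: "Detecting selective sweeps with ZHp and XP-EHH: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with ZHp and XP-EHH: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a beneficial allele rises quickly to (near-)fixation in a population it
drags its chromosomal neighbourhood along: local heterozygosity collapses and
unusually long haplotypes reach high frequency. `sweepscan` implements two
complementary genome scans for this signal on multi-sample SNP panels, of the
kind produced by short-read resequencing of two diverged populations — a
small, isolated population under putative selection and a larger reference
population:

* **ZHp**, a single-population allele-frequency scan: pooled heterozygosity
  in sliding windows, Z-transformed genome-wide, with extreme negative
  scores marking fixation troughs. It is sensitive to *completed* sweeps.
* **XP-EHH**, a cross-population haplotype scan: the log-ratio of integrated
  extended haplotype homozygosity between the two populations, z-normalized
  per core SNP. It is sensitive to *ongoing or recent* sweeps in which one
  population carries a long, frequent haplotype that the other lacks.

Around the scans the package provides the standard plumbing of such studies:
GATK-style hard site filtering, per-population site statistics (Ts/Tv,
fixed non-reference sites, shared/private segregating sites, windowed
nucleotide diversity), window-level significance by SNP-density-binned
empirical p-values, candidate-region merging with gene annotation, and a
forward-in-time simulator that generates truth-annotated synthetic panels so
that every stage is testable end to end without any external data.

# Site filtering

A site survives [`apply_site_filters()`] only if it passes **all** of:

| filter | rule | default |
|---|---|---|
| quality by depth | QD ≥ `qd_min` | 5.0 |
| mapping quality | MQ ≥ `mq_min` | 40.0 |
| Fisher strand | FS ≤ `fs_max` | 200.0 |
| site quality | QUAL ≥ `qual_min` | 30.0 |
| call rate | fraction called ≥ `call_rate_min` | 0.9 |
| minor allele frequency | MAF > `maf_min_exclusive` | 0.01 |

Design choices worth stating explicitly:

* **Missing INFO metrics pass their own sub-filter.** Absence of a metric is
  not evidence of failure; variant callers emit these fields on called
  sites, while synthetic or externally processed panels may omit them. The
  count of sites passing-by-absence is logged.
* **MAF is computed over all samples pooled**, ignoring missing alleles. A
  per-population variant of the call-rate/MAF screen is exposed through the
  `population` argument, since reasonable pipelines differ here.
* **Multiallelic records are dropped, not split.** The scans are defined on
  biallelic SNPs; splitting would introduce allele-matching semantics the
  downstream statistics never use.
* Filtering is conjunctive per site, hence idempotent and order-free — both
  properties are asserted in the test suite.

Coordinates are 1-based inside VCFs (as the format requires) and 0-based
half-open in every internal window computation; conversion happens at I/O
boundaries only.

# Site statistics

**Ts/Tv.** Transitions are A↔G and C↔T; the eight remaining ordered pairs
are transversions, so every biallelic SNP falls in exactly one class. The
ratio is reported at full precision in tables and rounded to two decimals in
summaries. With zero transversions the ratio is reported as `NA`, never
infinity.

**Fixed sites.** A site is fixed for the non-reference allele in a
population iff *every* sample is called and homozygous alternate. Sites with
any missing genotype are excluded — the strict complete-case reading of
"homozygous in the entire population" — and the near-misses are logged.

**Nucleotide diversity.** Per site, π is the unbiased pairwise
heterozygosity `2·n_ref·n_alt / (n·(n−1))` over the `n` called alleles;
window π sums site values over a 10 kb window and divides by the full window
length, invariant positions included (the convention of the standard VCF
diversity tools, which makes values comparable across SNP densities). Mean
diversity weights windows by their length, so truncated terminal windows do
not distort the average. The per-site formula is verified in the tests
against exhaustive enumeration of all C(n, 2) allele pairs.

# The ZHp scan

For a window, with `ΣnMAJ` and `ΣnMIN` the summed major and minor allele
counts of its SNPs,

$$\mathrm{Hp} = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
                     {(\Sigma n_{MAJ} + \Sigma n_{MIN})^2},$$

which lies in [0, 0.5], is invariant to ref/alt label swaps, and attains 0.5
exactly when the summed counts balance. ZHp is the genome-wide Z-transform
`(Hp − mean) / sd` over retained windows.

Parameters (defaults in parentheses): window span (150 kb), overlap (50%),
MAF screen before pooling (sites with MAF < 0.05 removed), minimum SNPs per
retained window (10), candidate threshold (ZHp < −3.5, strict).

Numerical and convention choices:

* Windows are anchored at position 0 of each contig and advance by
  `window_bp × (1 − overlap)`; the final window is truncated at the contig
  end, and a contig shorter than one window yields a single truncated
  window. Window enumeration stops at the first window reaching the contig
  end, so a 300 kb contig holds exactly three 150 kb half-overlapping
  windows.
* On a major/minor tie the reference allele is counted major; Hp is
  symmetric in the two counts, so the tie-break cannot affect any result.
* The Z-transform uses the sample standard deviation (denominator n − 1).
* The −3.5 threshold is strict (`<`). A genome-scale threshold is only
  meaningful with thousands of windows; on the 2 Mb synthetic condition
  (~25 windows) the minimum of 25 standard normal variates is nowhere near
  −3.5, so the analysis drivers use the *ranking* (the genome-minimum
  window) as the single-contig readout, and the candidate threshold remains
  available for genome-scale inputs.

# The XP-EHH scan

**EHH.** From a core SNP, haplotypes are grouped by their allele string from
the core out to each flanking marker (core allele included); EHH at a marker
is the probability that two randomly drawn haplotypes are identical over
that span, `Σ_g C(n_g, 2) / C(n, 2)`. EHH starts at 1 at the core and is
non-increasing. All haplotypes of a population enter the computation —
core-allele stratification (as in within-population iHS) is deliberately not
used; the cross-population contrast carries the signal.

**Decay-point recording.** A marker that splits no group — in particular any
monomorphic marker — adds no information, so curves record only markers at
which EHH actually drops. This makes the integral exactly invariant to
inserting uninformative markers (a property the tests assert), while
trapezoidal integration between decay points is unchanged for informative
markers.

**iHH and the score.** iHH is the trapezoidal area under EHH versus physical
distance (bp; no genetic map is assumed), summed over both directions. The
two populations are integrated over *shared bounds*: extension stops where
the EHH of the pooled sample (all haplotypes of both populations) falls
below `stop_cutoff` (default 0.05), with the crossing distance interpolated
linearly. Shared bounds prevent the ratio from comparing areas over
different genomic spans. The raw score is `ln(iHH_obs / iHH_ref)`; z-scores
normalize to mean 0, sd 1 (sample sd) over scored cores. A core whose pooled
EHH never decays below the cutoff before a contig end is flagged truncated
and excluded from normalization by default (`exclude_truncated`), because
truncated areas bias the ratio toward whichever population decays slower.

The per-core extension loop is implemented in C++ (as haplotype-scan tools
in this field generally do); a plain-R reference implementation of the same
per-core computation ships in the package and the two are required to agree
to 10 decimal places on randomized panels in the test suite. EHH itself is
verified against exhaustive identical-pair counting on panels of up to 12
haplotypes.

**Phasing.** The scan requires phased haplotypes. For unphased input,
[`pseudo_phase()`] offers deterministic seeded random assignment of
heterozygous alleles — off by default, and documented as destroying
long-range haplotype structure: scores on pseudo-phased data underestimate
true homozygosity and should be treated as exploratory only.

# Window significance

XP-EHH scores are summarized over non-overlapping 50 kb windows by the
maximum score among a window's SNPs; windows without scored SNPs are
dropped. Because SNP-dense windows take maxima over more draws, windows are
compared only within SNP-density bins: increments of 500 SNPs, with all
windows of ≥ 1000 SNPs pooled into one bin — i.e. bins [1, 500), [500,
1000), [1000, ∞). The first bin starts at 1 because zero-SNP windows are
dropped, the only self-consistent reading of "increments of 500".

Within a bin, the empirical p-value of window *i* is the fraction of windows
whose statistic is **strictly greater**; the window never counts itself, so
the best window of each bin always has p = 0, and tied windows share a p.
Significance is `p < 0.005`, strict. Two deliberate literalisms, both
configurable:

* "maximum (positive) score" is read as the literal maximum — an
  all-negative window keeps its least-negative value — with
  `positive_only = TRUE` available for the stricter reading under which such
  windows are dropped.
* No pseudo-count is added; an optional `(r + 1)/(n + 1)` correction
  (`add_one = TRUE`) avoids exact zeros but is off by default, reproducing
  the counting rule exactly. Note one consequence of the strict rule: in a
  bin of identically-scored windows *every* window has p = 0; the rule is
  reproduced literally rather than patched.

A direct consequence of the p = 0 floor: at α = 0.005 the method can never
report fewer than ~1 window per bin per genome, so the *attainable*
false-positive floor is ~1/n_windows. The neutral control (below) is sized
with this in mind.

# Candidate regions and genes

Significant windows of each method are merged when they overlap or are
book-ended (adjacent); merged regions carry the count of source windows and
the best statistic (minimum ZHp, maximum XP-EHH). Merging is idempotent and
order-independent. A gene (from BED, 0-based half-open, or GFF3, 1-based
inclusive, converted on read) is reported for a region iff they share at
least 1 bp — book-ended intervals do not overlap — with strand ignored and
duplicates collapsed in the per-method unique gene set. Method agreement is
computed at the *gene* level (set intersection of gene ids), with
region-level BED output also emitted. Any-overlap rather than full
containment is the permissive default for "gene in region".

# The synthetic study condition

The simulator exists to give the scans a controlled input with a known
answer, not to model any real demography.

**Neutral model.** A pool of `founder_haplotypes` (40) identical haplotypes
evolves forward in time: each generation every offspring haplotype is formed
from two random parents with at most one uniformly-placed crossover
(probability `min(1, r·L)`), then receives `Poisson(µ·L)` new mutations at
fresh positions. The first half of `n_generations` (400) is a shared
burn-in; two copies of the pool then evolve independently, diverging by
drift. Finally `2 × n_samples` haplotypes per population (12 + 10 diploids)
are drawn and paired into individuals.

**Rates are scaled up, sizes scaled down.** With µ = 3×10⁻⁶ /bp/gen,
r = 5×10⁻⁷ /bp/gen and L = 2 Mb, the sampled panel carries ~3 SNPs/kb with
linkage decaying over tens of kb — enough structure for all scans at desk
scale. Consequences a user should know:

* Drift is fast (2N = 40): after 200 post-split generations essentially all
  *ancestral* polymorphism has fixed or been lost, so the two populations
  share fixed derived sites (removed by the pooled MAF screen) but almost no
  segregating sites. Real diverged breeds share far more polymorphism.
* The site-frequency spectrum is equilibrium-neutral per population; there
  is no population growth, migration, or sequencing error model.
* Ref/alt bases are drawn with a 2:1 transition bias, so synthetic panels
  show a genome-wide Ts/Tv near 2 — a realism check, not a calibration.
* QUAL/QD/MQ/FS are synthesized in passing ranges;
  `contaminate_fraction > 0` plants known failing sites to exercise the
  filters.

**Sweep injection.** Rather than simulating selection dynamics, one donor
haplotype's alleles over `[core − halo, core + halo]` are copied into a
seeded fraction `carrier_freq` of the target population's haplotypes. This
produces precisely the signal the scans are built for — a long,
high-frequency shared haplotype with locally depressed heterozygosity — and,
crucially, an *exact* truth interval for recovery tests. The default study
condition is a 2 Mb contig, sweep at the midpoint, halo 150 kb, carrier
frequency 0.9.

Passing the recovery tests on this fixture demonstrates that the statistics
rank a textbook hard sweep correctly against a neutral background of the
simulated kind; it does not demonstrate power on soft sweeps, background
selection, bottlenecks, or real sequencing artefacts, none of which the
generator emulates.

**Determinism.** All randomness flows from the `seed` in the parameter
object; the global RNG state of the caller is saved and restored. Identical
parameters and seed reproduce byte-identical exported fixtures, and the
JSON manifest written next to each fixture suffices to regenerate it.

# Problem sizes used in the shipped analyses

The analysis drivers and the acceptance checks run, on one CPU:

* the default sweep fixture (2 Mb, 22 diploids, ~6000 SNPs): simulation
  ~4 s, full XP-EHH scan ~2 s;
* a neutral control of 20 replicates, each three 2 Mb contigs — 120
  fifty-kb windows per replicate, so the attainable false-positive floor
  (~1/120 ≈ 0.008) sits meaningfully below the 0.01 criterion;
* brute-force oracle comparisons on panels of ≤ 12 haplotypes, where
  exhaustive pair enumeration is exact and fast.

# Known limitations

* XP-EHH uses physical distance only; with a genetic map the integrals
  would weight recombination-dense regions differently.
* The empirical-p floor of 0 means the top window per bin is always
  "significant" at any α; genome-scale inputs with many windows per bin
  dilute this artefact, desk-scale inputs do not — interpret single-contig
  significance through the truth-overlap checks, not the p-value alone.
* The simulator's single-crossover meiosis underestimates double-crossover
  shuffling on long contigs; LD decay is therefore slightly slower than a
  Poisson-recombination model at the same r.
* `pseudo_phase()` does not impute; missing genotypes become homozygous
  reference, acceptable only for the exploratory use it is intended for.
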