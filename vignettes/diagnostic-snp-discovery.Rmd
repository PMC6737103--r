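---
title: "Methods: discovering and validating species-diagnostic SNP markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and validating species-diagnostic SNP markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagsnp)
```

## The problem

Hybridisation and introgression between closely related species — tilapias
are the motivating case, where *Oreochromis niloticus*, *O. aureus*,
*O. mossambicus* and *O. u. hornorum* are routinely crossed in aquaculture
and escape into the wild — can only be analysed with markers that separate
the species cleanly. `diagsnp` implements the downstream analysis of a
reduced-representation (ddRAD-style) genotyping study: starting from a
multi-species diploid genotype matrix, it identifies *species-diagnostic*
SNP markers, screens them for assay designability, and validates candidate
panels with allele-frequency tables and cross-platform concordance.

## Definitions and the discovery model

All stages operate on a `geno_matrix`: unphased diploid calls over A/C/G/T
at SNP sites grouped into RAD loci (tags), with per-call missingness. Three
locus-level definitions drive filtering (`filter_shared_loci()`):

* a **polymorphic locus** is a RAD-tag with at least one SNP (a site
  showing two or more alleles among non-missing calls);
* a **shared locus** is a polymorphic locus genotyped in at least a
  fraction `presence_threshold` (default 0.75) of all samples, at every one
  of its SNPs;
* under `require_biallelic` (default), a tag is dropped whole if any of its
  sites shows more than two alleles — the strictest reading of a biallelic
  tag, chosen because every downstream assay targets a two-allele contrast.

A site is **diagnostic** for a focal taxon (`find_diagnostic_markers()`)
when every analysed taxon is *fixed* at the site — no heterozygote and no
second allele within the taxon, with at least `presence_threshold` of the
taxon's samples genotyped — and the fixed alleles form a one-vs-rest
partition: the focal taxon carries one allele, all other taxa the other.
Strictness is deliberate: a single heterozygote or discordant homozygote
disqualifies a site, because downstream assays rely on the allele being
truly absent elsewhere. A taxon falling below the presence threshold
disqualifies the site entirely rather than being ignored, since fixation
cannot be asserted for a taxon that was barely observed. Taxa with a single
sample are allowed but flagged: fixation is unverifiable at n = 1.

With exactly two analysed taxa every fixed difference is diagnostic in both
directions; one marker per site is reported (focal = first taxon) so
pairwise counts stay per-site. Discovery is always recomputed on the
analysed sample subset — a marker set found for four species is generally
larger than for ten, because removing taxa removes constraints (the
subset-monotonicity property tested in the suite).

### SNPs-per-locus caps

Two different caps share one configuration knob, `max_snps_per_locus`:

* In `filter_shared_loci()` it caps *all* SNPs on a tag; tags over the cap
  are dropped whole, never thinned, because selection happens at locus
  granularity.
* In `find_diagnostic_markers()` the shared-locus prefilter runs with the
  cap disabled, and the cap is then applied to the number of
  *species-specific* SNPs on the tag (`snps_on_locus`). This is the "up to
  k SNPs per locus" bookkeeping that `tabulate_snps_per_locus()` turns into
  a cumulative per-taxon count table, whose rows are monotone by
  construction.

### Assay candidates and panels

`filter_assay_candidates()` keeps markers whose SNP lies at least
`min_edge_distance_bp` (default 20 bp) from **both** ends of its tag
(default 148 bp), leaving flanking sequence for allele-specific primers,
and whose tag carries at most two species-specific SNPs. The rule is
applied to both ends as the conservative design-feasibility reading.
Markers with unknown offsets are excluded with a visible counter, never
silently.

`select_panel()` reduces a catalog to a fixed-size panel. The selection
rule is this package's own design (published panels rarely state theirs):
greedy, preferring (1) the focal taxon currently least represented, then
(2) the linkage group with fewest selected markers, then (3) catalog order
— fully deterministic, with a best-effort panel and a warning when perfect
balance is infeasible.

## Validation model

`allele_frequency_table()` reports, per marker and taxon, the percentage of
the diagnostic allele among non-missing **alleles** (two per genotyped
individual). Allele-count denominators are used rather than individual
counts because published per-taxon percentages such as 31, 56 or 9 are not
multiples of 1/N — they arise naturally from 2N allele counts. Taxa with no
genotyped individual yield `NA`, not 0. Exact values are stored;
printing rounds (half-up) to whole percent.

`classify_markers()` judges each marker over its *discrimination set* — all
taxa except a designated excluded taxon, supporting designs meant to
separate only three of four species. Tiers: `fully_diagnostic` (100% in the
focal taxon, 0% elsewhere), `near_diagnostic_target_leak` (clean off-target
columns, some alternate allele in the target), `near_diagnostic_offtarget_leak`
(clean target, off-target leak at most `leak_cutoff_pct`, default 5%), else
`failed`. The cutoff applies to off-target leaks only, so raising it never
demotes a marker — the monotonicity tested in the suite. Target-side leaks
are reported as percentages and left to the analyst's judgement rather than
thresholded, since a rare alternate allele in the target population is a
sampling statement, not an assay failure.

`genotype_concordance()` compares two platforms (e.g. sequencing-derived
calls vs single-SNP PCR assays) over shared markers and samples: cells
missing on either side are excluded from the comparable count, matching is
on unordered allele pairs, and mismatches are typed as het-vs-hom,
discordant homozygotes or discordant heterozygotes. Het-vs-hom mismatches
are the expected signature of RAD allelic dropout, which assay platforms
tend to resolve correctly.

## Ordination and tree checks

`composite_genotypes()` concatenates each individual's calls into one
IUPAC-coded sequence (heterozygote → two-fold ambiguity code, missing →
`N`) for export to external tree builders; IUPAC is the convention ML
programs accept. `compute_pca()` codes genotypes as minor-allele dosages
(0/1/2; minor allele over all analysed samples, ties alphabetic), imputes
missing dosages with the per-site mean and centres columns — no
allele-frequency scaling, so cumulative-variance figures from differently
coded PCAs are not directly comparable. Signs are fixed by making each
component's largest-magnitude loading positive. `allele_sharing_distance()`
is `1 − shared alleles / (2 × sites called in both)`; it is symmetric with
zero diagonal but not guaranteed metric, which neighbor-joining
(`nj_tree()`, via `ape::nj`) does not require. The NJ tree is an internal
discrimination check — species should come out monophyletic when
species-level fixed differences exist — not a substitute for a
maximum-likelihood analysis with support values.

## The synthetic generator

`simulate_genotypes()` produces matrices with exactly the structure the
analysis assumes, plus a truth table, so every stage is testable without
external data. Its defaults describe a ten-species, 132-sample design with
uneven group sizes (the largest species split 30/33 into two subspecies),
148 bp tags and 1–5 SNPs per locus. Where a published design does not pin a
value, the defaults were chosen once as field-realistic and are not tuned:
500 loci; planted diagnostic fraction 0.005 per taxon (diagnostic loci are
a small minority of shared loci); background alternate-allele frequencies
from Beta(0.8, 0.8), the U-shaped spectrum typical of SNP panels; 5%
per-call missingness; 10% heterozygote dropout, reflecting the known
under-representation of heterozygotes in RAD data; 1% platform error for
the replicate.

Planted sites are homozygous diagnostic in the focal taxon and homozygous
alternate elsewhere *before* noise; all sites of a planted locus target the
same taxon, exercising the SNPs-per-locus bookkeeping. Background loci
share one allele frequency across all taxa — there is deliberately **no
species tree and no drift**: the diagnostic filter only distinguishes
fixed-vs-not, so background differentiation would add realism without
adding test power. Consequences to keep in mind: passing recovery tests
show correctness of the discovery logic, not robustness to genuine
population structure, linkage, or locus dropout correlated with divergence
(none of which are simulated; there is also no read-level error model).
Noise stages run in a fixed order (heterozygote dropout, then missingness),
each from its own substream of the mandatory seed, so adding a stage never
perturbs earlier draws and results are bit-reproducible.

`platform_replicate()` emulates re-typing on a second platform: dropped
heterozygotes are restored with probability `platform_error_rate`
(assays resolve heterozygotes better), other cells go missing at the same
rate; an exact mode plants precise numbers of het-vs-hom discordances and
missing cells on disjoint cells for arithmetic fixtures.

## Numerical and degenerate-input choices

* Presence is compared with `>=` on the exact fraction — 3 of 4 samples
  passes a 0.75 threshold; no integer rounding anywhere.
* Genotypes are unordered pairs; half-calls (`A/.`) are rejected as
  malformed rather than coerced.
* VCF coordinates are 1-based, tag offsets 0-based, BED intervals 0-based
  half-open; every writer documents its convention. Locus grouping in VCFs
  uses the `locus_offset` ID dialect; without it each record becomes its
  own single-site locus and a warning explains that per-locus counts
  degenerate.
* Indels and symbolic alleles are skipped with a counter; analyses are
  SNP-only.
* An all-constant matrix yields a zero-variance PCA rather than an error;
  an all-missing taxon yields `NA` frequencies; an empty discrimination set
  classifies as `failed`.
* Catalog order is (chrom, pos, locus, site index) with unknown coordinates
  last, making every export byte-stable across runs.

## Problem sizes used by the test suite

The suite favours many small, fully checkable instances: brute-force
oracle equivalence runs on 200 random matrices of up to ~16 loci × 12
samples × 4 taxa; planted-recovery runs 20 seeds of a 4-taxon, 60-locus
design; the tree check uses the full ten-taxon design at 300 loci; the
concordance fixture is the 34-sample × 24-marker two-platform layout. These
sizes were chosen so that an independent literal re-implementation of every
definition can be run alongside the package on each instance.

## Known limitations

* Fixation is judged on the sample, not the population: small groups can
  appear fixed by chance, and follow-up screening of wider panels routinely
  reveals low-frequency alternate alleles (the near-diagnostic tiers exist
  for exactly this reason).
* Discovery is strict one-vs-rest; markers that jointly (but not singly)
  separate taxa are out of scope, as are ML tree search, bootstrap support
  and discriminant analyses.
* The generator's simplifications (above) mean quantitative findings on
  synthetic data — e.g. PCA variance fractions — do not transfer to real
  data; only the logical properties do.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, missing_rate = 0, het_dropout_rate = 0,
                  planted_diagnostic_fraction = 0.01)
sim <- simulate_genotypes(cfg)
shared <- filter_shared_loci(sim$matrix, filter_config(max_snps_per_locus = 5))
cat5 <- find_diagnostic_markers(sim$matrix, filter_config(max_snps_per_locus = 5))
tabulate_snps_per_locus(cat5, max_k = 5)
cand <- filter_assay_candidates(cat5, locus_info(sim$matrix), filter_config())
panel <- select_panel(cand, size = min(24, nrow(cand)))
freqs <- allele_frequency_table(sim$matrix, panel$markers)
classify_markers(freqs)
```
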