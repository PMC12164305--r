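---
title: "Methods: drift simulation, FST estimation, and the differential-selection scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift simulation, FST estimation, and the differential-selection scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstscan)
```

`fstscan` covers the analysis stage that follows variant calling in a
multi-breed resequencing study: genotype QC, population structure, genome-wide
differentiation, and the detection of differential selection regions (DSRs)
between pairs of populations. This vignette documents the models, the
numerical choices, and the limits of each component.

## The simulation model

### Balding–Nichols drift

Each SNP has an ancestral allele frequency $\pi$ drawn uniformly from
`ancestral_freq_range` (default $[0.05, 0.95]$, avoiding SNPs that would be
immediately removed by the MAF filter and wasting panel size). A population
with drift parameter $c \in (0,1)$ has its frequency drawn as

$$p \sim \mathrm{Beta}\!\left(\pi \frac{1-c}{c},\; (1-\pi)\frac{1-c}{c}\right),$$

with mean $\pi$ and variance $c\,\pi(1-\pi)$ — the Balding–Nichols
parameterisation in which $c$ is the population's $F_{ST}$ against the
ancestor. Draws are clamped to $[10^{-9}, 1-10^{-9}]$ so downstream
log-likelihoods and binomial draws never see exact 0/1.

Populations may share internal branches of a **drift tree**
(`sim_config(tree_groups = ...)`): the ancestor first drifts along the shared
branch, then each leaf drifts independently from that intermediate frequency.
Two Beta steps with parameters $c_1$, $c_2$ compound to an effective drift of
$1-(1-c_1)(1-c_2)$, because the variance relation composes multiplicatively
in $(1-c)$.

For two leaves $i, j$, the expected pairwise Weir–Cockerham $F_{ST}$ is
approximately the *mean* of the drifts accumulated on the non-shared parts of
their paths, $(c_i + c_j)/2$. This identity is what calibrates
`sim_config_three_breeds()`: leaf drifts $0.09/0.09/0.17$ with an inner
branch of $0.088$ above the close pair yield realised pairwise $F_{ST}$ of
about $0.090 / 0.170 / 0.168$ — matching the magnitudes typical of closely
related versus more distant pig breeds. The diverged outgroup uses $c = 0.6$.

### Planted selection

A planted region (`planted_regions`) redraws the frequencies of a contiguous
SNP window in **one** population with a much larger drift parameter
`c_sel` (which must exceed every neutral drift). This mimics the local
excess differentiation left by a selective sweep without simulating the sweep
dynamics themselves. Genotypes are $\mathrm{Binomial}(2, p)$ per sample, with
i.i.d. missingness at `missing_rate` (default 0.02).

### What the simulator does *not* model

Sites are exchangeable: there is no linkage disequilibrium, no recombination
map, no mutation-rate variation, no genotyping-error model beyond missingness,
and no within-population structure. Consequences: (1) detected region
boundaries are sharper than in real data, where LD smears signals; (2) the
effective number of independent tests equals the SNP count, so Bonferroni is
exact rather than conservative; (3) planted-sweep recovery rates measured
here are optimistic upper bounds for real data.

## Genotype QC

`apply_qc()` runs five stages in a fixed order, each reported in a ledger:

1. **biallelic** — single REF and single ALT allele;
2. **autosomes** — chromosome in `autosomes` (default `"1"`–`"18"`, a pig
   genome; set for your organism);
3. **missing_rate** — removed when the per-SNP missing fraction is
   *strictly greater* than 0.10 (exactly 10% is kept);
4. **maf** — removed when minor allele frequency over *non-missing* alleles
   is below 0.10 (exactly 0.10 is kept);
5. **hwe** — Levene–Haldane exact test computed *within each population*;
   removed when $p < 0.01$ in any population.

Order matters: a SNP failing several criteria is charged to the first stage
that catches it, so the ledger columns sum exactly to the input count.
The HWE test is the conditional (on allele counts) exact distribution of the
heterozygote count, two-sided by summing all outcomes whose point probability
is at most that of the observed table times $1+10^{-7}$ — the standard
tolerance that stops floating-point noise from dropping ties. It is computed
in log space via `lgamma` and deduplicated over distinct genotype-count
triples, making genome-scale QC effectively $O(\text{distinct tables})$.

## Population structure

The IBS distance between samples is
$1 - \bigl(\text{IBS2} + \tfrac12\,\text{IBS1}\bigr)/N =
\operatorname{mean}\lvert d_i - d_j\rvert / 2$ over the $N$ sites where both
dosages are observed. `ibs_dist()` computes all pairs with three
`tcrossprod`s over genotype indicator matrices rather than a sample-pair
loop. Trees come from neighbor-joining (`ape::nj`), which is exact on
additive distances; ordination from classical MDS (`stats::cmdscale`).
Negative eigenvalues (IBS distances are not generally Euclidean) are
reported, and coordinates are returned as a tibble keyed by sample and
population for direct plotting.

## Pairwise $F_{ST}$: Weir & Cockerham (1984)

`wc_components()` computes the per-SNP variance components $a$ (between
populations), $b$ (between individuals within populations), and $c$
(within individuals) for two populations from sample sizes, allele
frequencies, and observed heterozygosities, using
$\bar n$, $n_c$, $\bar p$, $s^2$, $\bar h$ exactly as in the 1984 paper.
The genome-wide estimate is the ratio-of-sums
$\hat\theta = \sum_l a_l / \sum_l (a_l+b_l+c_l)$, not the mean of ratios —
the ratio-of-sums is the consistent combination. SNPs monomorphic in both
populations, with $\bar n \le 1$, or with non-finite components are excluded
and counted. Calibration at realistic sizes (25 and 17–23 samples, 50,000
SNPs) recovers the simulated drift to within $\pm 0.02$; under near-zero
drift the estimate stays below 0.03, confirming the small-sample bias
correction behaves.

## The differential-selection scan

For a population pair, each QC-passing SNP gets:

- **per-SNP $F_{ST}$** under the Nicholson model:
  $\bigl[((p_1-\bar p)^2 + (p_2-\bar p)^2)/2\bigr] / \bigl(\bar p(1-\bar p)\bigr)$
  with $\bar p = (p_1+p_2)/2$; undefined (NA) when $\bar p \in \{0, 1\}$;
- a **two-sided Fisher exact p** on the 2×2 table of REF/ALT allele counts,
  computed by `dhyper` point-probability enumeration with the same
  $1+10^{-7}$ tie tolerance (verified against `stats::fisher.test` and a
  `lchoose` enumeration oracle to $10^{-10}$), deduplicated over identical
  tables;
- **Bonferroni** correction by the number of tested SNPs.

### Two-tier classification

With $m$ SNPs having defined $F_{ST}$, the *extreme* threshold is the
$F_{ST}$ at sorted-descending rank $\lceil q_{\text{extreme}} \cdot m\rceil$
(default $q_{\text{extreme}} = 10^{-4}$, i.e. top 0.01%), and the
*significant* threshold uses $q_{\text{sig}} = 5\times10^{-3}$ (top 0.5%).
Ties at the threshold are included. Both labels additionally require
Bonferroni-corrected $p < \alpha = 0.05$; extreme SNPs are a subset of
significant ones. With fewer than $1/q_{\text{extreme}}$ SNPs the extreme
threshold degenerates toward the maximum and a warning is raised.

### Seed-and-extend region detection

Scanning each chromosome in position order, a region grows outward from an
*extreme* seed SNP until `break_len` (default 2) consecutive nonsignificant
SNPs are hit on that side; independently, any such maximal stretch containing
at least `min_run` (default 6) significant SNPs qualifies as a region even
without an extreme seed. Regions are trimmed to their outermost
significant/extreme SNPs, overlapping regions are merged, and merged regions
are re-counted and numbered `DSR1…` genome-wide.

Both rules reduce to the same object: maximal *blocks* of SNPs containing no
run of `break_len` consecutive nonsignificant labels. `detect_dsrs()`
exploits this for an $O(n)$ implementation via run-length encoding, while the
test suite checks it against a literal bidirectional-walk reference
implementation on hundreds of random label sequences — two independent routes
to the same definition.

`min_run = 6` encodes the convention that a qualifying seedless stretch needs
*more than five* significant SNPs; both it and `break_len` are `scan_config()`
parameters.

## Annotation

`read_gff_genes()` imports a GFF3 via `rtracklayer`, keeps `type == "gene"`
records, and requires unique IDs. `map_regions_to_genes()` intersects DSRs
with genes using `GenomicRanges::findOverlaps` with inclusive 1-based
coordinates, strand-blind, returning both a per-region table (regions without
hits keep an NA row) and the deduplicated gene list.

## Problem sizes and determinism

Defaults target panels of roughly 20,000–50,000 SNPs and 20–70 samples —
large enough for the quantile thresholds to be meaningful, small enough for
the full pipeline to run in seconds. All simulation randomness derives from a
single integer seed expanded into per-chromosome sub-seeds below $2^{31}$;
identical configurations produce byte-identical fixture files.

## Limitations

- Thresholds are *empirical quantiles*: the scan always labels the top tail,
  so region counts on pure-drift data are small but not zero; interpretation
  requires the Bonferroni gate and the region structure, not the labels alone.
- The Fisher test treats the two alleles per individual as independent,
  which overstates evidence under strong inbreeding.
- Weir–Cockerham $\hat\theta$ is for two populations; multi-population
  estimates are composed pairwise.
- No LD model: see the simulator caveats above before transferring measured
  detection rates to real data.
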