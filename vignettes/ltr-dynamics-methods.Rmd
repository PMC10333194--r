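---
title: "Methods: dating LTR insertions and their genomic consequences"
author: "ltrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating LTR insertions and their genomic consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrdyn)
```

## The model

An intact LTR retrotransposon carries two terminal repeats that are
identical at the moment of insertion and afterwards accumulate neutral
substitutions independently. Writing $d$ for the observed proportion of
differing sites between the aligned repeat pair, the Jukes–Cantor (JC69)
model for non-coding sequence gives the substitutions-per-site distance

$$K = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4d}{3}\right),$$

and, because both repeats evolve, the insertion age is

$$T = \frac{K}{2\mu},$$

with $\mu$ the neutral substitution rate per site per year. $\mu$ is
calibrated from synonymous divergence: if orthologs of two species with a
known split time $T_0$ show a mean synonymous rate $K_s$, then
$\mu = K_s / (2 T_0)$. `calibrate_mu(0.75, 62e6)` gives
$\mu \approx 6.0\times10^{-9}$; the same arithmetic applied to a paralog
$K_s$ peak dates a polyploidy event (`clock_age_from_ks()`). Full
precision is reported throughout — e.g. a $K_s = 0.73$ peak under a
$(0.48,\,45\,\mathrm{My})$ clock dates to 68.4375 Mya — and rounding is
left to the caller.

Assumptions worth keeping in mind: the repeats are pre-aligned and
equal-length (the upstream annotation convention; no aligner is embedded,
and indels are not modelled), substitution rates are homogeneous across
sites (JC69), and ambiguity symbols are excluded pairwise from $d$ rather
than counted as mismatches.

## NG86 Ka/Ks

`ng86()` implements the Nei–Gojobori (1986) counting method. For each
codon, each position's synonymous-site fraction is the share of its three
possible single-nucleotide changes that preserve the amino acid; changes
that create a stop codon are counted as nonsynonymous. Site counts are
averaged over the two sequences, so $S + N$ always equals the nucleotide
length. Codon pairs differing at $n_d$ positions are resolved by averaging
synonymous/nonsynonymous step counts over all $n_d!$ minimal substitution
paths with equal weights, excluding paths that pass through a stop codon
(when every path does — a rare corner — all are kept, stop-involving steps
counted nonsynonymous). $p_s = S_d/S$ and $p_n = N_d/N$ are then JC69
corrected. Proportions at or above $3/4$ have no finite correction and are
flagged saturated. The whole table is exercised against an independent
brute-force enumeration oracle in the test suite; that equivalence, not
any single worked value, is the correctness surface.

## Ks mixtures

`fit_ks_mixture()` fits univariate Gaussian mixtures by EM (unequal
variances) for each candidate component count and scores each fit by the
coefficient of determination between the mixture density and a histogram
density estimate with Freedman–Diaconis bin width. The smallest $k$
exceeding $R^2 = 0.95$ is selected; if none qualifies the best-$R^2$ fit
is returned with a warning, and BIC is always reported as a secondary
diagnostic. The histogram target and the bin rule are a pragmatic choice —
a density target must be fixed for $R^2$ to be well defined — and both are
configurable. Values exceeding the saturation bound (default 5) are
removed first by `filter_saturated()`; the bound itself is kept ("exceeding"
is strict). The dominant peak is reported as the mean of the
heaviest component; the histogram mode is available from
`age_histogram()`-style summaries when a mode-based reading is preferred.

## Gene proximity and enrichment

`classify_insertions()` labels each element genic (≥ 1 bp overlap with a
gene body), 5′-upstream or 3′-downstream within a 5-kb window, with
upstream/downstream decided by the gene's strand. When several genes
qualify, the category priority genic > upstream > downstream applies
first, then the nearest gene, then the lexicographically smallest gene id
— only the category priority is inherited from the analysis convention;
the remaining tie-breaks had to be fixed here and are documented so the
brute-force oracle can reproduce them exactly. Gene-body overlap, not the
element midpoint, defines genic. Because the anchor chosen by priority is
not necessarily the nearest gene, records also carry a strand-agnostic
`nearest_distance_bp`, and the flank statistic — the fraction of elements
whose nearest-gene distance falls in $(0, 1\,\mathrm{kb}]$ — is computed
from it.

Enrichment of insertions in the close flanks is tested by permutation:
each element is re-placed uniformly at random on the non-genic portion of
its chromosome, preserving its length, and the one-sided p-value is
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$. This add-one estimator
never returns 0 and is conservative under ties. Solo-LTR placement serves
as the empirical randomness control in real data.

## Expression divergence of recent paralogs

Pairs with $K_s < 0.5$ (strict) count as recent duplicates. Profiles are
$\log_2(\mathrm{RPKM} + 1)$ — the pseudocount of 1 keeps zero RPKM at zero
and the transformed profile non-negative, which the tau index requires;
it is configurable. Expression divergence is the Euclidean distance
between the two genes' transformed profiles over the five default tissues
(leaf, bract, stem, fruit, root — the file header is authoritative).
Tissue specificity is $\tau = \sum_i (1 - x_i/x_{\max})/(n-1)$, computed on
the same transformed profiles for internal consistency (a raw-scale
option exists); $\tau$ divergence is the absolute difference, with the
signed difference kept as a column. An all-zero profile has no defined
$\tau$ and yields `NA` with a warning. Groups (LTR-adjacent vs not, where
adjacency means an element within the 1-kb upstream flank of either gene
by default) are compared by a two-sided Wilcoxon rank-sum test, exact when
the smaller group has ≤ 20 observations and otherwise the tie-corrected
normal approximation.

## What the generator emulates — and what it does not

`simulate_genome()` builds one linear chromosome with non-overlapping
genes (lengths uniform in a configurable range; placement distributes the
free space uniformly, so it either succeeds or fails immediately with a
clear message). Each intact element receives an age drawn from a
truncated Gaussian mixture in Mya — the default is a single burst at
$1.5 \pm 0.5$ Mya, the regime of a recent proliferation episode — and its
two repeats are produced from one random ancestral repeat by a direct
JC69 sampler: each copy substitutes each site with probability
$\tfrac{3}{4}(1 - e^{-4\mu T/3})$, the JC69 transition probability at
branch length $\mu T$, with the target base uniform over the three
alternatives. JC69 transition matrices compose, so the expected pair
divergence is exactly the JC69 value at $K = 2\mu T$ — the quantity the
dating module inverts.

Elements are placed uniformly on the *non-genic* space (a configurable
fraction forced into the <1 kb flanks instead). This matches the
permutation test's null exactly, which is what makes the null-calibration
checks meaningful; it also encodes the biological prior that insertions
disrupting coding sequence are purged. Consequently the generator never
plants genic insertions — classification of genic elements is exercised
with hand-built fixtures instead. For short elements the forced-flank
placement also keeps the element midpoint within the flank; elements
longer than ~2 kb satisfy the edge-distance definition only.

CDS pairs (`simulate_cds_pairs()`) plant `round(ps * S)` single-nucleotide
synonymous substitutions at distinct codons, with
$p_s = \tfrac{3}{4}(1 - e^{-4K_s/3})$, so each planted change contributes
exactly one synonymous difference; targets at or beyond the saturation
bound are rejected. Expression profiles share a log-normal per-tissue
base (meanlog 3, sdlog 1 on the RPKM scale — no empirical distribution is
imposed by the analysis, so this is a documented, configurable choice)
plus independent per-gene log2-scale noise (sd 0.5); flagged pairs receive
additional divergence noise with the chosen effect size. Identical spec
and seed reproduce every output byte-for-byte.

Not emulated: TE nesting, indels and rate heterogeneity within repeats,
GC bias, multiple chromosomes, genic insertions, and correlated
tissue effects. Passing tests therefore demonstrate correctness of the
estimators and calibration of the tests under this idealized regime, not
robustness to alignment error or rate variation in real genomes.

## Problem sizes and numerical choices

The validation suites run at sizes chosen to make their statistical
assertions sharp: 1,000 elements with 5–7 kb repeats for age recovery
(at the JC69 binomial noise floor, ~600 bp repeats would leave ~20% mean
relative error for 0.5–3 Mya ages, so long repeats are the regime in
which a <10% recovery claim is testable); 2,000–4,000 draws for mixture
recovery; 1,000 replicates for type-I calibration of both tests at
nominal 0.05; 100 replicates for power at a planted effect of 2 log2
units across 200 pairs. Permutation p-values use the add-one estimator;
ages are held in years internally and reported in Mya to avoid unit
drift; histogram bins are left-closed right-open from zero.

## Known limitations

Dating inherits every JC69 assumption; ages of very young elements are
dominated by counting noise and ages beyond $d \approx 0.7$ are
uncorrectable. The $R^2$-based mixture selection follows the stated
acceptance criterion rather than a likelihood penalty and can prefer
fewer components than BIC would. The enrichment null re-places elements
independently, ignoring insertion clustering. Upstream/downstream calls
assume complete, correctly stranded gene models.
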