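---
title: "Methods and design of popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of popgenscan}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popgenscan compares two small diploid cohorts genome-wide: it filters a
multi-sample VCF, computes windowed diversity and differentiation
statistics, flags selective-sweep windows and differentiated copy-number
regions by empirical-quantile outlier criteria, and tests candidate gene
sets for term over-representation. This vignette documents the statistical
models, the defaults and why they are what they are, the synthetic-data
generator that the test suite exercises the pipeline against, and the
design decisions taken where more than one defensible reading existed.

## Statistical models

### Diversity statistics

All SNP statistics operate on a matrix of diploid alternate-allele dosages
(0/1/2, `NA` missing). At a site with $n$ called alleles and alternate
frequency $\hat p$:

* **Nucleotide diversity** $\theta_\pi$ sums
  $2\hat p(1-\hat p)\,n/(n-1)$ over sites and divides by the window length
  $L$. The $n/(n-1)$ factor makes the estimator unbiased; computing from
  allele frequencies rather than explicit haplotype pairs is exact for
  unphased data (phase never enters $\pi$) and is what the brute-force
  pairwise-difference oracle in the tests verifies.
* **Watterson's estimator** $\theta_w = S/(a_1 L)$ with
  $a_1=\sum_{i=1}^{n-1}1/i$ and $S$ the segregating-site count.
* **Tajima's D** uses the standard 1989 constants derived from $n$. With
  missing data the allele count varies across sites; the window's modal
  allele count is used for the constants while every site still contributes
  to $S$ and $\pi$. `D` is `NA` when $S=0$.
* The window length $L$ in the denominators is the full (reference-aligned)
  window span, so per-site values are comparable with genome-wide diversity
  tables reported on the $10^{-3}$ scale; invariant sites are assumed
  monomorphic.

### Differentiation

F~ST~ uses the Weir–Cockerham (1984) two-population variance components
$a$ (between populations), $b$ (between individuals within populations) and
$c$ (within individuals), estimated per site from genotype counts including
the heterozygosity term, and combined across a window as a **ratio of
sums** $\sum a / \sum(a+b+c)$. Ratio-of-sums is the standard choice for
small samples because averaging per-site ratios is badly behaved when
per-site denominators are small. Negative estimates are retained (they
carry information about sampling noise); a fixed difference gives exactly
1. Weir–Cockerham was chosen because it is the standard estimator for small
two-cohort genotype panels; Hudson's estimator (`fst_hudson()`) is provided
for sensitivity analysis.

The **log2 diversity ratio** $\log_2((\pi_A+\varepsilon)/(\pi_B+\varepsilon))$
uses a pseudocount $\varepsilon = 10^{-8}$ per site — small enough that no
realistic window ordering changes, large enough to keep windows swept to
zero diversity finite.

### Sweep selection

Windows are tiled from position 0 with a fixed step (presets: 40 kb/20 kb
for the joint F~ST~–diversity scan, 100 kb/20 kb for the π-ratio scan). A
truncated tail window is kept only if strictly longer than half the window
size, which avoids high-variance fragments while preserving coverage.

A window is selected for the focal population when all of these hold:

1. F~ST~ at or above the empirical upper 5% threshold;
2. focal-population $\theta_\pi$ at or below the lower 10% threshold of its
   own genome-wide distribution (the reduction-of-diversity reading; a
   cross-population variant that thresholds against the other population's
   distribution is available via `sweep_criteria(cross_population = TRUE)`);
3. focal-population Tajima's D negative (optional, on by default).

Thresholds are **nearest-rank quantiles** — always attained data values,
with no interpolation — so "top 5%" means literally the smallest set of at
least 5% of windows. Selection is purely threshold-based; no parametric
significance is attached to individual windows, because the empirical-tail
definition already fixes the selected fraction. Selected windows that
overlap or abut are merged, and any gene whose span intersects the merged
region extended by a 20 kb flank (half-open interval arithmetic) becomes a
candidate.

### Copy-number differentiation

For a region with copy numbers $x$ and total variance $V_T$,
$V_{ST} = (V_T - V_S)/V_T$, where $V_S$ is the sample-size-weighted mean of
the two within-population variances. All variances use denominator $n$
(population variances), so two internally constant but different
populations give exactly $V_{ST}=1$; size weighting is used because the two
cohorts differ in size (5 vs 3 by default). Numerically negative values
(floating point) are clamped to zero and $V_T=0$ yields `NA`. The top-5%
outlier threshold is recomputed from each dataset; no constant from any
particular dataset is hard-coded.

### Linkage disequilibrium

Samples with more than 50% missing genotypes are dropped first, then sites
failing MAF ≥ 0.05, genotyping rate ≥ 0.6, or the exact Hardy–Weinberg test
at p < 0.001 are removed — mirroring the Haploview-style defaults
(`maxDistance` 1000 kb, `minMAF` 0.05, `hwcutoff` 0.001, `missingCutoff`
0.5, `minGeno` 0.6). LD is the **composite r²**: the squared Pearson
correlation of dosages over jointly called samples. With unphased data from
a handful of individuals, EM haplotype phasing would add model assumptions
the sample size cannot support; composite r² is the standard phase-free
measure, and the tests verify it coincides with haplotype-count r² whenever
genotypes are homozygous. D′ is not computed. The decay curve is the mean
r² in 1 kb distance bins; the half-decay distance is the smallest bin
midpoint where the mean r² drops to half the curve maximum ("half of its
maximum value"), which is one defensible reading of LD-decay distance among
several in use.

The HWE test is the exact conditional test: given the allele counts, the
p-value sums the probabilities of all heterozygote configurations no more
probable than the observed one, computed in log space (a `1 + 10^{-12}`
relative tolerance guards the tie comparison against floating-point
noise).

### Divergence

The identity-by-state distance between two samples is the mean of
$|g_i - g_j|/2$ over jointly called sites. Neighbor joining is implemented
in-package with the Studier–Keppler $Q$ criterion so that two contracts the
standard library implementations do not make can hold: ties in $Q$ are
broken by the lexicographically smallest pair of node labels (internal
nodes inherit the smallest leaf label beneath them), making output
deterministic; and negative branch lengths are clamped to zero with the
deficit moved to the sister branch. On additive distances the generating
topology and branch lengths are recovered exactly; the test suite checks
agreement with the reference `ape::nj()` implementation on random
matrices. Rooting is midpoint (via phangorn) on request — the analyses this
package supports name no outgroup. PCA column-centers dosages over sites
with nonzero variance, mean-imputes missing entries, and optionally applies
Patterson scaling $1/\sqrt{\hat p(1-\hat p)}$.

### Enrichment

One upper-tail hypergeometric test per term: with a universe of $N$ genes,
$K$ annotated, and $n$ candidates of which $x$ are annotated, the p-value
is $P(X \ge x)$ accumulated from log-scale masses. The background universe
defaults to all annotated genes, mirroring enrichment "against the whole
reference genome". Both Benjamini–Hochberg (default) and Bonferroni
corrections ship, because both conventions are common in this literature
and published analyses are not always internally consistent about which
produced a reported significance; BH is the default as the less
conservative and more standard choice for exploratory term screens.

## Variant filters

All thresholds are strict inequalities exactly as conventionally printed:
QUAL > 20, per-sample supporting reads > 4, total depth < 100, MAF > 0.05.
Boundary records (QUAL = 20, MAF = 0.05) are rejected, and the bundled
12-record fixture (`inst/extdata/filter12.vcf`, expectations in
`filter12.expected.tsv`) pins this behaviour. The ≥ 5 bp spacing rule runs
after the per-record rules, scanning left to right and keeping the earlier
record of a conflict (the convention is arbitrary; left-to-right is
deterministic and order-independent given sorted input). Each rejected
record is attributed to the first rule it fails, so rejection counts plus
survivors always equal the input count.

Three further rules — flanking copy number < 1.5, a two-sided cohort
sequencing-depth band, and a rank-sum-test p > 0.05 — belong to the
upstream calling stage and cannot be computed from variant-level input.
They are exposed as optional filters reading pre-computed columns
(`cn`, `cohort_dp`, `ranksum_p`) and are skipped with a warning when the
columns are absent. The depth band and the per-record depth cap are kept as
independent rules because they plausibly refer to different quantities
(cohort-total vs per-record depth) and only one of them can be active in
any given dataset.

Multi-allelic sites are excluded from genotype matrices by default: every
downstream formula assumes two alleles.

## Effect annotation

Region assignment is a partition: each variant receives exactly one of
intergenic / UTR5 / UTR3 / CDS / splice / intronic. Precedence inside a
transcript: CDS over UTR, splice (the first or last two intron bases) over
plain intron. A variant overlapping several genes is classified against the
first by (gene start, gene id) and the multiplicity is recorded. Coding
effects rebuild the affected codon from the reference honoring strand and
frame and translate under the standard genetic code only — the analyses in
scope concern nuclear gene models. In-frame InDels are those with length
divisible by three inside a CDS; InDel length summaries bin 1–200 bp.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the package targets:

* two cohorts of **5 and 3 diploids** (the design it emulates),
* **200 windows of 40 kb** with 25 SNP sites each (5000 sites — large
  enough for stable empirical quantiles, small enough that the full
  pipeline runs in seconds),
* background differentiation **F = 0.1** under the Balding–Nichols model:
  ancestral frequency $p \sim U(0.05, 0.95)$, population frequencies
  $\sim \mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$, genotypes binomial — chosen
  over forward simulation because the closed-form link between $F$ and
  expected F~ST~ gives an analytic calibration target,
* **10 planted sweep windows** with an **8-fold** reduction of
  focal-population heterozygosity. Sweeps are planted by frequency
  manipulation, not selection dynamics: the scan only sees summary
  statistics, so matching the signature (low π, elevated F~ST~, negative
  Tajima's D) suffices. The focal-population frequency is pushed to within
  a calibrated $\varepsilon$ of fixation; **which** allele fixes is drawn
  with probability equal to its ancestral frequency, the way a hitchhiking
  haplotype samples one allele from the population — pushing toward the
  locally common allele instead would barely move F~ST~ and would not
  reproduce a sweep's differentiation signature. A few extra focal
  singletons per sweep window supply the excess of rare variants (and
  guarantee $S>0$ so Tajima's D is defined and negative).
* planted windows and differentiated CNV regions are placed **evenly
  spaced**, so the ground truth is a function of the plan alone and the
  VCF, CNV and annotation generators agree without sharing RNG state,
* CNV plan: 1000 regions, null copy number $\mathcal N(2, 0.2)$, 50
  regions with a between-population mean shift of 2 (variance arithmetic
  puts their expected V~ST~ near 0.96, well above the null tail),
* annotation plan: genes of 3 kb tiled with 1 kb gaps, 40 terms at a 5%
  baseline annotation rate, one term over-represented 5-fold among genes in
  planted sweep windows,
* QUAL, INFO depth and per-sample depths are drawn so that 2% of records
  fail each filter rule, exercising the filter stage end to end.

What the generator deliberately does **not** emulate: linkage
disequilibrium between background sites (sites are exchangeable given their
frequencies), recombination within windows, mutation-rate heterogeneity,
genotyping error correlated with depth, and reference bias. Passing tests
therefore demonstrate estimator correctness and pipeline recovery under the
assumed sampling models — not robustness to those real-data artefacts. The
separate LD generator (`simulate_ld_genotypes()`) uses a two-state Markov
chain along equally spaced sites, giving a geometric r² decay with a known
half-decay distance for calibrating the LD module.

The neutral-coalescent window simulator draws exponential coalescence times
with rate $\binom k2$ and Poisson mutations at rate $\theta/2$ per unit
branch length under infinite sites; it is the calibration oracle for
$\theta_\pi$, $\theta_w$ (both unbiased for $\theta/L$) and Tajima's D
(mean within ±0.1 of zero at 2000 replicates of $n=10$, $\theta=5$).

## Problem sizes and determinism

The test suite and the acceptance script run at: 2000 coalescent replicates
for estimator calibration; 5000 sites × 25 diploids per population for
F~ST~ recovery; the default 200-window study for sweep recovery; 1000 CNV
regions for V~ST~ recovery; 100 random additive 6-taxon trees for
neighbor joining; ~2100 exhaustive configurations (n ≤ 20) for the HWE
oracle and 1000 random instances each for the π, V~ST~ and hypergeometric
oracles. These sizes keep every estimator's sampling noise well inside the
asserted tolerances while the whole suite runs in about a minute on one
CPU. All randomness is seeded; identical seed and configuration produce
byte-identical output files, which the tests verify by checksum.

## Known limitations

* Tajima's D with heavy, unevenly distributed missingness relies on the
  modal allele count; windows mixing very different call rates are handled
  but the constants are approximate there.
* The spacing filter's "earlier record wins" rule is greedy; a different
  tie-break could retain a different (equally valid) SNP subset.
* Composite r² differs from EM-phased haplotype r² when genotypes are
  heterozygous at both sites; with the target sample sizes the phased
  quantity is not reliably estimable, which is why it is out of scope.
* The enrichment engine treats terms as flat sets; pathway topology is out
  of scope.
* Negative-branch clamping in neighbor joining redistributes length to the
  sister branch; path lengths are preserved only approximately when
  clamping fires (it cannot fire on additive input).
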