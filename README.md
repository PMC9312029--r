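# popgenscan

Comparative population-genomic scans for **two small diploid cohorts** — the
kind of design used when a handful of resequenced individuals from each of
two populations or subspecies (e.g. two tiger subspecies, 5 + 3 animals) must
be compared genome-wide. From a multi-sample VCF and a sample-to-population
map, the package provides the full desk-side analysis chain:

- **Variant filtering** with strict quality rules (QUAL > 20, per-sample
  supporting reads > 4, total depth < 100, MAF > 0.05, ≥ 5 bp inter-SNP
  spacing) and per-rule rejection accounting.
- **Effect annotation**: intergenic / UTR / CDS / splice / intron region
  calls against GFF3 gene models, synonymous / nonsynonymous / stop-gain /
  stop-loss classification under the standard genetic code, and summary
  tables (nonsyn/syn ratio, InDel length spectra).
- **Windowed diversity and differentiation**: θ&pi; (nucleotide diversity),
  Watterson's θ<sub>w</sub> = S/(a₁L), Tajima's D, Weir–Cockerham
  F<sub>ST</sub> (ratio of sums of the a, b, c variance components) and the
  log₂ θ&pi;-ratio, over sliding windows (40 kb/20 kb and 100 kb/20 kb
  presets).
- **Selective-sweep selection**: joint empirical-quantile criteria
  (F<sub>ST</sub> in the top 5%, focal-population θ&pi; in the bottom 10%,
  Tajima's D < 0), merging of selected windows into regions, and candidate
  genes within a 20 kb flank.
- **V<sub>ST</sub> scans** of copy-number matrices:
  V<sub>ST</sub> = (V<sub>T</sub> − V<sub>S</sub>)/V<sub>T</sub> with
  population-size-weighted within-population variances, top-5% outlier
  extraction and gene overlap.
- **LD decay**: Haploview-style site filters (MAF, missingness, exact HWE
  test, genotyping rate), composite genotype r², binned decay curves and the
  half-of-maximum decay distance.
- **Divergence**: identity-by-state distances, a deterministic
  neighbor-joining implementation with Newick output, and genotype PCA.
- **Term enrichment**: upper-tail hypergeometric tests with
  Benjamini–Hochberg (default) or Bonferroni correction.
- A **synthetic-data generator** (Balding–Nichols two-population model with
  planted sweep windows, differentiated copy-number regions, toy gene/term
  annotations, and a neutral-coalescent window simulator) that emits the
  same file formats the pipeline consumes, with exported ground truth.

## Worked example

Simulate the default study (two cohorts of 5 + 3 diploids, 200 windows of
40 kb, 10 planted sweeps with an 8-fold diversity reduction in the focal
population), then run the full chain — filter, scan, select, merge, enrich:

```r
library(popgenscan)

cfg <- sim_config(seed = 1)
res <- run_sweep_pipeline(cfg, dir = tempdir())

sel <- res$selected
cat("Fst threshold (top 5%):", round(attr(sel, "fst_threshold"), 3), "\n")
cat("windows selected:", sum(sel$selected), "\n")
cat("planted sweeps recovered:",
    sum(res$truth$sweep_windows$index %in% which(sel$selected)), "of 10\n")
cat("candidate genes:", length(res$candidates), "\n")
head(res$enrichment[, c("term", "x", "K", "n", "N", "p", "q")], 3)
```

```
Fst threshold (top 5%): 0.244
windows selected: 9
planted sweeps recovered: 9 of 10
candidate genes: 180
    term  x   K   n    N            p            q
1 term01 31 107 180 2000 6.869419e-10 2.747768e-08
2 term40 16 105 180 2000 2.246514e-02 4.493029e-01
3 term16 13 100 180 2000 1.081803e-01 9.892573e-01
```

The empirical top-5% F<sub>ST</sub> threshold (0.244 here) is recomputed
from the data, never hard-coded. Nine of the ten planted sweep windows pass
the joint criterion, their merged regions contribute 180 candidate genes,
and the term planted as over-represented among sweep genes (`term01`) ranks
first with a Benjamini–Hochberg adjusted p of 2.7 × 10⁻⁸; all other terms
are non-significant.

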