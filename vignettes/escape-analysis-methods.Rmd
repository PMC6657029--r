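---
title: "Methods: B2M/HLA escape-mutation cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: B2M/HLA escape-mutation cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoescape)
library(dplyr)
```

## The scientific question

MHC class I molecules present intracellular peptides — including
tumor-specific neoantigens — to CD8+ T cells. Every class I molecule is a
heterodimer of one polymorphic HLA heavy chain (HLA-A, -B or -C; up to six
distinct alleles per patient) and the invariant scaffold beta-2-microglobulin
(B2M). A somatic mutation in B2M cripples presentation globally; a mutation
in one HLA allele removes the peptide repertoire unique to that allele. Both
are candidate mechanisms of immune escape, and both should leave statistical
fingerprints in a tumor cohort:

1. escape-mutant tumors tolerate a higher burden of expressed,
   immunogenic mutations;
2. escape mutations co-occur with hypermutator states (microsatellite
   instability);
3. in HLA-mutant tumors, surviving neoantigens are biased toward binding
   the *disabled* allele;
4. B2M mutations tend to be clonal (high variant-allele-fraction
   percentile), HLA mutations bimodally clonal or subclonal.

`neoescape` implements the statistics for all four fingerprints, plus the
residue-level structural annotation used to interpret where escape mutations
fall on the B2M-HLA complex.

## Models and procedures

### PHBR presentation score

For one mutation, each allele slot `i` contributes its best (minimum)
peptide-level binding percentile rank `r_i`; the patient-level score is the
harmonic mean `PHBR = 6 / sum(1/r_i)`. The harmonic mean is deliberate: it is
dominated by the smallest rank, encoding that a single well-presenting allele
suffices for surveillance. Homozygous patients contribute duplicate slots —
the score is always over six values. `PHBR <= 2` (inclusive) calls a binding
neoantigen; the cutoff is a parameter everywhere it is used.

Allele-*specific* analyses (the mutant-allele bias and its early/late
stratification) use per-slot best ranks at the same cutoff, not the PHBR: the
question "does this neoantigen bind the mutated allele?" is intrinsically
allele-level. The mean over the five intact slots is unweighted, and
duplicate slots remain distinct identities.

### Test statistics

Group contrasts are two-sided Mann-Whitney tests; matched mutant-vs-intact
allele counts use the paired Wilcoxon signed-rank test with zero differences
dropped. Because the paired counts are small integers, tied absolute
differences are the norm, and R's `wilcox.test` abandons the exact null under
ties; `bias_test()` therefore computes the exact sign-flip null itself by
generating-function convolution over doubled mid-ranks (exact up to n = 25
nonzero pairs, normal approximation beyond). Distribution shapes (B2M vs HLA
VAF percentiles) are compared with the two-sample Kolmogorov-Smirnov test;
2x2 associations (escape status x MSI) use Fisher's exact test, reported with
the sample cross-product odds ratio `(ad)/(bc)` rather than the conditional
MLE, with zero-cell tables flagged unbounded rather than silently truncated.
Families of stratified tests (per-tumor-type burden, per-tumor-type immune
contrasts) are Benjamini-Hochberg adjusted within the family; pan-cancer
single tests are reported raw.

### Filters and thresholds

| Quantity | Rule | Boundary |
|---|---|---|
| expressed mutation | RNA reads >= 5 | inclusive |
| nonsynonymous | missense, nonsense, frameshift/in-frame indel, splice | enumerated |
| burden | # expressed nonsynonymous + 1 | pseudocount |
| binding | PHBR <= 2 | inclusive |
| MSI-H | MANTIS >= 0.4 | boundary to MSI-H |
| CNV region | log2FC > 0.1 or < -0.1 | strict |
| early / late | percentile > 60 / < 40 | strict, band excluded |
| core / surface | RSA < 5 / > 15 | strict, band ambiguous |

The variant-classification list makes "coding non-silent" explicit (splice
sites included); the MANTIS boundary is assigned to MSI-H on the reasoning
that the recommended threshold marks the instability call itself. Both are
config-exposed, as are the timing and RSA cutoffs.

The within-tumor VAF percentile uses the mid-rank convention over the other
`n - 1` expressed mutations of the same tumor:
`100 * (c_below + 0.5 * c_tied) / (n - 1)`. This makes unique extremes score
exactly 0 and 100, splits ties symmetrically, and is invariant under any
strictly monotone transform of the AF. Patients with a single expressed
mutation have no defined percentile and are excluded. Mutations in
copy-number-variant regions confound AF as a clonality proxy; the default
analysis retains them and a robustness variant (`exclude_cnv = TRUE`) drops
them before ranking.

### Structural consensus

Per structure, interface predictions override the RSA class; consensus across
structures *and* alleles is a single pooled plurality vote per position, with
ties and structurally unobserved positions resolved to ambiguous. Pooling is
used rather than nested two-stage voting because it is order-independent and
reproduces both behaviours one wants from a consensus: a minority interface
call (2 of 6 structures) yields to a surface majority, while genuinely split
evidence stays ambiguous. IMGT numbering is UniProt minus the 24-residue
signal peptide. Domain enrichment uses residue counts as the exposure column
of the 2x2 table, so the odds ratio asks "are mutations concentrated beyond
the domain's share of the protein?".

## The synthetic cohort generator

The generator (`simulate_cohort()`) emulates the *statistical* structure the
analyses assume — it is the package's test bed, not a tumor-evolution
simulator. Per patient it draws: group membership by deterministic rounding
of the configured fractions; MSI status with per-group probabilities solved
(numerically) so the population escape-x-MSI odds ratio equals the target
while the marginal MSI fraction is preserved; an expressed nonsynonymous
burden from a negative binomial whose mean is multiplied per group and MSI
status; passenger VAFs uniform, escape VAFs Beta(8, 2) for B2M and a 50/50
Beta(8, 2) / Beta(2, 8) mixture for HLA (the bimodal clonal/subclonal
pattern); read counts binomial over Poisson(80) depths; and a rank table with
one best rank per (mutation, slot).

Key defaults and why:

* `n_patients = 500`, `frac_b2m_mut = 0.10`, `frac_hla_mut = 0.20`,
  `frac_both = 0.01`. Escape fractions are enriched ~5-10x over pan-cancer
  population rates so that group contrasts have usable sample sizes at
  simulation scale; the analyses themselves are invariant to the enrichment.
* `baseline_burden_mean = 50`, `burden_dispersion = 2` — an overdispersed
  count distribution of the magnitude seen in exome cohorts; dispersion is a
  parameter because only location contrasts are analyzed.
* `burden_multiplier_b2m = 2`, `hla = 1.5`, `msi = 4`; patients with both
  mutations use the B2M multiplier (the dominant effect). Multipliers
  compound with MSI multiplicatively; burden and MSI are otherwise
  conditionally independent given group — a modeling choice, since their
  joint distribution beyond enrichment is not characterized.
* `msi_enrichment_or = 15`, `frac_msi = 0.15`.
* **Rank distribution: uniform on (0.01, 100]** per slot. A binding
  percentile rank is, by construction, uniform for a random peptide; under
  this default roughly 2-4% of mutations score PHBR <= 2, so binding-fraction
  curves rise through the interesting cutoff range instead of saturating. A
  log-uniform alternative is selectable, but as a *default* it would put more
  than half of all per-slot ranks below 2 and call nearly every mutation
  binding, which defeats the curve and bias analyses.
* `bias_strength = 0.15`: each rank at an HLA-mutant patient's mutated slot
  is replaced, with this probability, by a strong-binder draw on (0, 2] —
  enough signal that the paired Wilcoxon detects it reliably at ~100 carriers
  while leaving the other slots untouched.
* `expressed_prob = 0.8`, `cnv_fraction = 0.1`, `homozygous_prob = 0.15`
  per gene pair — unremarkable mid-range values.

The generator does **not** simulate sequences, peptides, subclone trees,
purity/ploidy, or any coupling between mutation timing and allele bias; it
draws summary quantities directly. Passing tests therefore demonstrate that
the statistics recover the structure they target under the stated models —
not that real MAF/netMHCpan-style inputs are free of upstream artifacts
(caller bias in AF, prediction error in ranks, deconvolution noise), which
the pipeline consumes as given.

## Calibration and recovery checks

The test suite runs the pipeline as a measurement instrument over many seeds
(problem sizes chosen to exercise the asymptotics while keeping the suite
quick): parameter recovery on 50 cohorts of n = 2000 (burden ratio for a 2x
multiplier recovered in [1.7, 2.3]; an odds-ratio-15 MSI enrichment within a
factor of 2; the allele bias detected in >= 90% of seeds; B2M percentile
medians above HLA in >= 90%), and null calibration on 200 cohorts of n = 600
with every effect switched off, where each contrast's rejection rate at
alpha = 0.05 must stay within [0.02, 0.09]. The exact tests (Mann-Whitney,
signed-rank, Fisher) are verified against full-enumeration oracles at small
n, and PHBR against the direct reciprocal-sum formula to 1e-12.

## Numerical and degenerate-input conventions

* Harmonic means and percentiles are plain double arithmetic; no special
  tolerance is needed anywhere (tests use 1e-12).
* Empty denominators (a patient with no expressed missense/indel mutation)
  yield `NA` fractions and exclusion from group medians, not zeros.
* All-zero paired differences give a degenerate-flagged p = 1 rather than an
  error; degenerate 2x2 margins likewise.
* Readers reject invalid records outright (alt > depth, rank <= 0, missing
  genotype slots, start > end) with classed conditions; nothing invalid
  reaches an analysis function.
* Seeding: a `cohort_config(seed = )` makes generation — and the files
  `write_cohort()` emits — byte-reproducible; analysis functions are
  deterministic given their inputs.

## Known limitations

* VAF percentile is a crude clonality proxy; no cancer-cell-fraction or
  subclone reconstruction is attempted.
* MHC class II (and affinity-nM scoring generally) is out of scope; ranks
  are consumed, never predicted.
* The immune layer carries cytolytic scores and consumed deconvolution
  outputs through the contrast machinery only; the generator gives them no
  group effect, so only their calibration, not power, is exercised.
* Structural annotation consumes precomputed RSA/interface tables; computing
  RSA from coordinates or predicting interfaces is upstream of this package.
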