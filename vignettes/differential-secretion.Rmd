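---
title: "Differential secretion analysis of label-free secretome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential secretion analysis of label-free secretome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomics)
```

## The analysis problem

Secretome experiments quantify the proteins a tissue releases into its
conditioned medium, here measured by data-dependent-acquisition LC-MS/MS
with MaxQuant label-free quantification (LFQ). Two features dominate the
statistics of such data. First, an LFQ value of 0 does not mean "absent" but
"not detected": missingness is strongly intensity-dependent
(missing-not-at-random, left-censoring at the detection limit). Second, the
data arrive in discrete batches (here: first-trimester and term placental
explants measured separately) whose global intensity levels are not
comparable without normalization.

`secretome_da()` implements the full cascade from a raw `proteinGroups.txt`
table to called hits:

1. **QC filtering.** Rows flagged as potential contaminants, reverse-decoy
   matches, or identified only by modification sites are removed. A
   multiply-flagged row is counted once in the filter report, with priority
   contaminant > reverse > site-only (the priority only affects accounting,
   not the set of retained proteins).
2. **Sample exclusions.** Samples listed in the exclusion table (e.g.
   untreated replicates with >95% unmeasured entries) are dropped *before*
   any filtering, so they never influence presence fractions or medians.
3. **Presence filter.** A protein is kept if it was measured in at least
   50% of the biological replicates of at least one condition group,
   evaluated per batch with an exact rational comparison, so 2 of 4
   passes (`tau = 0.5`, inclusive).
4. **Log2 transform and batch merge.** Intensities are log2-transformed
   (zeros having become missing), and the per-batch matrices are merged by
   union of proteins and samples.
5. **Secreted-protein restriction.** Only proteins annotated with at least
   one of six Gene Ontology Cellular Component terms — secretory granule,
   secretory granule lumen, secretory granule membrane, extracellular
   vesicle, extracellular space, extracellular exosome — are analyzed.
   Terms are matched case-insensitively after whitespace normalization.
6. **Median centering.** Each sample column is shifted so its observed
   median is 0, removing global intensity variation and the discrete batch
   offset. The operation is idempotent and leaves the missingness mask
   untouched.
7. **Down-shifted imputation** (below).
8. **Welch tests, BH correction, hit calling** (below).
9. **Hierarchical clustering** of the row-z-scored matrix for the heatmap
   view.

## The imputation model

Missing cells are drawn from normal distributions shifted below the mean of
the measured values, reflecting the left-censoring mechanism. Two cases are
distinguished per (protein, condition) group:

* at least 50% of the group's replicates measured (`presence_cut = 0.5`,
  ties to this branch): the value is near the detection limit, draw from
  `Normal(mu - 0.5 * sigma, (0.3 * sigma)^2)`;
* fewer than 50% measured (including none): the protein is treated as
  consistently absent in that condition, draw from
  `Normal(mu - 1.8 * sigma, (0.3 * sigma)^2)`.

All three constants are in units of the reference SD. The reference mean
`mu` and SD `sigma` are, by default, computed per sample column over that
column's observed values (the usual per-column down-shift), which
reconciles "impute separately for each sample" with the condition-level
branch logic. Because the exact reference scope is a genuinely open choice,
`imputation_params(scope =)` also offers `per_condition` and `global` for
sensitivity analysis; the branch choice is always condition-level.

Each missing cell gets an independent draw from an RNG stream seeded by a
hash of (seed, protein id, sample id), so results are reproducible and
invariant to row/column reordering. Observed cells are never modified. A
zero or undefined reference SD is a hard error rather than a silent
fallback — it indicates a degenerate sample that should have been excluded.

## Testing and hit calling

Each treatment is compared against the untreated replicates of the same
batch with Welch's unequal-variance t-test on the imputed matrix, so the
test and the reported `log2FC = mean(treated) - mean(untreated)` use the
same values. P-values are adjusted with the Benjamini-Hochberg step-up
procedure; the default family is one (batch, treatment) pair
(`family = "per_treatment"`), matching a per-treatment reading of the
analysis; `per_batch` pooling is available because the alternative reading
changes hit counts. A protein is a **hit** when `q < 0.1` (strict) and
`|log2FC| >= 1` (inclusive).

Degenerate inputs follow explicit conventions: identical groups give
`t = 0, p = 1`; two zero-variance groups with different means are tested
with the variance floored at machine epsilon and flagged `var_floored`,
preserving directionality instead of dividing by zero.

## Clustering

For the heatmap view each protein row is z-scored with the sample SD
(constant rows become zeros with a warning), and rows and columns are
clustered agglomeratively. The distance/linkage pair is not dictated by the
analysis itself; the default — Euclidean distance with average linkage on
the z-scored values — is the common choice for such heatmaps, and
correlation distance or complete/Ward linkage can be configured. Only the
qualitative batch-separation property of the column dendrogram is asserted
in tests, not a specific leaf order.

## Targeted assays

Multiplex-array and ELISA readouts are normalized to whole-tissue protein
content; fold changes are per-donor against the mean untreated value of the
same (analyte, batch) and then averaged over donors (computing FCs on group
means first is the other defensible order; per-donor is the default because
it weights donors equally). Technical duplicates are averaged beforehand.
Effects are flagged by a two-sided unpaired equal-variance Student t-test:
`significant` at p < 0.05, `notable` at p < 0.09. qPCR relative expression
is `2^-dCt` against the mean Ct of PPIA and ACTB, optionally normalized to
the untreated group.

## What the synthetic data emulate

`simulation_spec()` defaults encode the study layout: 1400 proteins in two
batches; untreated plus three treatments (TiO2, SiO2, DEP) at n = 4, except
n = 5 untreated in the term batch, which additionally carries two degenerate
untreated samples (donors d14/d16) with a forced 97% missingness and a
matching exclusion list. Baseline log2 intensities are Normal(25, 2) with
replicate noise SD 0.5. The batch effect of magnitude 2 log2 units enters
twice: as a constant column shift (the discrete offset that median
centering removes) and as a per-protein random sign times the same
magnitude (protein-specific differences between gestational stages, which
survive centering and are what makes the column dendrogram split by batch).
2% of proteins per (batch, treatment) receive effects drawn from
{-2, -1.5, 1.5, 2} log2 units, planted only on secreted proteins since
effects on filtered-out rows would be unobservable by construction. 20% of
proteins carry only non-secretory GOCC terms, and 2% each decoy and
contaminant rows are appended. Missingness is intensity censoring,
`P(missing | x) = logistic((22 - x) / 1)` on the log2 scale (an MCAR mode
exists for contrast), and raw intensities are written as `2^x` rounded to 6
significant figures to exercise parser tolerance.

The generator deliberately omits protein-protein correlation, peptide-level
structure, and donor random effects. Passing recovery tests therefore show
that the pipeline's arithmetic and error control behave as designed under
its own assumptions — not that those assumptions exhaust real secretome
data.

## Problem sizes and numerical choices

The validation suite uses the full 1400-protein study layout for parameter
recovery (20 replicates for bias, 50 for the empirical FDR at 5% affected
proteins) and 50 seeds of a 200-protein two-batch design for the
batch-separation check; imputation calibration pools 10^4 draws per branch
from columns standardized to reference mean 0 and SD 1. Medians are
computed over observed values only; presence fractions compare exactly
(`>=`); BH q-values are clipped at 1 and returned in input order;
clustering ties follow `stats::hclust`'s deterministic behaviour given the
input order.

## Known limitations

* Welch tests at n = 4 have moderate power: against a true 2-fold change
  (|log2FC| = 1) with replicate SD 0.5, many true effects are missed, and
  the recovery reports quantify this rather than hide it.
* Median centering assumes most proteins are unchanged; with a large
  fraction of affected proteins the centering itself absorbs part of the
  signal.
* Imputed values enter the test like measurements; with many imputed cells
  in a group, apparent precision is optimistic. The imputation audit
  records branch and count per (protein, condition) so such calls can be
  inspected.
* The GOCC restriction is only as good as the annotation provided; an
  external annotation table takes precedence over terms embedded in the
  proteinGroups table, with fallback per protein.
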