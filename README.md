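# secretomics

Differential secretion analysis for label-free quantification (LFQ)
secretome experiments, built for studies that ask whether a treatment
changes what a tissue secretes into its conditioned medium — for example,
placental explants exposed to nanoparticles, measured by LC-MS/MS and
quantified with MaxQuant.

The package takes a MaxQuant-style `proteinGroups.txt` table, a sample
design (batch / condition / donor / replicate), and a protein-to-GOCC
annotation, and runs the complete analysis:

* removal of contaminant, reverse-decoy and site-only protein groups;
* exclusion of listed degenerate samples before any filtering;
* replicate-presence filter: a protein must be measured in ≥ 50% of the
  replicates of at least one condition (per batch);
* log2 transform (LFQ = 0 is non-detection, i.e. missing), batch merge,
  restriction to secreted proteins (six GOCC terms: secretory granule,
  secretory granule lumen, secretory granule membrane, extracellular
  vesicle, extracellular space, extracellular exosome), and per-sample
  median centering;
* missing-not-at-random imputation: each missing value in a
  (protein, condition) group is drawn from
  `N(mu − s·sigma, (0.3·sigma)²)`, with `s = 0.5` when ≥ 50% of the
  group's replicates are measured and `s = 1.8` when the protein is
  consistently absent in that condition (`mu`, `sigma` from the sample's
  observed values);
* Welch's t-test of every treatment against the untreated replicates of
  the same batch, Benjamini–Hochberg FDR correction per
  (batch, treatment) family, and hit calling at `q < 0.1` and
  `|log2FC| ≥ 1`;
* hierarchical clustering (Euclidean / average linkage) of the
  row-z-scored matrix, with the top column split reported.

It also covers the fold-change arithmetic of the accompanying targeted
assays (multiplex arrays and ELISA normalized to tissue protein content
with FC vs untreated and p < 0.05 / p < 0.09 flagging; qPCR `2^-dCt`
relative expression against PPIA/ACTB), and ships a synthetic-data
generator with planted ground truth so every stage is testable offline.

## Worked example

A 12-protein toy study ships with the package: one contaminant, one decoy,
one site-only row, two proteins failing the presence filter, two
non-secreted proteins, and five analyzable proteins of which one is
strongly up- and one down-regulated by TiO2 exposure.

```r
library(secretomics)
pg     <- system.file("extdata", "toy_proteinGroups.tsv", package = "secretomics")
design <- system.file("extdata", "toy_design.tsv",        package = "secretomics")

fit <- secretome_da(pg, design, seed = 1)
summary(fit)
#> Filter report (rows per batch):
#>  batch input contaminant reverse site_only presence non_secreted retained
#>   term    12           1       1         1        2            2        5
#>
#> Contrasts:
#>  batch   contrast n_tested n_hits
#>   term TiO2_vs_UT        5      2
#>
#> Cross-batch hit overlap:
#>    contrast n_batches n_shared    shared
#>  TiO2_vs_UT         1        2 P008;P009

hit_table(fit)[, c("protein_id", "gene", "contrast", "log2fc", "p", "q")]
#>   protein_id gene   contrast    log2fc            p            q
#> 1       P008 UPP1 TiO2_vs_UT  3.012498 8.542303e-06 4.271151e-05
#> 2       P009 DWN1 TiO2_vs_UT -2.012497 1.120073e-04 2.800182e-04
```

The filter report accounts for every input row
(12 = 1 + 1 + 1 + 2 + 2 + 5). P008 is secreted ~8-fold more under TiO2
(log2FC ≈ 3), P009 ~4-fold less; both clear `q < 0.1` and `|log2FC| ≥ 1`
and are called hits. `coef(fit)` returns the protein × contrast log2FC
matrix, `plot(fit)` the clustered z-scored heatmap, and
`plot(fit, "hits")` the hit log2FC heatmap.

Synthetic full-scale studies come from the generator:

```r
sim <- simulate_secretome(simulation_spec(seed = 1))
fit <- secretome_da(sim$protein_groups, sim$design,
                    exclusions = sim$exclusions, seed = 1)
rec <- recover_truth(simulation_spec(fraction_affected = 0.05), n_rep = 20)
```

See the vignette (`vignettes/differential-secretion.Rmd`) for the model,
parameter meanings and design choices.

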