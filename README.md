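# evcargo

Count-level analysis of extracellular-vesicle (EV) RNA cargo in paired
drug-sensitive / multidrug-resistant (MDR) tumor models.

MDR tumor cells — typically driven by P-glycoprotein overexpression —
shed EVs whose RNA content may both mark and spread the resistant
phenotype. The reference design has 24 small-RNA libraries: 2 tumor
models (NSCLC, CML) × 2 compartments (cell, EV) × 2 phenotypes
(sensitive, MDR) × 3 replicates. `evcargo` takes the integer count
matrices such a design produces and answers, with tested code:

* **Which species change with MDR?** TMM normalization, a CPM ≥ 2
  abundance filter, and a conditional negative-binomial exact test
  (variance $\mu + \phi\mu^2$, common dispersion $\phi$ by conditional
  maximum likelihood; at $\phi = 0$ the test is exactly binomial), with
  Benjamini–Hochberg adjustment. Sign convention: positive
  $\log_2\mathrm{FC}$ = higher in MDR.
* **Does EV cargo mirror the donor cell?** Replicate-summed log2 RPM
  pairs (EV vs cell), OLS regression, and a grid search over noise
  thresholds $T = 0,0.1,\dots,10$ keeping points with both coordinates
  $> T$; `t_max` is the smallest threshold maximizing $R^2$. A maximal
  $R^2 < 0.8$ reads as selective packaging.
* **What replicates across tumor models?** Four-contrast Venn
  partitioning and a directional consensus table (significant in both
  models, same sign), plus a local miR→target join.
* **QC and composition.** Per-sample biotype read fractions,
  average-linkage clustering on 1 − Pearson distance, and
  leading-logFC multidimensional scaling of samples.
* **qPCR validation.** 2^−ΔΔCt quantification and sign-concordance
  against the sequencing fold changes.

A negative-binomial simulator (`sim_config()` / `generate_dataset()`)
reproduces the design's structure — log-normal baselines, planted MDR
effects partly shared across models, an EV packaging model with
log-normal factors and abundance-dependent logistic dropout (so every EV
species also exists in cells), biotype-exact read composition — and makes
every stage testable against known truth.

## Worked example

```r
library(evcargo)

ds <- generate_dataset(sim_config(rng_seed = 42))
#> sim_dataset: 5000 features, 24 samples (selective packaging, phi = 0.1)

de <- de_contrast(ds$counts, "NSCLC", "cell")   # sensitive vs MDR
print(de, 5)
#> de_result: 5000 features (4972 tested), phi = 0.102834
#>      feature_id     logfc      p_value   adjusted_p mean_log2_cpm tested
#> 762   feat00762  3.362205 7.262299e-16 8.749366e-13     10.284926   TRUE
#> 2255  feat02255 -3.521902 7.488651e-16 8.749366e-13      6.286658   TRUE
#> ...
```

The estimated dispersion (0.103) recovers the generator's 0.1, and the
top features are planted effects (true |logFC| ≥ 2). Selectivity of EV
packaging for one condition:

```r
pairs <- build_pairs(subset_samples(ds$counts, "NSCLC", "cell", "sensitive"),
                     subset_samples(ds$counts, "NSCLC", "EV", "sensitive"))
sel <- grid_search_threshold(pairs)
sel
#> Selectivity regression (EV ~ cell, log2 RPM)
#>   threshold 0: R^2 = 0.6773, slope = 0.946, n = 4680
#>   Tmax = 1.7: R^2 = 0.6804, n = 4559
#>   unique to cells: 295; unique to EVs: 0
selectivity_report(sel)$verdict
#> [1] "selective"
```

Even the best threshold explains only 68% of the variance — the
log-normal packaging factors put a floor under the residual scatter, so
the verdict is selective packaging; 295 species are detected in cells but
absent from EVs (dropout), and none the other way round. Cross-model
consensus:

```r
cons <- directional_consensus(de, de_contrast(ds$counts, "CML", "cell"))
nrow(cons)
#> [1] 179
head(as.data.frame(cons), 2)
#>   feature_id logfc_NSCLC      p_NSCLC logfc_CML        p_CML   direction
#> 1  feat00012  -2.0170735 6.691755e-04 -2.370022 3.898017e-07 down_in_MDR
#> 2  feat00043   0.8051566 3.756225e-02  1.152599 8.284613e-03   up_in_MDR
```

A thin CLI over the same functions lives at `inst/cli/evcargo.R`
(subcommands `simulate`, `de`, `selectivity`, `consensus`, `composition`,
`cluster`, `qpcr`).

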