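# tmedyn

Statistics for **paired pre-/post-therapy single-cell tumor-microenvironment
cohorts**: which cell populations predict treatment response, how the
T-cell repertoire and T-cell states reorganize under therapy, and whether
the same signals validate in bulk survival cohorts. The package is aimed
at analysts working downstream of a standard scRNA-seq + TCR-seq pipeline
(counts, cell annotations, and clonotype IDs already in hand) in settings
where each patient contributes one biopsy before therapy and one after.

## What it computes

Let each patient have a pre and a post sample, and let tumor change be
the relative change in target-lesion sum, `(post − pre)/pre` (negative =
shrinkage).

* **Composition** — per-sample cell-type proportions; the pre/post
  *enrichment score* `|1 − (pre/Npre) / ((pre+post)/(Npre+Npost))|`;
  *SLOCC*, the largest single-sample share of a cluster
  (`max(counts)/sum(counts)`), flagging patient-private clusters; exact
  paired Wilcoxon tests on proportion changes.
* **Predictive / therapeutic indices** — for a univariate OLS fit of
  tumor change on a feature with slope `b` and coefficient of
  determination `R²`, the signed index `−sign(b)·R² ∈ [−1, 1]`
  (positive = favors shrinkage). Pi uses the baseline proportion, Ti the
  `log10(post/pre)` proportion ratio; significance is the two-sided
  Wald (t) test on the slope with `n − 2` df.
* **TCR dynamics** — per-clonotype two-sided Fisher's exact test of
  repertoire share pre vs post (`p < 0.05` & `OR > 1` contracted;
  `p < 0.05` & `OR < 1` expanded, novel clones merged into expanded);
  unique/clonal/shared sharing classes; *D50* diversity (minimum
  percentage of distinct clonotypes covering half the repertoire);
  Jaccard clonal similarity across subtypes; expansion–response
  association.
* **Signature scores** — binned-control gene-signature scoring
  (exhaustion: *CTLA4, HAVCR2, LAG3, PDCD1, TIGIT*; cytotoxicity:
  *PRF1, IFNG, GNLY, NKG7, GZMK, GZMB, GZMA, CST7, TNFSF10*) with a
  one-tailed 99% cutoff from designated background populations.
* **Ligand–receptor specificity** — edge weights as the product of the
  ligand's sender share and the receptor's receiver share of cohort mean
  CPM, filtered at 10 CPM expression, 0.1 specificity, 20% detection.
* **Bulk validation** — marker-averaged cell-type scores, score-on-score
  regression, and median-split log-rank survival on score ratios.
* **Synthetic cohorts** — a seeded generator planting compositional,
  clonal, and expression effects, with a ground-truth record, so every
  stage is testable without access to patient data.

## Worked example

```r
library(tmedyn)

params <- sim_params(seed = 1)          # 8 patients, paired pre/post
sim    <- simulate_cohort(params)       # cells + tumor sizes + ground truth

pm     <- proportion_matrix(sim$cells, "major_type")
pi_tab <- predictive_index(pm, sim$tumor)
head(pi_tab[order(pi_tab$wald_p), c("feature","n","slope","r_squared","index","wald_p")], 3)
#>    feature n  slope r_squared  index  wald_p
#> 7  Myeloid 8   2.47     0.807 -0.807 0.00243
#> 10     pDC 8  13.09     0.670 -0.670 0.01299
#> 11  Plasma 8 -11.17     0.320  0.320 0.14412
```

The generator planted a *positive* slope of tumor change on the baseline
myeloid proportion (more myeloid at baseline → less shrinkage), and the
fit recovers it: Pi = −0.807 with Wald p = 0.0024 marks the myeloid
compartment as an unfavorable baseline predictor. The pDC row illustrates
why the index alone is not a discovery procedure at n = 8 — small
compartments can reach nominal significance by chance.

```r
clones <- simulate_clonotypes(params, sim$cells)
ct     <- build_clonotype_counts(sim$cells, clones$assignments)
table(classify_clonotype_change(ct)$label)
#> contracted   expanded   unchange
#>         11         15        832

head(d50_table(ct, by = "patient_timepoint"), 3)
#>      group n_clones  d50
#> 1 P01/post       59 5.08
#> 2  P01/pre       76 2.63
#> 3 P02/post       61 4.92
```

Of 858 clonotypes tested, 26 change significantly; D50 values of a few
percent reflect the heavy-tailed (Zipf) clone-size law the generator
plants. `run_pipeline(run_config(...))` chains all stages over a fixture
directory and writes per-stage TSVs plus `summary.json`.

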