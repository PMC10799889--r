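---
title: "Methods: paired pre/post tumor-microenvironment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired pre/post tumor-microenvironment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmedyn)
```

## The setting

`tmedyn` analyzes cohorts in which each patient contributes a tumor sample
before therapy and a second sample after a fixed number of treatment
cycles, profiled by single-cell RNA sequencing (and, for T cells, paired
TCR sequencing), together with the radiological change in tumor burden.
The scientific questions it addresses are: which cell populations at
baseline *predict* response, which on-treatment population *changes track*
response, how the T-cell receptor repertoire reorganizes under therapy,
and whether cell states (exhaustion, cytotoxicity) shift in the
populations that matter. A bulk-RNA validation arm asks whether the same
cell-type signals, summarized as marker-gene averages, stratify survival
in larger treatment-naive cohorts.

All statistics operate on three inputs: a per-cell metadata table
(patient, pre/post timepoint, sample, major cell type, subtype), a raw
gene-by-cell count matrix in MatrixMarket triplet form, and a per-patient
tumor-size table. TCR analyses additionally take a per-cell clonotype
assignment; a clonotype is a cluster of cells with identical CDR3
nucleotide sequences, and the IDs are taken as given from the upstream
V(D)J pipeline. Clustering, annotation, doublet removal, and trajectory
methods are deliberately out of scope: `tmedyn` starts where those
pipelines end.

## Preprocessing

Quality control removes cells with fewer than 500 detected genes, more
than 8% mitochondrial counts (gene symbols prefixed `MT-` by default), or
more than 6000 detected genes; genes detected in fewer than 3 of the
*retained* cells are then dropped. Cell filters run before gene filters,
so gene detection counts always refer to the post-filter cell set, and
`qc_filter()` is idempotent. Both inequalities at the cell level are
strict (a cell at exactly 8.0% mitochondrial content survives); the
thresholds are all adjustable through `qc_thresholds()`.

Two normalizations are used downstream: counts per million (`cpm`), which
the ligand-receptor stage needs for its absolute expression threshold, and
log-normalization with a size factor of 10,000
(`log1p(count * 1e4 / cell_total)`), which signature scoring expects.
The mitochondrial fraction is defined on counts, the standard practice.

## Composition statistics

**Enrichment score.** For a cell type with pooled pre-treatment count
`pre` (out of `Npre` cells) and post-treatment count `post` (out of
`Npost`),

    score = |1 - (pre/Npre) / ((pre + post)/(Npre + Npost))|

It is zero exactly when the pre and post proportions agree, 1 when the
type is absent before treatment, and invariant to scaling all four counts.
Counts are pooled over the whole cohort per timepoint.

**SLOCC** (sample-level occupancy of a cell cluster) is the largest
single-sample share of a cluster's cells, `max(counts)/sum(counts)`. It
lies in `[1/n_samples, 1]`; values near 1 flag clusters that are
effectively private to one patient sample, a caution against interpreting
their cohort-level dynamics.

**Proportion denominators.** Major-type proportions are over all cells of
a sample. For subtypes the field's figures are usually drawn per
compartment, so the default denominator is the parent compartment (CD8
subtypes over that sample's CD8-bearing major type, myeloid subtypes over
myeloid cells), with `scope = "all_cells"` available; the scope is
recorded in the output because the two conventions differ materially for
small compartments. Paired pre/post comparisons of proportions use the
exact two-sided Wilcoxon signed-rank test on per-patient differences.

## The predictive and therapeutic indices

Both indices compress a univariate ordinary-least-squares fit of tumor
change on a cell-population feature into a signed effect size. Tumor
change is `(size_post - size_pre)/size_pre` on target-lesion sums, so
negative values mean shrinkage. For a fitted slope `b` and coefficient of
determination `R²`,

    index = -sign(b) * R²

which lies in `[-1, 1]`: a *positive* index means the feature favors
shrinkage. The predictive index (Pi) uses the baseline proportion as the
predictor; the therapeutic index (Ti) uses `log10(post/pre)` of the
proportion, the log-ratio stabilizing the fit at small cohort sizes.
Significance is the two-sided t (Wald) test on the OLS slope with `n - 2`
degrees of freedom, matching `lm()` output exactly; at `n = 8` patients
the t reference is the appropriate small-sample version of the Wald test.

Numerical choices worth stating:

* **Zero proportions in Ti.** The log-ratio is undefined at zero. When a
  label has any zero proportion, both numerator and denominator receive a
  pseudocount of half the minimum nonzero proportion of that label across
  the cohort; when no zero occurs, no pseudocount is applied, so exact
  worked ratios are preserved. The epsilon used is returned with the
  result.
* **Degenerate fits.** A predictor with zero variance cannot be fit; in
  the per-label drivers this yields a flagged degenerate row rather than
  an error. A perfect fit (zero residual variance) reports `wald_p = 0`
  with `degenerate = TRUE`. A constant response reports a zero index with
  `wald_p = NA`.
* **Cluster-score indices** (`meta_cluster_pi`) summarize per-cell
  signature scores by the per-patient *median* at baseline before
  fitting — medians because per-cell score distributions are heavy-tailed
  and a single aberrant cell should not move a patient's summary.

## TCR repertoire dynamics

Cells without an identified immune receptor are excluded; dual-IR cells
are retained. Within each patient, every clonotype is tested with a
two-sided Fisher's exact test on the 2x2 table of (clone cells, other
repertoire cells) x (pre, post), with totals equal to the patient's
IR-positive T cells at each timepoint. With the cross-product odds ratio
(pre-odds over post-odds; 0 and infinity permitted), clones with
`p < 0.05` and `OR > 1` are *contracted*, `p < 0.05` and `OR < 1` are
*expanded* — clones absent before therapy ("novel", `OR = 0`) fall in the
expanded class — and everything else is *unchange*. No multiple-testing
correction is applied by default because each clone is thresholded on its
raw p-value; a Benjamini-Hochberg option exists. Swapping the timepoints
maps contracted to expanded exactly and inverts every odds ratio, a
symmetry the test suite enforces.

Sharing classes per patient and compartment: *unique* clones have exactly
one cell, *clonal* clones have two or more cells confined to one
timepoint, *shared* clones appear at both timepoints. **D50** diversity is
the minimum percentage of distinct clonotypes whose cumulative abundance
reaches half the repertoire (inclusive, with lexicographic tie-breaks for
determinism); lower values mean a more clonal repertoire. Cross-subtype
clonal similarity is reported as the Jaccard index of clone-ID sets — the
simplest set-overlap measure; this is a repository choice, as the
underlying similarity heat maps in this literature rarely state their
metric.

## Signature scoring and background cutoffs

The score of a cell for a gene panel is the mean log-normalized expression
of the panel genes minus the mean of *control* genes matched for
expression level: all genes are ranked by mean expression and split into
25 equal-frequency bins, and each panel gene draws 50 seeded controls from
its own bin (panel genes excluded). This is the standard binned-control
scheme used throughout single-cell analysis; 25/50 are that scheme's
conventional defaults. The score is invariant to adding a constant to all
genes, and adding a constant to the panel genes alone moves the score by
exactly that constant provided the shift does not reorder genes across
bins.

The shipped panels are exhaustion (`CTLA4, HAVCR2, LAG3, PDCD1, TIGIT`,
background: CD4 SOCS3+ and CD4 naive cells) and cytotoxicity (`PRF1,
IFNG, GNLY, NKG7, GZMK, GZMB, GZMA, CST7, TNFSF10`, background: all CD4+
T cells). The one-tailed 99% cutoff is the *empirical* 99th percentile of
the pooled background scores; an empirical quantile was chosen over a
normal-theory cutoff because nothing guarantees the background
distribution is Gaussian, and with a few thousand reference cells the
empirical quantile is stable. By construction about 1% of background
cells exceed their own cutoff. Myeloid functional annotation applies the
same scoring machinery to user-editable panels
(`inst/extdata/panels.yaml`); the bundled M1/M2/angiogenesis/phagocytosis
lists are commonly used defaults, not a curated consensus, and should be
replaced for serious use.

## Ligand-receptor specificity

For a ligand-receptor pair and an ordered (sender, receiver) type pair,
the edge weight is the product of the ligand's sender share and the
receptor's receiver share of cohort-wide mean CPM:

    weight = mean(ligand | sender) / sum_types mean(ligand)
           x mean(receptor | receiver) / sum_types mean(receptor)

The factors of each gene form a partition of unity over cell types, so
the weights of one pair sum to 1 over all (sender, receiver) combinations
and are invariant to rescaling a gene's expression. Edges are filtered on
mean expression (at least 10 CPM in sender and receiver), specificity
(weight strictly above 0.1), and detection rate (at least 20% of cells in
both types); each rejection is logged with the failing rule. Mean
expression is the mean of per-cell CPM, consistent with the per-cell
normalization upstream (pooled-count CPM would weight large cells more).
A uniformly expressed pair across `k` types has weight `1/k²`, far below
the specificity threshold — the filter is intentionally aggressive about
removing housekeeping-like interactions, and on cohorts without
type-specific expression it can retain nothing. The ligand-receptor
catalog is supplied by the user as a two-column table; no interaction
database is bundled, avoiding a versioned external resource.

## Bulk validation

A cell type's level in a bulk sample is the arithmetic mean of its marker
genes (bundled sets: CD5L+ macrophages `CD5L, SLC40A1, FCGR3A, MARCO,
SEPP1`; CD8 GZMK+ `GZMK, GZMA, ITM2C, TNFSF9`; CD8 GZMB+ `GZMB, RGS1,
RBPJ, CTSD`; proliferating CD8 `STMN1, TYMS, MKI67, TUBB`). Coordinated
dynamics between two types are quantified by the same univariate OLS
engine as the indices. Survival comparisons split the cohort at the
median of a score ratio, ties going to the high group (so group sizes
differ by at most one), and compare overall survival with the two-sided
log-rank test. If a score vector contains non-positive values — possible
on log-scale data — both scores are shifted by a common constant to
positivity before the ratio, and the shift is reported. The log-rank
statistic is computed in-package (observed minus expected events over
hypergeometric variances) and is verified against `survival::survdiff`
to 1e-8 in the test suite.

## The synthetic cohort generator

Because the motivating data are controlled-access, every stage is
exercised on synthetic cohorts with planted effects. The generator is
deliberately minimal — it emulates the statistical structure the methods
assume, not real transcriptomes.

* **Composition.** Per patient, baseline major-type composition is drawn
  from a Dirichlet whose mean matches the lineage mix typical of treated
  tumor biopsies (T ~39%, myeloid ~16%, NK ~13%, B ~11%, epithelial
  ~11%, the rest minor) and sampled multinomially into cells. The post
  sample multiplies one designated type's weight by `10^r`,
  `r ~ N(0, 0.25)`, and renormalizes.
* **Response.** Tumor change is linear-Gaussian in the *realized* sampled
  predictors: an intercept (default -0.2, a cohort that shrinks on
  average) plus a slope on the realized baseline proportion of the
  responder type, plus a slope on the realized log-ratio of the shifted
  type, plus `N(0, noise_sd)`. Generating from realized rather than
  latent predictors means a noise-free configuration puts the downstream
  regression exactly on a line, so the index contracts are testable
  exactly (`index = ±1`). Note that renormalization damps the realized
  log-ratio relative to the planted one — calibrations targeting a given
  true `R²` must use the realized spread.
* **Clonotypes.** Clone sizes follow a truncated Zipf law (exponent 1.5
  by default; infinity collapses to a monoclonal repertoire), matching
  the heavy-tailed structure of real repertoires. Planted expanded and
  contracted clones multiply or divide their post-timepoint sampling
  weight by a fold-change. Planted clones are drawn uniformly from the
  clone list, so under the default mild fold-change (8x) tail clones are
  often too small to reach significance — recovery of *strong* (50-fold)
  expansions is the calibrated benchmark.
* **Expression.** Counts are lognormal-Poisson: per-gene base rates
  (lognormal for filler genes; one fixed rate for signature, control, and
  marker genes so they share expression bins) times a lognormal per-cell
  depth factor. Designated exhausted cells (by default, the CD8 GZMB+
  subtype post-treatment) receive a multiplicative `exp(shift)` on the
  signature genes only, so signature-score recovery has a closed-form
  expectation up to normalization effects.

Defaults describe an 8-patient paired cohort, the design the statistics
were built for. Cells per sample default to 2000 — a realistic post-QC
yield for a needle biopsy at desk scale. All randomness flows through the
seed in `sim_params()`; calling the three simulators with the same
parameters is byte-reproducible.

What the generator does *not* emulate: transcriptome-wide covariance,
batch and patient effects in expression, doublets, ambient RNA, shared
clonotypes across patients, or any coupling between expression state and
clonotype dynamics. Passing tests therefore demonstrate the correctness
and calibration of the statistics under their own assumptions, not
robustness to the full messiness of real data.

## Problem sizes and calibration checks

The test suite verifies, among others: exact agreement of the index
engine with reference OLS fits (1000 random instances, 1e-10); agreement
of every clonotype Fisher p-value with exhaustive hypergeometric
enumeration over all 2x2 tables with grand total at most 60 (about 630k
tables, with label flips tolerated only at exact floating-point ties of
the 0.05 threshold); Wald-test size within [0.04, 0.06] over 10,000 null
cohorts of 8 patients; mean recovered Pi within 0.05 of +0.5 over 500
cohorts planted at true R² = 0.5; recovery of 50-fold clonal expansions
in at least 95% of 200 repertoires of 1000 cells per timepoint, with
neutral repertoires at most ~5% non-unchange; signature-shift recovery
against a brute-force Monte-Carlo oracle over 100 seeds; and log-rank
agreement with `survival::survdiff` over 200 random cohorts plus
detection of a planted hazard ratio of 3 (n = 200) in at least 95% of
seeds. These sizes were chosen to make Monte-Carlo error comfortably
smaller than the tolerances while keeping the default suite quick.

## Known limitations

* The indices are strictly univariate; confounding between cell-type
  proportions (compositionality) is not modeled, and no compositional
  transform is applied because the underlying statistics are defined on
  raw proportions.
* Fisher totals use all IR-positive T cells of the patient/timepoint as
  the repertoire; restricting totals to a compartment would change
  borderline classifications.
* The 99% cutoff depends on the choice of background populations; absent
  those populations in a cohort, the profile errors rather than silently
  substituting a different background.
* The specificity filter's absolute 10 CPM threshold interacts with
  sequencing depth; cohorts with shallow libraries will retain fewer
  edges for reasons unrelated to biology.
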