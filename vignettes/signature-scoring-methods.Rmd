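---
title: "Methods: cross-dataset scoring of microglial activation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dataset scoring of microglial activation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hamscore)
```

## The problem

Microglia — the brain's resident myeloid cells — change expression state
in Alzheimer's disease (AD) and other neurodegenerative conditions.
Comparing those changes across studies is hard for three reasons this
package addresses directly:

1. **Heterogeneous platforms and units.** Sorted-cell bulk RNA-seq,
   whole-tissue RNA-seq, single-cell/nucleus UMI counts and qPCR Ct
   values all quantify expression on different scales.
2. **Cell-composition confounding.** In whole tissue, a higher myeloid
   gene set score in AD may reflect more myeloid cells (microgliosis,
   neuronal loss) rather than per-cell activation.
3. **Outlier-driven differential expression.** With small post-mortem
   cohorts, a single aberrant sample can create spurious DE calls.

## Gene set and DE scores

All scoring happens on log-stabilized expression, `log2(x + 1)`, where
`x` is nRPKM, a size-factor-normalized count, or any nonnegative
expression unit. For each dataset separately, the per-gene mean of the
log-scale values over that dataset's **control** samples is subtracted
(`control_center()`), giving control-centered values interpretable as
per-gene log2 fold changes relative to the control mean.

The **gene set score** of a sample is the unweighted average of its
control-centered values over the genes of a set
(`gene_set_score()`). The score is on the log2 scale: a score of 0.5
for a 20-gene set means the set is, on average, about 1.4-fold above
the control mean. By construction the mean score of the centering
controls is exactly 0, which the tests assert to 1e-9.

The **DE score** (`de_score()`) is the signed variant for
up/down-split signatures: up genes contribute with weight +1, down
genes with weight −1, so coordinated movement in both directions
accumulates in one number. With all-+1 weights it reduces exactly to
the plain score.

Two conventions keep scores comparable across studies:

* **Shared-gene restriction** (`restrict_to_shared_genes()`): when
  scores from several datasets are compared, each set is intersected
  with the genes present in *all* of them.
* **Per-dataset centering**: centering is never pooled across
  datasets; each study's controls define its own zero.

Genes absent from a matrix are dropped from the score, never imputed
as zero; the number of genes actually used is carried on every score
table.

Group differences are summarized by `compare_groups()` as
`delta` (difference of group mean scores, log2 scale) with a
two-sided t test — Student's pooled-variance by default, matching the
convention of the cohort tables; Welch is selectable. When a dataset
has a single control sample, centering still uses it and the
comparison reports the delta with `p = NA` rather than a p value no
test supports.

## Myeloid balancing

To separate per-cell activation from myeloid abundance in whole
tissue, `myeloid_balance()` discards samples until diagnosis groups
are comparable in myeloid score: samples are split into `n_bins = 20`
bins of similar myeloid gene set score, and within each bin samples of
the over-represented group are removed uniformly at random (seeded)
until the bin's AD fraction is as close as achievable to the overall
target fraction.

Choices that the balancing procedure leaves open, and how this package
resolves them:

* **Bin construction.** Equal-count (quantile) bins of the pooled
  scores are the default, with ties assigned to the lower bin:
  quantile bins guarantee occupied bins and are invariant to monotone
  transforms of the score. Equal-width bins are available via
  `method = "width"`.
* **Target ratio.** Bins containing a single diagnosis group carry no
  within-bin contrast and are discarded wholly; the target AD
  fraction is then the AD fraction among the *surviving* samples, and
  each mixed bin is matched to it as closely as its integer
  composition allows (the per-bin optimum is found by enumeration,
  discarding from one group only — balancing never duplicates or
  reweights).
* **Determinism.** The seed is a required argument; the same seed
  reproduces the identical plan, and any seed yields the same per-bin
  kept counts (only the identity of the randomly discarded samples
  may differ).

On synthetic cohorts with a planted composition confound (myeloid
mixing weight mean 0.1 in controls vs 0.2 in AD, n = 50/50), balancing
removes the diagnosis–myeloid-score association in essentially all
replicates while a genuine 0.5 log2 signature shift remains
detectable — the acceptance suite quantifies both rates.

## Pseudobulk construction

Single-cell/nucleus UMI matrices are reduced to per-(sample, cell
type) **pseudobulk** profiles by `aggregate_pseudobulk()`: the UMIs of
each gene are summed over all cells of one type from one sample, and
any (sample, type) group with fewer than `min_cells = 10` cells is
dropped. Pseudobulk columns are then normalized by median-of-ratios
size factors (`pseudobulk_normalize()`), log-stabilized, centered on
the dataset's control pseudobulks and scored like any bulk dataset.

Per-study QC presets (`qc_rule()`) reproduce the published filters of
the three external single-cell datasets the analyses drew on, with
boundary semantics following their stated wording exactly — kept at
exactly 800 or 400 total UMIs, exactly 30% or 5% mitochondrial
fraction, exactly log10(total) = 3.25. The garbled threshold
"log10(total UMIs) R 3.25" in the source description is read as ≥,
consistent with the "at most 5%" phrasing of its paired criterion.
Mitochondrial genes are identified by a configurable id prefix
(default `"MT-"`), since no fixed rule is universal across
annotations; mitochondrial fractions are always computed on raw
counts, before any normalization. Cluster assignment (e.g. which
cells are microglia) is upstream input, not computed here.

## The DE stage and Cook's-distance filtering

`fit_gene_linear_models()` fits ordinary least squares per gene on
log-stabilized values — a deliberately transparent engine in place of
negative-binomial or precision-weighted machinery. Covariates (PMI,
sex, ApoE4 status, age) are additional design columns, not separate
code paths; an age-only model (`~ age`) expresses aging-DE analyses.
Genes are called DE at BH-adjusted p ≤ 0.05 among genes passing the
outlier filter.

The outlier filter follows the rule of keeping a gene only if its
maximum per-sample Cook's distance

$$D_j = \frac{r_j^2\, h_{jj}}{p\, s^2\, (1 - h_{jj})^2}$$

does not exceed the upper-0.01 critical value of F(p, m − p). The
analytic distances equal the leave-one-out refit definition to 1e-8
(tested). One property of the OLS version deserves note: because a
single outlier also inflates the per-gene variance estimate $s^2$,
$D$ for one outlier saturates at $\mathrm{df}/(p\,(g-1))$ for a group
of size $g$, so in small *balanced* designs the filter can only flag
genes when leverage is concentrated (unbalanced groups, extreme
covariate values). Engines with dispersion sharing across genes do
not have this ceiling; consequences for sensitivity are covered in
the tests by exercising the filter where the bound permits failure.

Type-I error of the stage is controlled empirically: on 5000 null
NB-simulated genes (dispersion 0.1, 15 vs 10 samples) the raw
p < 0.05 rate is within 0.05 ± 0.01.

## qPCR Ct processing

Fluidigm-style plates are processed in a fixed order, each step
idempotent or conservative:

1. **Ceiling imputation** (`impute_ceiling()`): per assay, the
   maximum reliable Ct (maxCt) over quality > 0 readings is computed
   — the 999 non-detection sentinel never counts as reliable — and
   every Ct above maxCt, including 999, becomes maxCt + 0.5. maxCt is
   computed on raw replicate records, before duplicate collapsing.
2. **Duplicate reconciliation** (`collapse_duplicates()`): duplicate
   wells differing by at most 2.82 cycles are averaged; wider pairs
   are discarded outright and logged. A pair differing by exactly
   2.82 has standard deviation 2.82/√2 ≈ 2 cycles, the rationale for
   the threshold.
3. **Global-median ΔCt** (`delta_ct()`): each sample's median Ct over
   its assays is subtracted from its Cts, removing per-sample loading
   offsets (ΔCt is invariant to additive per-sample shifts; tested).

Group DE on ΔCt (`qpcr_group_de()`) reuses the linear-model stage on
−ΔCt, so positive effects mean higher expression in AD and compare
like-for-like with RNA-seq log2 fold changes.

## Cohort statistics

`build_cohort_table()` reproduces cohort characteristic tables:
binary variables (sex, ApoE4 carriage) get counts, percentages and a
two-sided Fisher's exact p; continuous variables (age, PMI, MMSE) get
median (IQR) and a Student's t p. The Fisher p sums hypergeometric
point probabilities not exceeding the observed table's probability
(relative tolerance 1e-7 on the comparison — the summation
convention, not the doubling convention); quartiles interpolate
linearly between order statistics (type 7). Both conventions were
chosen to match mainstream statistical environments; the printed
medians and IQRs of published tables cannot adjudicate quartile
conventions without raw data, so the default is documented rather
than argued.

## The synthetic-data generator

`sim_config()` fixes the study conditions once; every generator is
fully deterministic under its seed.

* **Sorted-cell cohorts** (`simulate_sorted_counts()`): NB counts
  (variance μ + αμ², α = 0.1 by default) around a lognormal baseline
  (log-mean log 100, log-sd 0.8) with 25-gene marker blocks per cell
  type elevated 16-fold in their own type; planted log2 fold changes
  multiply AD means; default cohort 15 control / 10 AD.
* **Whole tissue** (`simulate_whole_tissue()`): convex mixtures of
  cell-type signatures with a diagnosis-specific myeloid weight
  (control mean 0.1, AD mean 0.2; sds 0.04 and 0.06, truncated to
  [0.01, 0.9] — chosen once as a realistic overlap so that mixed
  score bins exist) plus NB noise; default cohort 42 control / 158
  AD; the drawn weights are returned as ground truth.
* **Cells** (`simulate_cells()`): lognormal per-cell depth, a
  beta-distributed mitochondrial fraction allocated to MT- genes, and
  multinomial gene draws from the cell type's profile; the depth tail
  places some cells below QC thresholds by construction.
* **qPCR** (`simulate_qpcr()`): replicate Ct = intercept − slope ×
  log2(expression) + Gaussian noise, with a detection ceiling mapping
  to the 999/quality-0 convention.

What the generator deliberately does **not** emulate: batch effects,
library-size gradients correlated with diagnosis, doublets, ambient
RNA, gene–gene correlation beyond the cell-type blocks, and
alignment/counting artifacts. Green tests therefore demonstrate that
the *procedures* are implemented correctly and behave as designed
under their stated statistical assumptions — not that those
assumptions hold in any particular real dataset.

## Numerical choices and problem sizes

* Z scores use the n − 1 (sample) denominator; zero-variance rows
  become all-zero with a warning rather than NaN.
* IQR-based variable-gene ranking breaks ties by gene id in C-locale
  order, making selections reproducible across platforms.
* Size factors follow the median-of-ratios definition (reference =
  per-gene geometric mean over samples, genes with any zero
  excluded); they agree with the standard reference implementation to
  1e-8 on random fixtures.
* The noiseless-fit limit (residuals at rounding-error scale) is
  detected by a relative threshold and reported as p = 0 with zero
  Cook's distances.
* Validation suite sizes, chosen to characterize the estimators
  precisely while keeping the default test run quick: 100 seeds for
  shift recovery at n = 15/10, 200 replicates for balancing rates at
  n = 50/50, 5000 genes for type-I error. The acceptance script
  reports the same quantities at 50 replicates.

## Known limitations

* The OLS DE stage ignores mean–variance structure; it is calibrated
  for type-I error on log-stabilized NB counts at the simulated
  depths but is less powerful than dispersion-sharing engines, and
  its Cook's filter has the saturation property described above.
* Balancing discards samples; with strong confounding most samples of
  the majority group are lost, and the procedure refuses (errors)
  when no bin contains both groups.
* Gene identifiers are opaque strings; symbol/alias harmonization
  across annotations must happen upstream.
* nRPKM requires exonic model lengths supplied by the caller; no
  annotation handling is included.
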