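---
title: "proteopipe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proteopipe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopipe)
```

proteopipe implements three tandem differential-analysis pipelines for
quantitative proteomics — protein groups, PTM sites, and peptide tables
re-aggregated to proteins — followed by function mining (over-representation,
preranked gene-set enrichment, fuzzy pattern clustering, interaction-network
extraction). This vignette explains the statistical models, the tunable
parameters, and the design decisions, in that order of importance.

## Input dialects and identifiers

Wide tables follow the MaxQuant convention: per-sample intensity columns share
a prefix (`"LFQ intensity "`), an intensity of 0 encodes "not observed", and
decoy/contaminant rows carry a `"+"` in `Reverse` / `Potential contaminant`
columns. Long tables (DIA-NN, Spectronaut) encode missingness by row absence;
because DIA software dialects differ, `reshape_long()` takes explicit
feature/sample/value column names rather than hard-coding any one of them.
Duplicate (feature, sample) pairs error by default (`"max"`/`"sum"` policies
are available): silent aggregation would hide upstream problems. Protein
groups keep the full `";"`-separated identifier; the first member is the one
used for annotation joins (razor-protein convention). `make_unique()` gives
every feature a distinct identifier with deterministic `.1`, `.2` suffixes.

PTM features are identified by site, `PROTEIN_<aa><pos>_M<multiplicity>`
(e.g. `P04637_S15_M1`). Rows quantified at different multiplicities are kept
as distinct features rather than collapsed — multiplicity classes are
distinct molecular species and averaging them mixes stoichiometries. When a
localization-probability column is supplied the class-I convention
(probability ≥ 0.75) is applied; with no such column the filter is off.

## Missing-occupancy filtering

The default filter keeps a feature if it is *fully observed in at least one
condition* (`thr = 0`). This criterion suits on/off regulation: a protein
absent in the control but complete in the treatment is exactly what one wants
to keep, while a feature scattered 2-of-3 everywhere is mostly imputation
fodder. An `overall-fraction` mode is available for designs with many
conditions.

## Variance-stabilizing normalization

Raw MS intensities have noise whose standard deviation grows with the mean
(multiplicative component) plus a roughly constant additive floor. The
transform

$$h_i(x) = \mathrm{glog2}\!\left(\frac{x - a_i}{b_i}\right),\qquad
\mathrm{glog2}(y) = \log_2\left(y + \sqrt{y^2 + 1}\right)$$

with per-sample offset $a_i$ and scale $b_i > 0$ behaves like
$\log_2(2y)$ for large $y$ and is linear near zero, so a single pair
$(a_i, b_i)$ can stabilize both regimes. Parameters are fitted by maximum
likelihood under the model that a feature's transformed values are equal
across samples up to Gaussian noise of common variance, profiling out the
feature means and the variance, and including the Jacobian of the transform.
Robustness against genuinely regulated features comes from least-trimmed
squares: cells with the largest squared residuals (10% by default) are
excluded from the fit, and the trimmed set is refreshed as the parameters
move.

Numerically, the fit minimizes the profile negative log-likelihood jointly
over all $(a_i, \log b_i)$ with BFGS inside an outer loop that refreshes the
LTS cell set, declaring convergence when parameters move less than `tol`
(1e-8) or the objective and trimmed set are stable. A per-sample coordinate
scheme was considered and rejected: with the glog Jacobian in the
likelihood, the per-sample updates have no closed form, and the joint
quasi-Newton step converges in a handful of outer iterations on typical
matrices. Parameters are internally rescaled by per-sample medians so the
optimizer works on dimensionless quantities.

Two caveats worth knowing. First, the glog scale *compresses* fold-changes
of low-intensity features (the transform is flatter near the additive-noise
floor); this is the price of stabilized variance and it is why the
fold-change-accuracy checks in the test suite run on the plain `log2` scale.
Second, a simpler per-sample median centering (`normalize_median()`) is
provided for comparison but is not the default.

## Imputation

Methods split by missingness mechanism. MNAR (left-censored) methods use
*per-sample* statistics, since detection limits are run-specific:
`left-shifted` draws from
$\mathcal{N}(\mu_s - \text{shift}\cdot\sigma_s,\ (\text{width}\cdot\sigma_s)^2)$
with the Perseus-style defaults shift = 1.8, width = 0.3; `min-det`
substitutes the per-sample 1% quantile deterministically; `min-prob` draws
around that quantile. The MAR option is `knn`: the average of the k = 10
nearest feature rows (Euclidean distance on shared observed columns, scaled
by the number of shared columns; ties broken by feature order), falling back
to the feature's row mean when no neighbour is observed at the missing cell
(the fallback is recorded in the processing history). Draws come from one
seeded stream, and cells are imputed in row-major order, so results are
exactly reproducible and adding features below a row does not change the
draws above it.

A documented interaction: gross positive outliers inflate $\sigma_s$, which
pushes `left-shifted` imputations further down; combined with left-censoring
this attenuates recovered fold-changes of regulated low-abundance features.
The synthetic-data harness quantifies this (about 15% attenuation when 5%
gross outliers and soft censoring act together, versus about 2% with
censoring alone). Filtering outliers upstream or using `min-det` reduces the
effect.

## Peptide-to-protein aggregation

Three strategies, chosen to span the robustness/efficiency spectrum:

* **median polish** — Tukey's alternating row/column median sweeps decompose
  the peptide × sample block into overall + peptide effect + sample effect +
  residual; the protein abundance is overall + sample effect. The sweep
  pairing follows base R's `medpolish` (after each row sweep the median of
  the *column* effects moves into the overall term, and vice versa), because
  median-polish fixed points depend on the sweep scheme and this is the
  canonical one. Convergence is declared when no effect moves more than
  `tol`; the residual matrix then has row and column medians at zero.
* **robust regression** — the two-way model
  $y_{ps} = \mu_s + \pi_p + \varepsilon_{ps}$ with sum-to-zero peptide
  effects, fitted by IRLS with Huber weights (k = 1.345). The sum-to-zero
  identification makes $\mu_s$ the group-average abundance, directly
  comparable with the other two methods. The residual scale (MAD/0.6745) is
  re-estimated for the first ten iterations and then frozen: with a fixed
  scale and a convex loss the reweighting iteration is monotone, whereas
  perpetual re-estimation was observed to oscillate on contaminated blocks.
  $k = \infty$ recovers ordinary least squares exactly.
* **total sum** — column sums on the *raw* intensity scale (the only scale
  where summing is meaningful), then log2 for testing. Missing peptides
  contribute zero. Not outlier-resistant; provided because it matches what
  much upstream software reports.

Median polish and robust regression operate on imputed, normalized log-scale
data (the pipeline imputes at peptide level first); `sum` un-logs a `log2`
matrix but refuses a `glog2` one, which cannot be inverted to raw
intensities — aggregate before VSN in that case. Groups of one peptide pass
through unchanged under all three methods. With 5% gross outliers, both
robust methods recover true per-sample profiles with RMSE ≈ 0.13 on the
default synthetic dataset, while `sum` exceeds 2; very occasionally (one
protein-sample block in several hundred) a majority of a block's peptides
are contaminated and no aggregator can rescue it.

## Moderated testing

Per feature, a cell-means fit gives condition means, the pooled residual
variance $s^2_g$ with $d_g$ residual degrees of freedom, the contrast
estimate $\beta_g$ (a log2 fold-change) and its unscaled standard error
$u_g = \sqrt{1/n_A + 1/n_B}$. Variances are modelled as draws from a scaled
inverse chi-square prior with hyperparameters $(d_0, s_0^2)$ estimated by
the method of moments on $\log s^2_g$: with
$e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)$, $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d_g/2)}$ via a monotone
Newton iteration on the trigamma inverse, and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When the spread of
$\log s^2$ does not exceed chi-square sampling noise, $d_0 = \infty$ and
$s_0^2$ is the plain average of the variances (the natural pooled estimate
in that regime). Zero variances are floored at 1e-12 before the log-moment
step, where the digamma moments are undefined.

The moderated statistic uses the posterior variance
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$,
$\tilde t_g = \beta_g / (u_g \tilde s_g)$, with two-sided p-values on
$d_0 + d_g$ degrees of freedom; $d_0 = 0$ reproduces the ordinary t-test
and $d_0 = \infty$ the normal reference with $\tilde s^2 = s_0^2$.
Benjamini–Hochberg adjustment is applied per contrast by default (pooled
adjustment is an option); significance gates on `padj <= alpha` **and**
`|log2fc| >= lfc`, defaulting to 0.05 / 1.0 — conventional thresholds,
surfaced in the configuration since no universal values exist. The test
suite verifies calibration (null p-values uniform; ~5% below 0.05) and FDR
control (observed FDP ≈ 0.04 at the 0.05 level with 10% true effects).

## Function mining

**ORA** is the upper-tail hypergeometric test of query/set overlap. The
universe defaults to the features actually tested, not the whole annotation
— the standard background correction; set sizes are bounded to [5, 500]
after intersection with the universe.

**GSEA** is the preranked variant: the weighted running sum over the ranked
list (hits weighted by $|score|^p$, default $p = 1$, normalized to total 1;
misses decrement $1/(N-K)$), with the enrichment score the signed maximal
deviation. The null is *gene-label* permutation — memberships redrawn
uniformly with a seeded stream — which is the appropriate null when only a
ranked list (the default ranking metric is the signed moderated t) reaches
the module; sample permutation would need the raw matrix. NES divides ES by
the mean same-sign permutation score; `perm_p` is the fraction of same-sign
permutation scores at least as extreme, so its resolution is `1/n_perm`
(default 1000).

**Pattern clustering** uses fuzzy c-means (Bezdek updates) on row-z-scored
per-condition means of the significant features. Euclidean distance on
z-scored profiles is rank-equivalent to correlation distance, which is what
makes z-scoring the right preprocessing. The fuzzifier defaults to the
conventional m = 2; m → 1 approaches hard k-means (the suite checks both
regimes). A feature at zero distance from a center takes full membership
there; the objective $\sum_{ik} u_{ik}^m d_{ik}^2$ is non-increasing across
iterations by construction and is recorded in the result.

**Networks** are read from local STRING-format `protein1 protein2
combined_score` files; species prefixes (`9606.`) are stripped, edges below
the threshold (default 400, "medium confidence") dropped, orientations
merged keeping the maximum score, and identifiers matched
case-insensitively. The induced subnetwork keeps queried nodes that are
present in the graph even when isolated.

## Synthetic data: what it emulates and what it does not

`simulate_peptide_dataset()` builds a two-condition LFQ experiment from the
generative chain protein abundance → peptide offset → replicate noise →
outliers → missingness. Defaults describe a routine deep LFQ comparison:
100 protein groups × 7 peptides (deep experiments typically quantify ~5–10
peptides per protein), 4 replicates per condition, 10% regulated proteins
at one log2 unit (signs alternating), replicate SD 0.3 log2 units (~20%
CV), 5% gross positive outliers of 5–10 log2 units, soft left-censoring
centered 2 SD below the per-sample mean with a logistic transition of width
0.5 log2 units, and 5% uniform dropout. The soft (logistic) censoring was
chosen over a hard threshold so imputation-method comparisons have a smooth
target; note that with a transition this narrow relative to the abundance
spread, missing cells concentrate almost entirely in the lowest intensity
tercile at any plausible shift.

What the generator does *not* emulate: correlated peptide noise within a
protein, shared/razor peptides between groups, batch effects, retention-time
drift, or PSM-level FDR. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not performance on any
particular instrument's quirks.

Problem sizes used by the test suite and the acceptance script — 2000
features for calibration checks, 5000 simulated variances for prior
recovery, 20 replicate simulations for FDR control, 100-protein datasets
for aggregation accuracy — were chosen as the smallest sizes at which the
Monte-Carlo error is well below each check's tolerance.

## Degenerate inputs and tie-breaking

Even-count medians are the midpoint of the central order statistics
(`stats::median`), making every median-based result platform-deterministic.
kNN ties break by feature order. Constant profile rows are dropped before
clustering (they carry no pattern). A sample with no observed values cannot
be imputed and errors. Contrasts naming an unknown condition error before
any computation. All random stages take an explicit seed; the pipeline forks
per-stage seeds from the global seed by stable stage-name hashing, so
inserting a stage does not perturb the streams of later stages.

## Run logs

Every matrix-mutating operation appends one record (operation, parameters,
feature counts in/out) to the object's history; `run_pipeline()` merges that
history with ingest/downstream stages into a JSON run log that also records
input MD5 digests, the seed, the package version and the output file list.
`write_report()` regenerates the human-readable summary from the log alone,
so a report can always be reproduced from a saved run.

## Known limitations

No TMT/reference-channel normalization or batch correction; no moderated
F-tests across more than two conditions or duplicate-correlation models; no
identifier mapping between annotation namespaces; no uncertainty propagation
from imputation into the test (single imputation only); networks and gene
sets are consumed from local files only.
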