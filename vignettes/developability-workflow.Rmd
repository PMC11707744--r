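---
title: "Condensing developability assay panels: rates, clusters, ADOS and the HDP"
author: "devrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensing developability assay panels: rates, clusters, ADOS and the HDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devrank)
```

## The problem

Early-stage antibody candidates are screened with a panel of developability
assays (DAs): viscosity, chromatographic retention times (SEC, HIC, SMAC),
self-interaction measures (AC-SINS, the diffusion interaction parameter kD),
thermal transitions by DSC, particle counts, extensional-flow stress assays,
and in silico sequence/structure liabilities. Each formulation:antibody
combination (a *sample*) yields dozens of scalar assay variables, frequently
long-tailed, often conflicting, and partially redundant. Meanwhile the
attribute one actually cares about — e.g. the monomer-loss rate under
long-term storage — is slow and expensive to measure.

`devrank` implements a statistical workflow that (i) estimates degradation
rates with proper error weighting, (ii) maps the redundancy structure of the
assay variables by rank correlation and hierarchical clustering, with a
leave-one-sample-out robustness statistic, (iii) condenses the panel into a
single Averaged Developability Output Score (ADOS), and (iv) finds the
minimal set of cheap t = 0 variables whose ranks predict the ranked storage
attribute — the Holistic Developability Parameter (HDP) — via LASSO
regression, with a systematic sweep over rank uncertainty.

## Degradation-rate estimation

Percent monomer (or HMW / fragment) versus months in storage is fit with a
straight line, $y = a + bt$; the slope $b$ (percent/month) is the observed
relative rate and its standard error comes from the fit. Technical
replicates enter as independent points rather than per-time means, so
duplicating a measurement legitimately tightens the slope error.

`fit_rate_wls()` adds instrumental error weighting $1/\mathrm{CV}^2$: each
time point's CV (percent) is computed from its replicate spread, and points
with zero spread (or a single replicate) receive a default CV so their weight
stays finite. The default of 0.036 %/month reflects the panel-wide average
CV of a typical 25 °C monomer data set; at 5 °C degradation is so slow
(median ~0.015 %/month against an average CV of ~0.074) that rates are
dominated by fitting error, which is why the 25 °C rate is the recommended
target attribute.

Whether two samples' rates genuinely differ is decided by a two-sided z-test
on the slope difference with pooled standard error
$\sqrt{SE_1^2 + SE_2^2}$ (`rate_significance()`, $\alpha = 0.05$). The test
statistic is deliberately simple: slopes and their standard errors are the
only quantities the rate-fitting stage guarantees.

### Rank uncertainty

Samples whose rates are statistically indistinguishable from several
neighbours make the outcome ranking itself uncertain.
`enumerate_rank_sets()` formalizes the sensitivity analysis: samples with
unambiguous positions keep fixed ranks, statistically tied samples share a
tie-averaged rank, and each *ambiguous* sample is swept through its minimal
(L, $|b| - SE$) and maximal (H, $|b| + SE$) degradation rate. Four ambiguous
samples give $2^4 = 16$ labelled rank sets (LLLL…HHHH) plus the "absolute"
set ranked on point estimates — 17 responses for the LASSO robustness sweep.
One convention deserves a note: because every rank set must remain a
tie-averaged permutation of $1..S$ (so ranks always sum to $S(S+1)/2$), a
pair tied "first" occupies positions 1–2 as rank 1.5 each, and the ambiguous
block then competes for the next free positions.

## Correlation structure and clustering robustness

`spearman_matrix()` computes pairwise Spearman $\rho$ over samples
(average-rank ties), making every downstream stage invariant to monotone
re-expression of any assay variable. `cluster_variables()` then builds a
group-average (UPGMA) dendrogram on Euclidean distances between rows of the
correlation matrix — each variable is represented by its full correlation
*profile*, so two variables are close when they relate to the whole panel in
the same way. (The more common $1-\rho$ dissimilarity is available via
`profile = FALSE`.) Branch labels come from cutting the tree into `k`
groups; a count-based cut is reproducible where a visual height cut is not.
Defaults are k = 6 for the full 32-variable panel and k = 4 for the
28-variable panel, matching the branch counts those panels support.

Robustness is assessed by leaving out one sample at a time, re-ranking and
re-clustering from scratch (`leave_one_out_dendrograms()`, 1 + S = 10 trees
for a nine-sample panel). Two statistics summarize the result
(`pairing_stability()`):

* **P** — the fraction of iterations in which a variable's first-merge
  partner set intersects its reference partner set. "Immediate neighbour" is
  operationalized as the sibling leaf-set at the variable's first merge,
  which stays well-defined when a variable first merges into a multi-leaf
  cluster. The reference iteration counts, so $P \ge 1/10$.
* **group_P** — the fraction of iterations in which the variable keeps its
  branch label at the same k, after majority-mapping each iteration's
  branches onto the reference branches.

Within each branch, the *least significant* member is the leaf whose own
first merge sits highest (`flag_least_significant()`; ties break to the
lowest var_id). Variables flagged in at least 6 of the 10 dendrograms are
deemed difficult to cluster (`identify_poor_clusterers()`) and removed
before scoring — on the canonical panel that is the 32 → 28 step, and the
removal set {29, 30, 31, 32} is carried as explicit configuration rather
than re-derived on every run, so the pipeline is deterministic even when a
reduced panel would flag a different set.

## ADOS: a percentile-scaled distance from ideal

For each variable $j$ and sample $i$, with $Y_{50\%}, Y_{20\%}, Y_{80\%}$
the median and 20th/80th percentiles of the variable's observed values:

$$V_{ij} = \frac{y_{ij} - Y_{50\%}}{Y_{80\%} - Y_{20\%}}, \qquad
NV_{ij} = \frac{V_{ij} - \min_i V_{ij}}{\max_i V_{ij} - \min_i V_{ij}}$$

Percentiles use linear interpolation with inclusive endpoints
(`stats::quantile` type 7, the spreadsheet convention; exclusive and
nearest-rank variants are exposed through `quantile_type`). For variables
where the *largest* value is desirable (e.g. thermal transitions, kD) the
normalized score is reflected, $NV^{+} = 1 - NV$; otherwise $NV^{+} = NV$.
After adjustment 0 is always the best sample and 1 the worst, and the whole
construction is invariant under per-variable increasing affine transforms —
assay units never matter.

Scores are averaged within each cluster group,
$\overline{Grp}_x = \sum_j NV^{+}_{ij} / n_x$, and ADOS is the *sum of the
group means*: a sample best in everything scores 0, one worst in everything
scores the number of groups. The Euclidean distance-from-ideal
($\sqrt{\sum_x \overline{Grp}_x^2}$) is available via
`aggregate = "euclidean"`, but the sum is the default because group means —
not squared distances — are what the MLR weighting stage consumes. A
variable whose $Y_{80\%} = Y_{20\%}$ has no discriminating power at the
panel size and raises an error rather than being silently zeroed.

`ados_mlr()` regresses the target ranks on the group means (unconstrained
OLS with intercept — no sign or intercept constraint is imposed) and reports
the Pearson correlation between the re-ranked fitted scores and the
tie-averaged target ranks. With nine samples and four groups the fit is
close to saturated; the function warns when degrees of freedom run out, and
aliased (collinear) group weights are set to zero with a warning.

## The HDP: LASSO on ranked data

All variables are first converted to tie-averaged desirability ranks
(`rank_matrix()`; rank 1 = most desirable under the registered direction,
spreadsheet RANK.AVG tie semantics), and the target attribute to ranks of
the *absolute* observed rate (smaller loss = better). `fit_lasso()`
standardizes predictors internally, builds a 100-point log-spaced λ grid on
$[10^{-3}\lambda_{\max}, \lambda_{\max}]$ (with $\lambda_{\max}$ the
smallest λ that zeroes every coefficient), and picks λ* by minimum mean
5-fold cross-validated squared error; the fold assignment is drawn once from
the recorded seed, so every fit — and the entire 17-fit sweep — is
bit-reproducible. The minimum-CV rule is used rather than the 1-SE rule
because model selection here *is* the scientific output: the chosen set of
variables is the HDP. Coordinate descent (via glmnet) runs to tolerance
1e-7, and coefficients are reported back on the ranked-predictor scale.

`selection_sweep()` refits the model once per rank set and counts nonzero
coefficients per variable; variables with selection frequency near 1 across
all 17 rank sets are keystone predictors robust to the rank uncertainty of
the outcome.

## What the synthetic generator emulates — and what it does not

Real per-sample assay values for such panels are rarely deposited, so every
stage is validated against `synth_config()`/`generate_matrix()` panels with
the statistical structure the analysis assumes:

* **Panel geometry** — 9 samples (3 mAbs × 3 buffers, ids A1…C3) × 32
  variables.
* **Correlated blocks** — a latent-factor model: four blocks (9, 8, 5 and 6
  variables — the red/blue/green/purple branches) plus four unassigned
  variables (ids 29–32). Each member is
  $\lambda f_b + \sqrt{1-\lambda^2}\,\varepsilon$ with default loading
  $\lambda = 0.9$, i.e. within-block latent correlation $\lambda^2 = 0.81$ —
  strong but not degenerate, the regime a correlation heatmap of related
  assays actually shows. The factor model was preferred to a copula because
  it controls the within/between-block Spearman structure directly and is
  trivially auditable.
* **Long tails** — values pass through the rank-preserving map
  $(e^{\tau z} - 1)/\tau$ (default $\tau = 0.5$), giving positively skewed
  marginals without touching any rank-based statistic.
* **Sparse outcome signal** — the monomer-loss rate is driven by five
  variables (ids 5, 8, 10, 2, 27 — one red pair, one purple pair, one blue),
  standardized, direction-oriented and weighted (1, 0.25, 0.8, 0.7, 0.6);
  the 0.25 weight plants a deliberately small-but-real contributor, the
  kD-like case. Gaussian noise of sd 0.1 on the standardized-signal scale
  is the default; rates are anchored in a realistic band around −0.35
  %/month.
* **Time courses** — linear monomer loss on the study grids (40 °C:
  0, 0.5, 1, 3; 25 °C: 0, 1, 3, 6; 5 °C: 0, 3, 6, 12, 18 months), two
  replicates per point, CV-type heteroscedastic noise (default CV 0.036%,
  so ~0.036 percentage points at 100% monomer), with 40 °C running ~30×
  faster and 5 °C ~7× slower than 25 °C.

The generator does **not** emulate: real assay units or detection limits,
missing values (the data model rejects them by design), inter-assay
correlations that change sign across buffers, insoluble-aggregate dropout
points, or non-Arrhenius temperature coupling (rates per temperature are
independent draws, deliberately — no Arrhenius extrapolation is attempted
anywhere). Passing tests on synthetic panels therefore demonstrate that the
*statistical machinery* behaves as specified, not that any particular real
panel will yield a five-variable HDP.

## Validation problem sizes and numerical choices

The test suite validates each stage against independent brute-force oracles
(explicit rank/Pearson Spearman, normal-equations OLS/WLS, sort-and-average
ranking, a from-scratch UPGMA agglomerator, and the λ→0 LASSO limit against
OLS) on ≤ 10-sample instances, and runs planted-structure recovery at
n_samples = 40 over 20 seeds: block recovery is checked at loading 0.95
(near-collinear stress), sparse-signal recovery (≥ 4/5 planted variables
selected) at the default loading, where the planted variables are not
interchangeable with their block peers. At loading 0.95 LASSO increasingly
substitutes a peer for a planted variable — the same within-branch
interchangeability the clustering stage is designed to expose. The exactness
benchmark for rank prediction is the noiseless single-signal panel, where
the outcome is a monotone image of one variable and the HDP correlation must
be exactly 1.

Tie-breaks and degenerate inputs are handled deterministically throughout:
lowest var_id wins wherever a tie must be broken; constant variables are
errors at the correlation stage (their ρ is undefined); a perfect linear fit
reports a slope standard error of exactly 0; panels below 3 samples refuse
percentile scaling, and dropping to S = 2 warns. Euclidean profile distances
include the self-correlation entry (it contributes 0 after differencing;
stated for bit-reproducibility).

## A worked run

```{r, eval = FALSE}
fx <- make_fixture(seed = 1, dir = tempfile())
cfg <- pipeline_config()
report <- run_full(cfg, matrix = fx$matrix_obj, series = fx$series)
report
report$hdp
```

See the README for the printed output of this exact run and
`scripts/acceptance.R` for the full set of recomputed headline quantities.

## Known limitations

* Nine samples is a very small panel: percentile scaling, CV folds and the
  MLR fit all operate near their degrees-of-freedom floor. The package keeps
  such fits honest by warning rather than refusing, but conclusions from
  S = 9 should lean on the rank-uncertainty sweep, not on a single fit.
* The LASSO's selected set is stable only up to collinearity: within a
  tightly correlated branch, which member is selected can change with the
  fold seed or a single sample. That is a property of sparse selection on
  redundant panels, and exactly why the selection-frequency sweep exists.
* The P statistic depends on the chosen k; comparing P values across
  different cuts is not meaningful.
* Degradation is modelled as linear in time at each temperature; no
  shelf-life extrapolation across temperatures is offered or implied.
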