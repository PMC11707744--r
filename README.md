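# devrank

Rank-based aggregation and sparse prediction for antibody developability
panels.

Early developability screens measure each formulation:mAb sample with a
dozen or more assays — viscosity, SEC/HIC/SMAC retention, DSC thermal
transitions, DLS (R_h and the diffusion interaction parameter kD), AC-SINS,
BVP, particle imaging, extensional-flow stress, in silico liabilities —
producing dozens of scalar variables that are long-tailed, partly redundant
and often conflicting. `devrank` condenses such a panel into two
interpretable outputs and quantifies how robust each one is:

* **ADOS** (Averaged Developability Output Score) — every variable is
  percentile-scaled, `V = (y − Y50) / (Y80 − Y20)`, normalized onto a
  best(0)/worst(1) scale with its favorable direction applied
  (`NV⁺ = 1 − NV` where the largest value is desirable), averaged within
  each cluster branch of assay variables, and summed over branches: a
  distance from the ideal candidate, 0 = best possible, (number of
  branches) = worst.
* **HDP** (Holistic Developability Parameter) — the sparse linear
  combination of tie-average-ranked t = 0 assay variables selected by LASSO
  regression (5-fold CV, 100-point λ grid, λ* = minimum CV error) against a
  ranked manufacturability attribute, typically the absolute monomer-loss
  rate at 25 °C fit by CV-weighted (1/CV²) least squares.

Supporting stages: Spearman correlation + group-average (UPGMA) clustering
of variable correlation profiles; leave-one-sample-out stability (the
pairing P statistic); enumeration of the 2^m rank sets implied by rate
uncertainty and a per-variable LASSO selection-frequency sweep across them;
and a synthetic-panel generator with planted block structure and a planted
sparse signal so every stage is testable end to end.

## Worked example

A complete synthetic study (9 samples = 3 mAbs × 3 buffers, 32 variables,
stability time courses at 5/25/40 °C) and a full pipeline run:

```r
library(devrank)

fx <- make_fixture(seed = 1, dir = tempfile())
report <- run_full(pipeline_config(), matrix = fx$matrix_obj, series = fx$series)
report
#> devrank run report
#>   variable filter chain: 32 -> 28 -> 19
#>   poor clusterers removed: 29, 30, 31, 32
#>   HDP variables: 1, 3, 4, 5, 13, 16, 27 (r = 1.000)
```

The filter chain is the workflow's variable bookkeeping: 32 assay variables,
28 after removing the four difficult-to-cluster variables, 19 after removing
the nine expensive stability-study (Group V) variables so that only rapid
t = 0 assays remain as predictors.

```r
report$ados
#> ADOS (sum over 4 groups): 0 = ideal, lower = better
#>  sample_id    G1     G2     G3      G4  ados rank
#>         A1 0.452 0.4976 0.5696 0.64011 2.160    8
#>         A2 0.531 0.2575 0.6097 0.20894 1.608    2
#>         A3 0.427 0.1837 0.0534 0.21208 0.876    1
#>         B1 0.451 0.5344 0.5692 0.08601 1.641    3
#>         B2 0.387 0.0259 1.0000 0.40782 1.821    6
#>         B3 0.373 0.8707 0.3895 0.69980 2.333    9
#>         C1 0.645 0.1280 0.0896 0.93224 1.795    5
#>         C2 0.470 0.7978 0.1627 0.60212 2.032    7
#>         C3 0.504 0.8016 0.4225 0.00191 1.730    4
```

Each `G*` column is the sample's mean best(0)/worst(1) score within one
cluster branch; `ados` sums them, so A3 (0.876) is closest to ideal and B3
(2.333) furthest. The HDP then predicts the ranked 25 °C monomer-loss rate
from seven selected ranked variables:

```r
report$hdp
#> HDP from 7 selected variable(s): 1, 3, 4, 5, 13, 16, 27
#>      hdp predicted_rank
#> A1 6.927              7
#> ...
#> Pearson r (predicted vs observed ranks) = 1.000
```

At this fixture's noise level the HDP ranks the panel perfectly (r = 1.0);
the selected set contains planted signal variables (5, 27) together with
block peers that can substitute for them at S = 9 — which is exactly what
the rank-uncertainty selection sweep (`selection_sweep()`, 17 LASSO fits)
is there to expose.

A thin command-line front end covering `validate` / `simulate` /
`kinetics` / `run` lives at `inst/cli/devrank.R`.

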