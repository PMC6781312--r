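# blockpath

Multi-block latent-variable path modeling and overlapped design-space
development for multi-unit pharmaceutical manufacturing processes.

## What problem this solves

Pharmaceutical Quality-by-Design development needs to relate what can
be controlled early in a manufacturing line — raw-material lot
selection, granulation settings — to the quality of the finished
product, across *several* unit operations at once. A tablet line is
modeled here as named data blocks sharing the same experimental runs:
material properties **M**, granulation parameters **P1** (combined
into **X1 = [M, P1]**), granule intermediate properties **X2**,
compaction parameters **X3**, and tablet critical quality attributes
**Y** (tensile strength TS in MPa, disintegration time DT in min),
with the path topology **X1 → {X3, Y}**, **X2 → Y**, **X3 → Y**
(**X3** interior).

The package is for process modelers and formulation scientists who
want to:

1. screen blocks with PCA (eigenvalue table, Hotelling T² outlier
   limits) and VIF collinearity diagnostics;
2. fit and compare three latent-variable models of the whole line —
   PLS on concatenated predictors, super-score multi-block PLS
   (MBPLS), and the Wangen–Kowalski multi-block PLS path model
   (MBPLSPM) — with leave-one-out cross-validated Q²;
3. identify critical process units and critical variables with the
   block/variable importance in projection indices

   BIP_i = sqrt( m · Σ_k R²_{Y,k} (wˢ_{i,k})² / Σ_k R²_{Y,k} ),
   VIP_i = sqrt( n · Σ_k R²_{Y,k} (w_{i,k})² / Σ_k R²_{Y,k} ),

   with the threshold-1 criticality convention (Σ BIP² = m,
   Σ VIP² = n);
4. build an overlapped design space: per-CQA response surfaces
   evaluated on a factor grid, masked by the CQA bounds and
   intersected, with bounding ranges and contour exports.

The 52-run D-optimal wet-granulation/compaction design (7 factors,
11 material lots) is packaged verbatim, together with the published
TS/DT response-surface equations. Because the study's raw
measurements are unpublished, a seeded synthetic generator
(`generate_case_study`) reproduces the documented data structure with
known ground truth for recovery experiments.

## Worked example

```r
library(blockpath)

cs <- generate_case_study(generator_config(seed = 1))
X1 <- concat_blocks(list(cs$blocks$M_expanded, cs$blocks$P1),
                    name = "X1")
compare_models(X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, n_lvs = 3)
#>     model n_lvs r2x_cum r2y_cum q2y_cum
#> 1     pls     3    67.0    83.0    75.4
#> 2   mbpls     3    65.1    84.9    80.5
#> 3 mbplspm     3    77.7    83.0    78.2

fit <- fit_mbplspm(X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, 3)
criticality(fit)
#> <diagnostics_report> threshold = 1
#> BIP:
#>    X1    X2    X3
#> 0.529 1.214 1.116
#> critical blocks: X2, X3
#> critical variables: C, D_t, MC, D_10, D_90, F, G
```

Reading the output: the path model (MBPLSPM) explains the most
predictor variance (R²X 77.7% vs 65.1% for MBPLS) at comparable
predictive ability (Q²Y), which is why it is the interpretation model.
Its BIP flags the granule-property and compaction blocks — not the
raw-material/granulation block — as the critical process units, and
VIP flags binder amount (C), lubrication time (F) and minimal punch
tip separation distance (G) among the critical variables, matching the
generator's ground truth.

The design space under the packaged response models:

```r
region <- feasible_region(
  printed_models(),
  list(cqa_spec("TS", lower = 3, upper = 5, units = "MPa"),
       cqa_spec("DT", upper = 5, units = "min")))
region
#> <feasible_region> 23367 of 35301 grid points feasible
#>   binder: [20, 24]
#>   lubrication: [10, 20]
#>   distance: [3.01, 3.2]
```

The bounding ranges are extents of an irregular region, not a box:
`in_region(region, c(binder = 23, lubrication = 20, distance = 3.2))`
is `FALSE` (TS falls below 3 MPa there) while
`(22, 15, 3.15)` is inside.

## Command line

A thin wrapper over the same functions lives in `inst/cli/blockpath.R`:

```sh
Rscript inst/cli/blockpath.R simulate --seed 7 --out sim/
Rscript inst/cli/blockpath.R fit --model mbplspm \
  --x1 sim/M_expanded.csv --x1 sim/P1.csv --x2 sim/X2.csv \
  --x3 sim/X3.csv --y sim/Y.csv --lvs 3 --out fit/
Rscript inst/cli/blockpath.R diagnose --x1 sim/M_expanded.csv \
  --x1 sim/P1.csv --x2 sim/X2.csv --x3 sim/X3.csv --y sim/Y.csv \
  --out diag/
Rscript inst/cli/blockpath.R designspace --out ds/
```

Exit codes: 0 success, 1 computation error, 2 usage error.

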