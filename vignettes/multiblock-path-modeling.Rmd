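---
title: "Multi-block path modeling and design-space development for multi-unit processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block path modeling and design-space development for multi-unit processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockpath)
```

## The modeling problem

A tablet manufacturing line is a chain of unit operations: raw-material
lots are granulated under chosen process settings, the granules are
lubricated and compressed, and the finished tablets are judged by
critical quality attributes (CQAs) such as tensile strength (TS, MPa)
and disintegration time (DT, min). Quality-by-Design development asks
two questions of such a line: *which* unit operations and *which*
material attributes or process parameters drive the CQAs, and *where*
in the space of controllable settings is quality assured (the design
space).

`blockpath` answers both with multi-block latent-variable models. The
data are organized as named blocks sharing the same experimental runs:

* `M` — raw-material (lot) physical properties, measured once per lot
  and expanded to one row per run;
* `P1` — granulation process parameters (the designed factors A–E);
* `X2` — granule intermediate properties;
* `X3` — compaction-stage parameters (lubrication time F, minimal
  punch tip separation distance G);
* `Y` — tablet CQAs.

`M` and `P1` are concatenated into a single predictor block
`X1 = [M, P1]`. The path topology is `X1 -> {X3, Y}`, `X2 -> Y`,
`X3 -> Y`: `X3` is *interior* — it predicts the response and is itself
predicted upstream.

## Models

All blocks are autoscaled (mean-centered, unit sample variance,
`n - 1` denominator — the chemometric convention; every latent-variable
result here is invariant to the denominator choice). The multi-block
fitters additionally divide each autoscaled block by the square root of
its variable count (`block_scaling = "sqrt_nvars"`). This choice was
genuinely open — the literature states "scale each block" without a
formula — and the package default follows the evidence: without block
scaling a 2-variable block's score norm is dominated by 9- and
14-variable blocks, so super-level weights measure block *width* rather
than response relevance, and the compaction block can never be flagged
critical no matter how strongly it drives the response.
`block_scaling = "none"` remains available.

**PLS** (`fit_pls`) extracts score directions `t = X w` maximizing
covariance with the response, deflating `X` by `t p'` and `Y` by the
rank-one prediction per component (NIPALS, deterministic start from the
largest-variance response column).

**MBPLS** (`fit_mbpls`) stacks per-block scores `t_b = X_b w_b` into a
super matrix and extracts a single super score against `Y`; the
super-score variant is used throughout: loadings and deflation use the
super score for every block, `X_b = T_s P_b' + E_b`.

**MBPLSPM** (`fit_mbplspm`) is the Wangen–Kowalski path model for the
fixed topology above. Per latent variable a backward phase computes
predictor-side weights from the current response score (`X2`, `X3`
against `u_Y`; `X1` against the superblock `U = [u_X3, u_Y]`) and a
forward phase recomputes predictee scores (`u_X3` from `t_X1`; `u_Y`
from the superblock `T = [t_X1, t_X2, t_X3]`), iterating until `u_Y`
is stationary. Loadings use the block-score update for `X1` and the
super-score update for `X2` and `X3`; the interior block's residual is
split between its predictor role and its predicted part with factors
`r_X3` and `s_X3` (`r^2 + s^2 = 1`).

### Numerical choices

* **Initialization.** `u_Y`, `u_X3` and `t_X1` start from the
  largest-variance column of their matrix — deterministic and standard
  NIPALS practice.
* **Convergence.** Relative change of `u_Y` below `tol` (default
  `1e-8`), at most 500 alternations per latent variable. When the
  interior path is active the interior score `u_X3` must be stationary
  too: with a one-column response `u_Y` converges instantly while the
  `X1 -> X3` relation is still moving, and stopping there would freeze
  an unconverged interior split.
* **Sign convention.** Per latent variable the largest-magnitude
  element of `w_X1` (or of the concatenated block weights when `X1` is
  absent) is made positive, and every sign-coupled vector is flipped
  together, so all bilinear identities survive and the super-score /
  response-score correlation is reported non-negative.
* **Interior-block deflation.** The published recursion defines the
  `X2` loading from the super score but prints the `X2` residual with
  the block score; the two are inconsistent (the deflation would not be
  an orthogonal projection, block norms could grow, and the exact
  reduction to MBPLS when `X1` is absent would fail). The package
  deflates `X2` by the super score, `E_X2 = X2 - t_T p_X2'`, the form
  the super-score update rule implies.
* **Interior index convention.** The interior-block path coefficients
  select the element of `c_U` and `w_T` *corresponding to `X3`'s
  position* in `U = [u_X3, u_Y]` and `T = [t_X1, t_X2, t_X3]`
  (positions 1 and 3). The printed recursion indexes both as "(1)";
  `wk_index_literal = TRUE` reproduces that literal reading.
* **Degenerate topologies.** `NULL` or zero-width blocks are skipped:
  with `X2` and `X3` absent the model is exactly PLS on `X1`; with
  `X1` absent, `X3` loses its interior role and the model is exactly
  MBPLS on `[X2, X3]`. These reductions are tested to `1e-8`.

## Criticality: BIP and VIP

With per-LV response variance increments `R2_{Y,k}` as weights, block
importance is
`BIP_i = sqrt( m * sum_k R2_k w_{i,k}^2 / sum_k R2_k )` over the
super-level block weights, and variable importance uses the
concatenated per-block variable weights renormalized per LV. Both are
implemented with the square root, so `sum(BIP^2) = m` and
`sum(VIP^2) = n`, which is what makes the threshold-1 criticality
convention meaningful (an "average" block or variable scores exactly
1). The printed index formulas render without a radical;
`squared = TRUE` recovers that literal form. Within-block collinearity
is screened beforehand with `vif()` — ordinary `1/(1 - r^2)` from
regressing each variable on its block peers.

## The synthetic case-study generator

The original study's raw measurements (material, granule and tablet
data) are not published, so the package ships a generator
(`generate_case_study`) that emulates the documented structure with
known ground truth, anchored to what *is* published:

* the 52-run D-optimal design (granulation parameters, compaction
  parameters, lot assignment) is packaged verbatim and used as-is;
* 11 material lots are drawn from two latent factors — a
  filling/dimension factor loading positively on densities and
  particle sizes and negatively on specific surface area, and a
  flowability factor loading on angle of repose, Hausner ratio and
  span;
* granule size/density variables respond positively to binder amount
  and to the lot's filling/dimension factor; granule moisture and
  flow variables carry the flowability factor;
* TS and DT are generated from the published response-surface
  equations evaluated at each run's (binder, lubrication, distance),
  plus a *negative* granule-size perturbation (larger granules compact
  into weaker, faster-disintegrating tablets) and Gaussian noise.

Distributions are Gaussian on latent factors and noise; no
distributional information is published. Default effect sizes and
noise scales were fixed once so that the fitted path model's
three-LV `R2Y` centers near 0.80 (mean 79.3 over 60 seeds, range
0.70–0.89), bracketing the published fit quality; under those defaults
the criticality calls recover the generating structure (critical
blocks exactly `{X2, X3}`, critical variables including binder amount,
lubrication time and punch separation) in ≈98% and 100% of seeded
replicates respectively.

What the generator does **not** emulate: mechanistic granulation
physics, drying/milling effects (held constant in the emulated study),
non-Gaussian lot-to-lot structure, and any real measurement error
correlation. Passing recovery tests therefore show that the estimator
identifies the programmed causal routing at realistic noise — not that
it would do so on any real line.

## Design space

`fit_response_surface` fits CQAs on process factors by OLS over a
small term language (linear, `A*B` interaction, `A^2` quadratic) with
`R^2`, adjusted `R^2` and the overall-F ANOVA p-value (significance
threshold 0.05). The published TS and DT equations are packaged
exactly (`printed_models()`, `evaluate_printed_models()`); DT is in
minutes — the published "< 5 min" target and the model arithmetic,
which yields ≈3–5 at in-range settings, are only mutually consistent
in minutes.

`feasible_region` evaluates each model on a full factorial grid
(defaults 0.1 % binder, 0.5 min lubrication, 0.005 mm distance — fine
enough to resolve the 0.1 mm distance extent of the published region),
masks each CQA's bounds, intersects the masks, and reports the
combined region plus its per-factor bounding ranges. The published
operating ranges are treated as the bounding extents of a region, not
as a box: the region is strictly smaller than its bounding box, and
membership of a specific point should be checked with `in_region`.

```{r design-space}
region <- feasible_region(
  printed_models(),
  list(cqa_spec("TS", lower = 3, upper = 5, units = "MPa"),
       cqa_spec("DT", upper = 5, units = "min")))
region
max(region$predictions[region$mask, "DT"])
```

## A worked run

```{r worked, eval = FALSE}
cs <- generate_case_study(generator_config(seed = 1))
X1 <- concat_blocks(list(cs$blocks$M_expanded, cs$blocks$P1),
                    name = "X1")
compare_models(X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, n_lvs = 3)
fit <- fit_mbplspm(X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, 3)
criticality(fit)
```

Model comparison uses leave-one-out cross-validation (`loo_q2`):
preprocessing statistics are recomputed inside every fold so nothing
leaks from the held-out run; `Q2 = 100 (1 - PRESS/TSS)` with PRESS on
the autoscaled response scale and TSS pooled over centered response
columns. Three latent variables are the working choice for all three
model kinds, matching the emulated study.

## Known limitations

* The path topology is fixed to `{pure predictors} + at most one
  interior block + one predictee`; the general path-model engine for
  arbitrary graphs is out of scope (`path_spec` validates, but the
  fitter implements this topology).
* On data that *violate* the topology (an interior block unrelated to
  its upstream predictor), the interior split deflation can leave a
  few percent of even a noiseless response unexplained; the model
  comparison table makes such mismatch visible.
* `Q2` is not monotone in the number of latent variables and can be
  negative for noise; only `R2` values are monotone.
* VIF is computed strictly within-block; importance indices assume the
  fitted model explains a nonzero share of response variance.
* Problem sizes follow the emulated study throughout (52 runs, 11
  lots, 27 predictor variables); property tests use 20–100 seeded
  replicates at those sizes.
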