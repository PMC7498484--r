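---
title: "Modeling nonlinear covariate effects on brain morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nonlinear covariate effects on brain morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlmorph)
```

## The problem and the model

Morphometric studies relate a per-subject image — gray-matter volume maps,
cortical thickness, any spatially normalized modality — to subject-level
covariates: a disease-staging index, age, sex, genotype dose. The analysis
is *mass-univariate*: every voxel or vertex is modeled independently from
the same covariates, producing statistical maps. Linear models dominate
this field, but many documented effects are nonlinear — atrophy that
accelerates along the disease continuum, aging trajectories with an
inverted-U shape — and a purely linear predictor can be blind to them
(a centered quadratic effect has zero linear component; see the power
analysis in the test suite).

`nlmorph` keeps the familiar confound-correction structure and swaps the
per-location fitter freely. Covariates `X` (L subjects × M covariates) are
split by a contrast matrix `C` (M × P) into a predictor design
`X_P = X C` and a corrector design `X_C = X C₀`, where `C₀ = I − C C⁺`
projects onto the orthogonal complement of the contrast (`C⁺` is the
Moore–Penrose pseudoinverse, computed by SVD with a relative singular
value cutoff of 1e-8). The two subspaces are orthogonal *as subject-space
designs* only when the columns of `X` are orthogonal — hence the optional
preprocessing below. Fitting is two-stage: the corrector model is fitted
to the observations, the predictor model to the corrector residuals, so
any combination of model families is legal at the two stages.

### Why the predictor stage carries its own intercept

A constant column is always prepended to the corrector design, so
corrector residuals have exactly zero mean; the intercept is never counted
in the degrees of freedom. The predictor stage nevertheless fits its own
(equally uncounted) intercept. This is deliberate: without it, a predictor
with nonzero mean (a disease index on \[0, 2\], say) would be projected
*uncentered* onto the residuals, deflating the explained variance by the
squared cosine between the predictor and its centered version. In null
simulations this drove the empirical type-I error of the F-test from the
nominal 0.05 to essentially 0. With the intercept, the predictor stage is
the projection onto the centered predictor, the estimate of the redundant
constant is ~0, and no effective degree of freedom is spent.

### Covariate preprocessing

`preprocess_covariates()` offers `normalize` (unit Euclidean norm per
column), `orthogonalize` and `orthonormalize`. Orthogonalization is a
sequential Gram–Schmidt sweep **in file order** with the implicit
intercept as column zero: every output column is mean-centered and
residualized on all earlier columns. Putting confounders first therefore
lets them absorb shared variance — the order is the user's modeling
choice, not a heuristic. Under orthogonalized covariates the two-stage
procedure reproduces the joint single-model fit exactly (verified to
1e-8 in the tests), and the F-test attains its nominal calibration; with
correlated raw covariates the two-stage statistic is conservative in
proportion to the corrector–predictor correlation, which users should
keep in mind when covariates are strongly collinear.

## The three fitter families

**GLM** (`spec_glm(degrees)`) solves least squares on a raw polynomial
expansion; a degree-d covariate contributes d degrees of freedom. One QR
factorization is shared by all observations.

**GAM** (`spec_gam(smoothers)`) fits an additive model by backfitting:
cyclically, each smoother is refitted to its partial residual, components
are mean-centered each sweep (the additive decomposition is otherwise
only identifiable up to constants), and iteration stops per observation
when the largest component change falls below `tol` (default 1e-6,
`max_iter` 500; non-convergence is a recorded warning, not an error).
Smoothers: `sm_linear()` (df 1), `sm_poly(d)` (df d), `sm_bspline(df)`
and `sm_nspline(df)` (df = basis dimension, knots at covariate quantiles,
natural splines linear beyond the boundary). Each smoother regression
carries a local intercept, which makes the backfitting fixed point equal
the joint least-squares fit on the combined basis; with linear or
polynomial smoothers the GAM is therefore exactly the GLM, a property the
suite asserts to 1e-6.

**ε-SVR** (`spec_svr()`) finds the flattest function in the kernel feature
space with at most ε deviation from the data, `cost` bounding the dual
coefficients. Kernels: RBF `exp(-γ‖u−v‖²)` and polynomial
`(u·v + coef0)^degree`. The quadratic program is solved by libsvm
(\pkg{e1071}) with scaling disabled so the kernel sees the covariates as
given; an independent solver (kernlab) reproduces the fits to 1e-6 in the
tests. Effective degrees of freedom are estimated as the number of
*marginal* support vectors (dual coefficients strictly inside the box),
floored at 1; a kernel-trace estimate is available via
`df_method = "trace"`. Degenerate inputs (constant design or response, or
a tube wider than the data range) collapse to the constant model with
df 1. `grid_search_svr()` samples hyperparameter combinations
(deterministic linear/log grids or random draws, seeded), scores each on
a random subset of observations weighted by inverse observation variance
(background locations are excluded via `sigma_min`), averages over subset
re-draws, and breaks ties toward smaller `cost` then smaller `gamma`;
Mallows's Cp takes its noise variance from the most complex combination
in the space.

### Chunked execution

Observations are processed in contiguous chunks (`chunk_size`). Because a
BLAS matrix–vector product rounds differently from a multi-column
product, all products inside the chunk loops are computed column by
column; chunked results are therefore *bit-identical* for every chunk
size, which the suite checks with `identical()`.

## Inference maps

Per observation: `mse` (the squared residual norm; the per-sample mean is
used where a likelihood requires it), `r2`, `aic` (`2k + L(log(2π·MSE) +
1)` with `k = df_correctors + df_predictors`), and the nested-model
F-test of full vs correctors-only,

    f = ((SS_res − SS_full) / SS_full) · ((L − df_full) / (df_full − df_rest)),

with the p-value from `F(df_full − df_rest, L − df_full)`. The statistic
is clamped at 0 (an SVR predictor stage can in principle increase the
residual). Calibration: ~0.05 type-I error at α = 0.05 over 2000 null
simulations under orthogonalized designs; the denominator df ignores the
(estimated but inert) intercepts, an approximation of order 1/L.

`prss` penalizes the *shape* of the fitted predictor curve rather than
its parameter count: the curve is evaluated on a uniform T-point grid
over the training predictor range (T = 100 by default; the grid size is a
resolution choice, not a model parameter), its second derivative is
estimated by central differences, and `PRSS = MSE + γ ∫ f″(x)² dx`
(trapezoidal rule over the interior grid; γ defaults to 1; an
absolute-value integrand is available). A complex fitter that produces a
straight line pays nothing — the complexity lives in the curve, not the
family. `vnprss` divides by the curve energy about the observation mean
and is `NA` for constant curves. On `f(x) = x²` over \[0, 1\] the
integral is 4 analytically; the discrete estimate at T = 400 is within
1%, which the suite asserts.

`threshold_map()` applies uncorrected (or Bonferroni) p-thresholds with
6-connectivity cluster-extent filtering on volumes — the convention used
with uncorrected mass-univariate maps; no random-field or permutation
correction is attempted.

## Post-hoc analysis

`combine_maps()` implements difference / absolute / squared difference
(2 maps), RGB composites (3 maps, each channel min–max rescaled over the
mask) and the per-voxel best model (argmax/argmin by metric polarity,
ties to the lowest model index). `cluster_curves()` performs average-
linkage agglomeration under the derivative-weighted distance

    SD(x, y) = Σₙ wₙ · d_n(x, y),  n = 0, 1, 2,  w = (0.2, 0.8, 0.2),

where `d_n` is the Euclidean distance between n-fold *unit-step*
differences, normalized by √(T−n) so the orders contribute on a common
per-point scale. Two numerical choices deserve note. First, the discrete
derivative is deliberately **not** divided by the grid spacing: rescaling
by `1/hⁿ` amplifies any unsmoothed pointwise perturbation by `1/h²` in
the second-derivative term (≈2400 on a 100-point grid), and the distance
then measures noise, not shape; unit-step differences keep all orders
commensurate for smooth fitted curves, which are the intended input.
Second, curves are z-scored over the grid by default (`standardize`), so
clusters capture trajectory *shape*; families that differ mainly in
amplitude or sign of curvature should be clustered on raw curves
(`standardize = FALSE`). Merge ties break toward the smallest original
curve indices, making the hierarchy fully deterministic; the merge
sequence is verified against a brute-force linkage oracle and heights
against `stats::hclust`. `cluster_diagnostics()` reports mean silhouette
(singletons contribute 0), within-centroid and between-centroid
dispersion, for choosing the number of clusters — which is always a user
decision, not an automatic selection.

## Imaging input and output

NIfTI volumes are read and written through RNifti; the MGH volume format
and FreeSurfer curvature-style per-vertex files have no reader in the R
ecosystem used here, so `read_image()`/`write_image()` implement those
layouts directly (big-endian binary, gzip wrapping for `.mgz`), with
round-trips covered by tests. All subject images must share geometry;
subjects are matched to covariate rows by file order with an optional id
cross-check, and mismatches are fatal. The default analysis mask keeps
locations with nonzero across-subject variance (`sigma_min = 0`,
strictly); an explicit mask image overrides it. Maps are written back in
the input format with the input affine, zeros outside the mask, 32-bit
floats for continuous maps and 32-bit integers for label maps.

## The synthetic phantom

`generate_phantom()` emulates the structure of a staging-index study: a
disease index uniform on \[0, 2\] (predictor), age uniform on \[45, 75\]
and sex Bernoulli(1/2) as correctors with linear age, quadratic age and
offset effects; three disjoint 3×3×3 regions carry linear (−0.3·x),
quadratic (−0.3·x²) and sigmoid (−0.5/(1+e^{−6(x−1)})) ground-truth
trajectories on a baseline of 1, plus i.i.d. Gaussian noise σ = 0.4.
These defaults were chosen once as a moderate signal-to-noise regime —
strong enough that the degree-2 F-test detects the quadratic region
essentially always at p < 0.001 with L = 80, weak enough that per-voxel
estimates are visibly noisy. The default volume is 16³ with L = 80:
large enough for stable F statistics, small enough that the full pipeline
runs in seconds, which is also the problem size the acceptance script
uses. `generate_curve_set()` produces labeled curve families for
clustering tests (rising line 0.5·x, accelerating decline −0.5·x², steep
sigmoid 3/(1+e^{−6(x−1)}), ±15% parameter jitter); the three archetypes
were chosen to be mutually well separated under SD — a unit-amplitude
sigmoid is nearly indistinguishable from a line of the same mean slope.

What the phantom does **not** emulate: spatial autocorrelation, anatomy,
partial-volume effects, scanner or site effects, non-Gaussian noise.
Passing tests on the phantom therefore validate the estimation and
inference machinery, not robustness to the full messiness of real data;
cluster-extent thresholds calibrated on spatially independent noise are
conservative for smooth real data.

## Pipeline

`run_stage()` drives the staged workflow (`generate-phantom`, `fit`,
`infer`, `compare`, `cluster`, `show-curves`, `show-data-distribution`)
from a YAML/JSON configuration merged over `default_config()`, with
dotted-key overrides. Stages verify prerequisite manifests (naming the
stage to run first), echo the effective configuration, log parameters,
and overwrite only their own artifacts. The model store persists GLM
predictor coefficients as one image per parameter plus a JSON sidecar of
specs and degrees of freedom; families with per-voxel-varying parameter
counts are stored in an internal serialized store that later stages
reload, so inference reruns without refitting. With a fixed seed the
whole pipeline is bit-reproducible (checksummed in the tests); phantom
images are written as uncompressed `.nii` by default since gzip embeds
timestamps that would break checksum comparisons.

## Known limitations

* The two-stage F statistic is conservative under corrector–predictor
  correlation; orthogonalize when calibration matters.
* SVR effective degrees of freedom are an estimate (marginal support
  vector count); AIC/F-test values for SVR models are heuristics, best
  used comparatively across voxels rather than as exact test statistics.
* Curve evaluation sweeps one predictor column (others held at their
  means); multivariate predictor interactions are fitted (SVR) but not
  visualized as surfaces.
* No multiple-comparison control beyond uncorrected thresholds,
  cluster-extent filtering and optional Bonferroni.
* Surface data carry no adjacency here, so extent filtering applies to
  volumes only.
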