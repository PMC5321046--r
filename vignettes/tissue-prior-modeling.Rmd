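---
title: "Spline-based modeling of tissue probability maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spline-based modeling of tissue probability maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmars)
```

## The problem

Spatial normalization and tissue segmentation of brain MRI rely on prior
tissue probability maps (TPMs): per-voxel probabilities for gray matter
(GM), white matter (WM), cerebrospinal fluid (CSF), bone, soft tissue and
background. Priors built from young-adult averages misrepresent children and
elderly subjects. Instead of averaging a matched subgroup, `tpmars` models
each voxel's tissue probability as a function of demographic covariates —
age (months), sex, scanner field strength (1.5 vs 3 T) and a combined
data-quality indicator — and then *generates* priors for any in-range
demographic target. Statistical description removes noise and known
confounds that plain averages blindly absorb.

## The regression model

Per response $y$ (a voxel's probability across subjects, or the global
tissue volume) we fit multivariate adaptive regression splines (MARS):

$$f(X) = \theta_0 + \sum_{m=1}^{M} \theta_m B_m(X),$$

where each basis function $B_m$ is a product of at most two hinge functions
$(x - t)_+$ or $(t - x)_+$ with knot $t$. A greedy **forward pass** adds the
reflected hinge pair (or product with an existing basis function) that most
reduces the residual sum of squares; a **backward pass** deletes one basis
function at a time, keeping the best model of each size and returning the
one minimizing a generalized cross-validation (GCV) score. Binary
predictors (sex, field strength) enter as single linear terms: a hinge on
{0, 1} is affinely equivalent to a linear term, and knot-spacing constraints
would be degenerate there.

### Sample-count constraints and defaults

All tunables live in `fit_constraints()`:

* `max_final_funcs = 8`, `max_initial_funcs = 40` (5 × final): the pruned
  and forward-pass basis-function caps.
* `min_obs_between_knots = 20`, `min_obs_to_edge = 10`: knots must be
  observed predictor values leaving at least these many observations
  (counted with multiplicity on the knot's own variable) strictly between
  knots and between a knot and the data extremes. This stabilizes the fit
  toward the margins of the cohort.
* `penalty = "cv"`: the curvature penalty entering the GCV effective
  parameter count is chosen by 5-fold cross-validation over `0:5` on the
  global series, deterministic given `rng_seed`; ties go to the smallest
  penalty.
* `cubic = TRUE`: after pruning, each hinge is replaced by a C¹
  piecewise-cubic with side knots at the midpoints to the adjacent knots on
  the same variable (data extremes as outer boundaries), and coefficients
  are refit. Outside the side-knot span the cubic piece equals the linear
  hinge exactly; the smooth transition better preserves gradually varying
  age trajectories.
* Cohort screening: a minimum of 20 subjects per 2-year age bracket
  (half-open brackets anchored at 0 months — the simplest deterministic
  convention) is enforced by `age_bracket_filter()`; dataset-specific age
  limits are ordinary options of `load_cohort_table()`, not hard-coded.

The GCV score is $(\mathrm{SSE}/n) / (1 - C/n)^2$ with effective parameters
$C = M + 1 + \lambda \cdot (\#\text{knots})$; linear terms contribute no
knots (no curvature). Only voxels whose cohort-average probability exceeds
10% are fitted.

### The quality indicator

Per-subject voxel resolution, contrast-to-noise and inhomogeneity-to-noise
indicators are z-transformed and summed (`quality_indicator()`), oriented so
larger = better (the resolution z-score is negated: smaller voxels are
better). Constant columns contribute 0 rather than NaN. During prior
generation the quality predictor is pinned at the best available (maximum)
training value, so generated priors represent the best-quality rendition of
the requested demographics.

## The four homogeneity options

Neighboring voxels are not independent; `fit_voxelwise()` offers four levels
of spatial regularization, from conservative to liberal:

1. the pruned global model's basis is frozen; only coefficients are refit
   per voxel;
2. the *unpruned* global basis is the per-voxel candidate set; coefficients
   are refit and backward pruning runs per voxel;
3. a full per-voxel forward + backward fit that inherits the final
   basis-function count and the smallest observed inter-knot sample count
   from the fitted global model;
4. a fully independent per-voxel fit.

Two design choices here are deliberate and load-bearing. First, in option 2
the per-voxel pruning **protects the backbone** — the basis functions the
pruned global model selected. Option 2 is thereby strictly intermediate
between options 1 and 3–4, and the per-voxel explained variance of option 2
is *exactly* ≥ that of option 1 at every voxel (nested bases with refit
coefficients). Without protection, GCV would prune pure-noise voxels to
intercept-only models ($r^2 = 0$) while option 1's refit of a fixed basis
always attains $r^2 > 0$, inverting the intended conservative-to-liberal
ordering at exactly the least informative voxels. Second, options 1 and 2
share one cubic expansion of the unpruned global model (option 1 uses the
backbone columns), so their bases are nested columnwise; converting the
pruned model separately would shift its side knots and break exact nesting.

Degenerate voxels (response variance < 1e−12) get intercept-only models;
out-of-mask voxels carry the cohort mean map so assembled priors stay smooth
at mask edges. Voxel fits are mutually independent, so results do not
depend on traversal order. For options 3–4 the penalty must be numeric or a
fitted global model must be supplied (its cross-validated penalty is
reused); running a 5-fold CV per voxel would be computationally meaningless.

## Prior generation

`predict_priors()` generates one map per requested demographic row and
averages them ("matched pairs"); requests outside any predictor's training
range are hard errors, never extrapolations. `build_priors()` then clips to
[0, 1], applies a 3×3×3 median filter per class (radius configurable;
median filtering avoids the spatial blurring of Gaussian smoothing), and
enforces six-class consistency: background absorbs any per-voxel deficit; if
the five foreground classes already exceed 1, background is set to 0 and the
five are rescaled proportionally (negative probabilities are inadmissible).
Filtering runs before consistency enforcement, so the written priors always
sum to 1 within 1e−6. Covariate-effect overlays
(`covariate_difference_map()`) subtract priors generated at two settings of
one predictor and zero differences below a 5% visualization threshold.

## QC metrics

* `affine_scaling()`: |det| of the 3×3 linear block of the affine matrix —
  the global volume scaling of spatial normalization.
* `nonlinear_volume_change()`: voxelwise |det J| of the total mapping by
  central finite differences (one-sided at volume borders), divided by the
  affine determinant so only non-linear volume change remains, summed and
  averaged over a brain mask. A `"excess"` variant reports |J − 1|.
* `dissimilarity_from_mean()`: per subject, the sum of absolute voxelwise
  differences from the cohort mean image (whole volume by default — masked
  sums are available; structural-similarity indices would be dominated by
  background).
* `neighborhood_inhomogeneity()`: for voxels above 10% probability, the
  mean absolute deviation from the 26 surrounding voxels (truncated
  neighborhoods at volume borders), averaged and reported in percent.
* `glm_baseline()`: the conventional per-voxel OLS with age, age², age³,
  sex, field strength and quality; `moving_average_baseline()`: rank-window
  moving averages (25/50/100 subjects) that visibly blunt developmental
  peaks.
* `lilliefors_normality()`: composite-normality test (delegated to
  `nortest::lillie.test`).
* `compare_to_gold_standard()` / `shrinking_population_curve()`: the
  prior-versus-average protocol — random subgroups of 25/50/100 subjects,
  scored (sum of absolute differences) against the full-population mean,
  versus matched synthetic priors generated from the same subgroups'
  demographics; and the disagreement of 25-subject matched priors as the
  reference population shrinks in steps. All stochastic metrics take
  explicit seeds and echo them in their reports.

## The phantom generator

`generate_cohort()` draws a demographically realistic cohort and builds
six-class probability volumes with known ground truth. The head is a
spherical six-layer object on a 128-mm cube; class memberships are logistic
partitions of unity along the radius, so classes sum to 1 before noise.
Planted effects with distinct spatial signatures: a logistic-rise ×
logistic-fall age trajectory exchanging GM and WM mass at their interface; a
sex offset at the GM/CSF interface; a field-strength offset at the GM/WM
interface ("greatest at tissue boundaries"); Gaussian observation noise with
per-subject σ = `sigma0 · exp(−0.25 · z_quality)`, clamped to [σ₀/4, 4σ₀].
Ages are drawn from a 50/50 mixture of uniform[13, 250] and
uniform[250, 900] months, mirroring the pediatric enrichment of pooled
lifespan cohorts — uniform lifespan sampling would leave childhood
trajectories unresolvable under the 20-subjects-between-knots rule at
desk-scale n.

What the phantom does *not* emulate: real anatomy (no MNI-space heads),
registration residuals, spatially correlated noise, or segmentation
artifacts. Passing tests therefore demonstrate the statistical machinery —
recovery of planted demographic effects, orderings across fitting options,
the advantage of modeling over averaging — not segmentation accuracy on
real images.

## Numerical choices

* Least squares via SVD minimum-norm solves (rank-deficient bases get
  minimum-norm coefficients); per-voxel multi-response fits share one
  decomposition.
* Backward pruning runs on Gram matrices with inverse downdating
  (ΔSSE for deleting regressor j is $\beta_j^2 / [G^{-1}]_{jj}$), so the
  per-voxel cost is quadratic, not cubic, in the basis size; a tiny ridge
  (1e−9 × mean diagonal) guards singular Grams along the greedy path, and
  the finally selected subset is refit exactly.
* Forward-pass tie-breaks: smallest SSE, then lowest variable index, then
  smallest knot, then earliest parent — fully deterministic.
* Candidate knots are observed data values only. When more than
  `knot_thinning` (default 64) values are admissible for one variable at
  one step, an evenly index-spaced subset (keeping both endpoints) is
  searched; this bounds the per-step cost on large cohorts without leaving
  the observed-value lattice.
* The forward pass stops when no admissible candidate improves SSE by more
  than 1e−12 × SST, at the basis cap, or at (numerically) zero residual.
* Mask thresholding is strict (`mean > 0.10`); a cohort-average of exactly
  0.10 is excluded.

## Scales used by the test suite

Validation runs at sizes a laptop handles in minutes, chosen to keep every
property statistically meaningful: engine oracles at n ≤ 12 (exhaustive
search) and n = 500 (hinge recovery); end-to-end trajectory recovery on a
16³ phantom with 400 subjects (recovery RMSE is required below twice the
mean per-observation noise σ̄, the natural error scale of a single voxel
observation); the option-ordering property on 8³ smooth-truth phantoms with
60 subjects averaged over 12 seeds; and the comparison protocol on a 32³
phantom with a 400-subject population and 20 repeats. The smooth-truth,
small-n, low-penalty regime for the ordering test is intentional: it is the
regime where per-voxel fits can actually overfit, which is the phenomenon
the homogeneity ordering describes.

One interaction worth knowing: on coarse grids whose structures are only
1–2 voxels thick, the 3×3×3 median filter erases real shell structure.
The comparison-protocol functions therefore score unfiltered matched-pairs
predictions by default, while `build_priors()` keeps the filter on — at
realistic voxel sizes (≈1–1.5 mm) tissue structures span many voxels and
the filter only removes isolated outliers.

## Known limitations

* No spatial regularization beyond the four options (no hierarchical or
  Markov-random-field coupling across voxels).
* No more than two levels per categorical predictor; no automatic variable
  selection beyond MARS itself.
* Deformation fields are inputs (or synthetic); registration itself is out
  of scope, and affine mismatches between stacks are errors, never silently
  resampled.
* A product basis function may not reuse a variable, and the exact
  curvature-penalty semantics of other MARS implementations may differ from
  the GCV surrogate used here.
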