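---
title: "Methods: gray-matter asymmetry analysis of symptom-defined subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gray-matter asymmetry analysis of symptom-defined subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what its green tests do and do not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis model

### Symptom-dominance subgrouping

Cases carry three interview subscale scores: social (range 0–30), verbal
(0–26), and restricted-repetitive-behavior (0–12). Each score is normalized
by its maximum, `X' = X / X_MAX`, and a case joins the SI, VA, or RRB
subgroup when the corresponding normalized value is the *strict* maximum of
the three; any tie at the maximum excludes the case. Sub-maximal ties do not
exclude. Because the three subscales have different ranges, normalization is
what makes dominance comparable across domains.

*Open choice — which maxima?* "The corresponding maximal values" can mean
instrument maxima or sample maxima. `asymvbm` defaults to instrument maxima
(30, 26, 12), which makes a subject's label independent of who else is in
the sample; sample-maximum normalization is available by passing
`max_scores` explicitly. The same machinery subgroups by any three columns
(e.g. ADOS subscales) — the instrument is a column mapping, not code.

### Matched controls

For each analysis (general, SI, VA, RRB) controls are drawn independently:
greedy pass over the cases, each receiving a uniformly random unused
control with the same site, same gender, and |age difference| ≤ 2 years.
The tolerance is a package default (the protocol names the matching
criteria but no tolerance). Controls may be reused *across* analyses — a
deliberate reading of the protocol's "matched four times" — but never
within one. Cases with no eligible control are reported and dropped from
that analysis.

### Asymmetry index

On a grid whose mid-sagittal plane lies exactly between two voxel columns,
left–right flipping is an index reversal: exact, involutive,
mass-preserving. The symmetric template is the voxel-wise mean of every
volume and every flip (where a registration-based pipeline would build a
symmetric diffeomorphic template; inputs here are assumed already
normalized, so the warp stage is an identity). The right-hemisphere mask is
`world x > 0` ∧ `template ≥ 0.2` (threshold configurable; unspecified
upstream). Then, per subject,

```
AI = ((i1 − i2) / ((i1 + i2) · 0.5)) · i3
```

with i1 the original volume, i2 its flip, i3 the mask: positive AI =
rightward asymmetry, range [−2, 2] for non-negative inputs. Where
`i1 + i2 < 1e-6` the AI is defined as 0 rather than dividing by zero — such
voxels are essentially absent inside a GM-thresholded mask. The AI image
(not the segments) is smoothed with an 8 mm FWHM Gaussian and re-masked;
mask-edge voxels are thereby attenuated toward zero, which we document
rather than renormalize, matching common tooling. Because the left
hemisphere of the AI map is the exact negation of the right, analysis on
one hemisphere loses nothing.

### Voxel-wise GLM

Design columns: intercept, case indicator, centered age, female indicator,
and one indicator per site (full one-hot, following the stated site coding
literally). The full one-hot overlaps the intercept, so the model is fitted
by SVD pseudo-inverse with the effective rank reported; the case–control
contrast is estimable regardless, and `df = n − rank`. Standardized
residuals are kept for smoothness estimation, and the raw case-minus-control
mean AI per voxel for direction reporting. Voxels with numerically zero
residual variance get t = 0 and are counted, not dropped silently.

### Cluster-level random-field inference

The t map is thresholded at the t value whose one-tailed tail probability
is 0.005; positive and negative exceedance sets are labeled separately
(two one-tailed families — the analysis reports "more rightward" and "more
leftward" clusters from one procedure). Default connectivity is 18; 6 and
26 are available. Cluster extents are converted to family-wise corrected
p values with the standard Gaussian-field formulas: expected cluster count
`E[m] = R · (4 ln 2)^{3/2} (2π)^{−2} (u² − 1) e^{−u²/2}` at resel count R
and Gaussianized threshold u, expected suprathreshold volume
`E[N] = S · Φ(−u)`, extent tail `P(k) = exp(−β k^{2/3})` with
`β = (Γ(5/2) E[m]/E[N])^{2/3}`, and corrected
`p = 1 − exp(−E[m] · P(k))`. Clusters with p < 0.05 are reported with
extent, peak world coordinate, peak t, and direction.

Smoothness is estimated from the standardized residuals: per axis, the
variance of one-voxel first differences of the unit-variance field gives
the roughness λ, and `FWHM = sqrt(4 ln 2 / λ)` voxels. The estimator's
white-noise floor is `sqrt(2 ln 2) ≈ 1.18` voxels; estimates under 1.5
voxels are flagged as unresolved. Resels are the mask volume in FWHM³
units.

*Open choices, decided and config-exposed:* two one-tailed families rather
than one two-tailed family; 18-connectivity; Gaussianization of the t field
before applying Gaussian EC densities (t-field EC densities are a known
alternative, left unimplemented). The acceptance suite's null calibration
is the empirical check that this stack of approximations yields a
family-wise error rate inside [0.01, 0.10] at the stated thresholds.

### Brain–behavior and age regressions

The regression unit is the cluster-mean AI (one value per subject per
cluster — the quantity the protocol's scatter plots display), not
voxel-wise small-volume maps. For symptom predictors the covariates are
age, gender, and site; for age they are gender and site. The predictor's t
is converted to a partial correlation `r = t / sqrt(t² + df)` with its
two-sided p; with no covariates this is exactly Pearson's r. Whether the
upstream analysis reported partial or zero-order r is not stated; partial
is implemented and documented. A covariate that duplicates the predictor is
an error, not a silent fit.

## 2. The synthetic world

The generator is a first-class, tested module, not a fixture. Its defaults
*are* the stated cohort: 230 cases and 274 controls over 8 sites of unequal
size (weights patterned on the published per-site counts), ages 7–18
(truncated normal, mean 12.3, sd 2.6 — matching the published per-group
means/sds), ~85% male, subgroup proportions 146:43:41. Cases receive
integer subscale scores rejection-sampled so the intended dominance label
is the strict normalized maximum (ties impossible by construction); a
configurable subset (default 129/230, the published regression n) carries a
symptom score.

Volumes are sums of mirrored Gaussian blobs on a 48×56×48 lattice of 3 mm
voxels (every grid dimension scales). Blob amplitudes are chosen so the
summed template peaks near 0.83 — comfortably below 1, because a saturated
template would censor the additive noise at the [0, 1] clip and distort the
per-voxel error distribution the GLM assumes. Each subject adds:

* **Effects**: spherical regions scaled on one hemisphere. A fractional GM
  change δ yields an expected AI of `2δ/(2+δ)` (the package's analytic
  oracle); the realized multiplier also absorbs an optional per-year drift
  and a between-subject latent sd (default 0.05 AI units, a typical
  inter-subject spread for smoothed AI maps).
* **Site bias**: one smooth field per site (sd 0.005, 20 mm correlation),
  shared by the site's subjects — exactly the nuisance the site covariates
  must absorb.
* **Subject noise**: white Gaussian noise smoothed to 6 mm FWHM and
  rescaled to sd 0.02 (~3% of typical GM amplitude), the spatial-
  correlation structure random-field inference presumes.

Symptom coupling generates the score as `round(11 + 4(bz + e))` clipped to
[0, 22], with z the standardized latent regional AI and
`b = r/sqrt(1 − r²)`, hitting the requested correlation in expectation
(discretization attenuates it by well under 1%).

**What the generator does not emulate** — and hence what a green test does
not establish: real anatomy (blobs, not brains), registration error (the
warp is an identity), non-Gaussian or heavy-tailed noise, scanner-protocol
differences beyond an additive site field, handedness, and any
segmentation step. Published cluster coordinates and t values from real
cohorts are outside what desk-scale synthetic data can or should reproduce;
the acceptance targets are therefore calibration properties (error rate,
power, recovery) plus the published contingency-table statistics, which are
pure arithmetic on printed counts.

## 3. Numerical choices

* **Midline**: even x extent, world x = 0 between columns; flipping is
  index reversal, so involution and mass preservation are bit-exact.
* **Template symmetry**: each blob and its mirror are summed *before*
  accumulation; since floating-point addition is commutative (though not
  associative), this keeps the template bit-exactly flip-invariant for any
  number of blobs.
* **Smoothing**: separable discrete Gaussian, σ = FWHM/(2√(2 ln 2)) per
  axis in voxel units, kernel truncated at 4σ and normalized; replicate
  boundary, so constants are preserved exactly and interior-supported
  images keep their integral.
* **AI denominator guard**: `i1 + i2 < 1e-6` ⇒ AI = 0.
* **Pseudo-inverse**: SVD with tolerance `max(dim) · max(d) · eps`;
  the same routine backs the GLM and the partial correlations.
* **Permutation invariance**: reordering subjects permutes floating-point
  summation order inside BLAS, so the t map is reproduced to 1e-12, not
  bit-exactly; the test asserts the former.
* **Seeds**: every stochastic stage draws through `with_seed`, which
  restores the caller's RNG state; stage seeds are fixed offsets from the
  master seed and recorded in the run manifest with a config hash (output
  path excluded, so identical analyses hash identically wherever written).
* **Null t check**: in-mask t values are spatially correlated by
  construction, so the marginal-distribution test thins the mask to a
  12 mm sublattice (beyond the ~10 mm combined correlation length) before
  a Kolmogorov–Smirnov comparison with t(df).

## 4. Known limitations

* NIfTI support is a deliberately thin shim (float32 write, common scalar
  datatypes and diagonal sforms on read, axis flips to RAS); oblique or
  quaternion-only orientations are rejected loudly. It is cross-validated
  against an independent reader in the test suite.
* GRF cluster p values use Gaussian-field EC densities on a Gaussianized
  t map; at very low df this approximation is cruder than t-field
  densities. The null-calibration acceptance test bounds the practical
  consequence at the df this pipeline actually runs at.
* No permutation inference, FDR, or TFCE; no Jacobian modulation; no
  longitudinal modeling. Cluster-restricted regressions use cluster means,
  not voxel-wise small-volume correction.
* The matched-control step is greedy, not optimal assignment; with sparse
  pools it can leave cases unmatched that a global matcher would pair.
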