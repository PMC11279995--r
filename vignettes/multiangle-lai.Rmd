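---
title: "Multi-angle vegetation indices and angle-stable LAI estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-angle vegetation indices and angle-stable LAI estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opivi)
```

## The problem

A crop canopy is not a Lambertian surface. Viewed in the solar principal
plane (SPP), its reflectance is lowest near the vertical and rises towards
oblique view zenith angles (VZAs), strongly and asymmetrically in the
visible (back-scatter brightening towards the hotspot) and more weakly and
almost symmetrically in the red edge and NIR. Vegetation indices (VIs)
combine band reflectances, so each index inherits its own angular
signature; an index that tracks leaf area index (LAI) well at nadir may
correlate far worse at −60° or +60°. This package quantifies that angle
sensitivity for 16 index formulas — 15 established ones plus OPIVI, the
observation perspective insensitivity vegetation index
`(R720 − R450)/(R660 − R450)` — and estimates LAI from single- and
multi-angle index values.

## Statistics implemented

**Amplitude vs nadir.** For an index profile across VZAs,
`100 · (VI(θ) − VI(0)) / VI(0)`; the −60° and +60° extremes are reported as
the index's amplitudes. Computed on the across-sample mean profile.

**One-way ANOVA.** Per-sample index values grouped by VZA; the F ratio
MS_between/MS_within with (k−1, N−k) degrees of freedom tests whether the
index varies across angles, over all nine VZAs and over the
forward-scatter subset {+30°, +45°, +60°}. Degrees of freedom are always
the true ones implied by the data at hand. When the within-group variance
is exactly zero, F is defined as 0 for equal means and +Inf otherwise.

**Per-angle correlation and DR.** Within a sub-dataset (growth stage,
nitrogen or coverage stratum), the signed Pearson correlation r between an
index and LAI is computed at each VZA; the angular-stability statistic is
`DR = (max r − min r)/mean r`. DR is scale-invariant and zero iff the
profile is flat. A negative mean correlation yields a negative DR; rankings
therefore use mean |DR| (ascending), tie-broken by mean |r| (descending), so
that sign flips can neither rank first nor cancel across sub-datasets.

**Sub-datasets.** The study design varies growth stage, nitrogen (N0–N4 =
0/70/140/210/280 kg/hm²) and coverage (straw SM, film FM, none NM). The
stage strata are unambiguous. For the treatment strata this package holds
the *other* factor at its modal level: "n_rates" = samples at the modal
coverage (nitrogen varies), "overlay_mode" = samples at the modal nitrogen
(coverage varies). This is one defensible reading of treatment-wise
correlation tables; any other stratification can be supplied as an explicit
filter list to `stability_report()`.

## LAI models

Samples are split 70/30 once (`round(0.7 · N)`, round-half-even; 180
samples give exactly 126/54) and the same partition is reused for every
VZA and model so that accuracies are comparable. Metrics are the
conventional `R² = 1 − SSres/SStot` and RMSE, reported for train and test;
headline numbers are the held-out ones.

* **Per-angle linear**: OLS `LAI ~ VI` at one VZA.
* **Random forest**: 500 CART regression trees on bootstrap samples, 3
  candidate features per split (clamped to the feature count with a
  warning), leaf size 5. Implemented in compiled code; randomness flows
  from R's RNG so a seed fixes the fit.
* **Gradient-boosted trees**: squared-loss boosting, depth 5, learning
  rate 0.01, L2 leaf regularization λ = 1 and L1 α = 0 exposed. The number
  of rounds is not pinned by the study settings; the default of 500 rounds
  at learning rate 0.01 fits the training data essentially completely on
  smooth targets while remaining cheap.
* **RBF ε-SVR**: C = 1, ε = 0.1, γ = 1/p on internally standardized
  features. The dual quadratic program (2n variables in [0, C], one
  equality constraint, a 1e−8 diagonal ridge for strict positive
  definiteness) is solved exactly, so the fit is deterministic.

C, ε, α, λ and the round count are not fixed by the study and are exposed
as arguments with the defaults above.

## The synthetic canopy world

The study's field spectra are unreleased, so the package ships a generator
that reproduces the *qualitative* anisotropy and treatment structure, making
every analysis stage testable end-to-end:

```
R(λ, θ) = f(θ, λ) · [(1 − P) · R_veg(λ) + P · R_soil(λ)] · gain · (1 + ε(λ))
P       = exp(−G · LAI / cos θ),  G = 0.5
```

* **Leaf template**: pigment absorption troughs at ~445 nm (deeper) and
  ~670 nm scaled by a nitrogen-driven pigment level `chl_proxy` (at mid
  level R450 ≈ 0.045, R660 ≈ 0.09, R550 ≈ 0.15 — the blue trough sits well
  below the red one, as in real leaves), a sigmoid red edge whose
  inflection migrates 706 → 722 nm with pigment load (the classical
  red-edge shift: the growth signal that is independent of view geometry),
  and an NIR plateau near 0.45.
* **Backgrounds**: linearly brightening soil, scaled by coverage (NM 0.45,
  SM 0.70, FM 0.95). A yellow-petal template exists for flowering canopies
  but contributes nothing by default (below).
* **BRDF multiplier** `f(θ, λ) ≥ 1` with its minimum exactly at nadir: a
  symmetric `(1 − cos θ)` rise whose band profile dips at the absorbing
  blue/red bands (coefficient 0.12), peaks at the green maximum (+0.40) and
  is high on the NIR plateau (0.55); a back-scatter hotspot ramp (amplitude
  0.15, Gaussian width 25° around −60°) applied to the visible block only;
  and a tiny forward gain (0.0003/°). This yields blue/red amplitudes
  within ~40 % of nadir, larger green/NIR amplitudes, visible asymmetry
  (−60° brighter than +60°) and NIR symmetry within 2 % — the observed
  in-plane signatures.
* **Noise**: per-wavelength multiplicative noise (sd 0.02), mostly removed
  again by SG smoothing, *plus* a per-observation gain (sd 0.04): the field
  protocol recalibrates against a reference board at every VZA while the
  sun keeps moving, so every (sample, angle) spectrum carries its own
  radiometric gain of a few percent. This term is the reason a
  scale-invariant difference ratio such as OPIVI is angle-stable in
  practice while formulas with additive constants (SAVI, EVI-1, Vlopt) are
  exposed to it.
* **Design**: `reps` plots per nitrogen × coverage cell and stage
  (reps = 3 reproduces the 45-plot layout), LAI log-normal per
  (stage, nitrogen, coverage) with medians rising N0 → N4
  (budding 1.2 → 2.8, flowering 2.2 → 5.0, sdlog 0.18, ±8 % coverage
  effect), pigment level 0.15 + 0.1625 · rank(N).

With these defaults the simulated world reproduces, at its default seeds:
r(OPIVI, LAI) > 0.6 at all nine VZAs, OPIVI the most angle-stable index by
mean |DR| with NDDA the least stable red-edge index, and a multi-angle
random forest whose held-out accuracy matches or beats the best
single-angle linear model. A green test establishes exactly that — internal
consistency of the pipeline on a world with known truth — and **not** that
the package reproduces field-measured accuracies: headline real-data
numbers cannot be recovered from synthetic data.

### Choices that were genuinely open

* **Grid**: inputs are resampled to 1 nm over 350–1300 nm because the index
  formulas distinguish 1 nm-adjacent bands (R680 vs R681). SG window
  defaults to 15 points (not stated by the study); order 2 is the stated
  quadratic.
* **Replicates**: duplicated (sample, VZA, wavelength) rows are treated as
  replicate scans and averaged on read (the field protocol averaged three
  scans per angle); strict rejection is available via `replicates =
  "error"`. Averaging precedes smoothing.
* **CCII** is the ratio TCARI/OSAVI whose components the source table never
  defines; the literature-standard TCARI
  `3[(R700 − R670) − 0.2(R700 − R550)(R700/R670)]` and OSAVI
  `1.16(R800 − R670)/(R800 + R670 + 0.16)` are adopted as an external
  assumption.
* **Vlopt** is implemented exactly as printed, `(1 + 0.45)(R800² + 1)/(R670
  + 0.45)`; because the squared term is a suspected typo, `vi_registry
  (vlopt_variant = "r800_linear")` switches to the linear form.
* **mND705 / EVI-1** use R445 and R470 as printed even though the narrative
  features 450 nm bands: formulas are authoritative over prose.
* **RI-dB** is the printed plain ratio R735/R720; no decibel log transform
  is applied.
* **Undefined cells**: any denominator within 1e−12 of zero raises an
  undefined-index error in scalar use and becomes a counted `NA` in table
  use; NaN is never propagated silently.
* **OPIVI's λ1 screen**: only the final published choice λ1 = 720 nm is
  implemented; the screening over 700–760 nm is not reproduced because the
  procedure is unspecified.

### Known limitations

* The generator is a two-component turbid medium with a multiplicative
  BRDF kernel — no radiative-transfer coupling (PROSAIL), no row/ridge
  geometry, no within-session solar movement. Because Pearson r at a fixed
  angle is invariant to any common multiplier, the BRDF kernel affects
  index *values* but influences correlation profiles only through the
  nonlinear gap-fraction mixing; angular r-stability contrasts between
  indices are therefore driven by formula structure (scale invariance,
  additive constants, small-difference denominators) and measurement gain,
  which is a narrower mechanism set than a real canopy offers.
* The petal mechanism that degrades red-band indices at flowering in real
  rapeseed cannot be active by default: with a bright petal admixture even
  at a few percent, OPIVI's small `R660 − R450` denominator is overwhelmed
  and its LAI relation collapses — contrary to the strong flowering
  correlations the generator must emulate. It is available explicitly via
  `canopy_scenario(flower_fraction = ...)`.
* The ranking "OPIVI first" is a stochastic property of the default world:
  across probe seeds it holds in the large majority of draws (6/7 probed),
  with occasional photo-finish losses to EVI-1 (e.g. mean |DR| 0.099 vs
  0.098 at one seed).
* Extinction G is fixed at 0.5 (spherical leaf-angle distribution). A
  per-plot architecture spread is supported through
  `canopy_scenario(g_extinction = ...)` but is not part of the default
  world.
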