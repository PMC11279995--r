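# opivi — multi-angle vegetation indices and angle-stable LAI estimation

Canopy reflectance measured off-nadir is not the same as at nadir: in the
solar principal plane, visible bands brighten markedly towards the
back-scatter (hotspot) side while red-edge/NIR bands vary almost
symmetrically, with the minimum near the vertical view. Any vegetation index
(VI) built from those bands therefore inherits some sensitivity to the view
zenith angle (VZA), which corrupts leaf area index (LAI) monitoring from
goniometers, drones and satellites observing at varying geometry.

`opivi` implements the analysis toolkit for this problem, for crop
spectroscopists and phenotyping researchers:

* **Spectral core** — reflectance spectra on a uniform 1 nm grid over
  350–1300 nm, Savitzky–Golay smoothing (window 15, quadratic), point-band
  sampling, long-format CSV I/O with replicate averaging and percent
  auto-detection.
* **Index registry** — the 16 validated index formulas (PRI, RI-dB, SAVI,
  NDRE, DVI, Vlopt, mND705, NDDA, MTCI, EVI-1, DDn, VOG-2, DD, REP, CCII)
  including the *observation perspective insensitivity vegetation index*

  ```
  OPIVI = (R720 − R450) / (R660 − R450)
  ```

  a difference ratio of red-edge, red and blue bands. Being invariant under
  any affine transform `R → aR + b` of the spectrum, OPIVI cancels
  per-measurement gain errors that indices with additive constants (SAVI,
  EVI-1) cannot.
* **Angular analysis** — percent change vs nadir `100·(VI(θ) − VI(0))/VI(0)`,
  one-way ANOVA F across VZAs, per-angle Pearson correlation with LAI, and
  the angular-stability statistic

  ```
  DR = (r_max − r_min) / r_mean
  ```

  over a nine-angle correlation profile (smaller = more angle-stable).
* **LAI models** — deterministic 70/30 sample split (180 → 126/54),
  per-angle univariate OLS, and multi-angle regressors with the study
  settings: random forest (500 trees, mtry 3), gradient-boosted trees
  (depth 5, learning rate 0.01) and RBF ε-SVR (C = 1, ε = 0.1), evaluated by
  R² and RMSE on the held-out set. The tree ensembles are compiled (Rcpp);
  the SVR dual is solved exactly with `quadprog`.
* **Synthetic canopy generator** — a 5-nitrogen × 3-coverage × 2-stage
  factorial (45 plots per stage) observed at VZAs −60°…+60° in 15° steps:
  leaf templates with pigment-driven troughs and red-edge shift,
  soil/mulch backgrounds, Beer–Lambert gap fraction
  `P = exp(−0.5·LAI/cosθ)`, a kernel-style BRDF multiplier with nadir
  minimum, visible hotspot asymmetry and near-symmetric NIR, plus
  per-wavelength noise and per-observation calibration gain drift.

## Worked example

```r
library(opivi)

ds  <- smooth_dataset(simulate_dataset(reps = 3, seed = 1))  # 90 samples x 9 VZAs
vt  <- compute_index_table(ds)                               # 90*9*16 index cells
rep <- stability_report(vt, ds$metadata)
head(rep$ranking, 5)
#>   index mean_abs_dr mean_abs_r rank
#> 1 OPIVI  0.08862133  0.8949997    1
#> 2  SAVI  0.09301865  0.9091973    2
#> 3 Vlopt  0.11254561  0.9031200    3
#> 4 EVI-1  0.11558063  0.8982986    4
#> 5   DVI  0.13806911  0.8900765    5
```

OPIVI ranks most angle-stable (smallest mean |DR| across the stage,
nitrogen and coverage sub-datasets) while keeping a high correlation with
LAI. Its nine-angle correlation profile and DR:

```r
r <- correlation_by_angle(vt, ds$metadata, "OPIVI")
round(setNames(r$r, r$vza_deg), 2)
#>  -60  -45  -30  -15    0   15   30   45   60
#> 0.75 0.84 0.87 0.87 0.87 0.87 0.86 0.83 0.74
dr_statistic(r$r)
#> [1] 0.1669
```

Multi-angle machine-learning estimation from OPIVI at the three best
angles, against the best single-angle linear model:

```r
fit_multiangle(vt, ds$metadata, "OPIVI", c(-30, -15, 0), "rf",
               split_spec(0.7, 1), seed = 1)
#> <fit_result> rf on OPIVI @ VZA {-30, -15, 0}
#>   train R^2 = 0.844, RMSE = 0.490 | test R^2 = 0.791, RMSE = 0.603 cm^2/cm^2

fit_linear_per_angle(vt, ds$metadata, "OPIVI", -15, split_spec(0.7, 1))
#> <fit_result> linear on OPIVI @ VZA {-15}
#>   train R^2 = 0.708, RMSE = 0.671 | test R^2 = 0.875, RMSE = 0.466 cm^2/cm^2
```

(Numbers are from this exact seed; the generator is fully deterministic
given `seed`.)

## Command line

```sh
Rscript inst/cli/opivi-cli.R simulate --reps 3 --noise 0.02 --seed 7 \
    --out spectra.csv --meta meta.csv
Rscript inst/cli/opivi-cli.R indices --in spectra.csv --meta meta.csv \
    --names OPIVI,NDRE,EVI-1 --out vitable.csv
Rscript inst/cli/opivi-cli.R stability --vitable vitable.csv --meta meta.csv --out report/
Rscript inst/cli/opivi-cli.R fit --vitable vitable.csv --meta meta.csv \
    --index OPIVI --angles -30,-15,0 --model rf --seed 7 --out fit.json
Rscript inst/cli/opivi-cli.R run --out study/ --seed 7
```

Exit codes: 0 success, 2 config error, 3 data error.

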