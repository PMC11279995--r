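# Synthetic multi-angle canopy reflectance with known LAI.
#
# The generator is a turbid-medium two-component mixture with a kernel-style
# multiplicative BRDF factor:
#
#   R(lambda, theta) = f(theta, lambda) *
#                      [(1 - P) R_leaf(lambda) + P R_soil(lambda)] * (1 + e)
#
# with gap fraction P = exp(-G * LAI / cos theta), G = 0.5 (spherical leaf
# angle distribution), and e ~ N(0, noise_sd) drawn per wavelength. The BRDF
# multiplier f has its minimum exactly at nadir, a symmetric rise towards
# oblique angles (larger in the NIR than in the visible), a back-scatter
# hotspot ramp applied to the visible bands only, and a small forward gain --
# reproducing the qualitative anisotropy of an in-principal-plane goniometer
# measurement of a crop canopy: visible bands asymmetric (back-scatter
# brighter), red edge / NIR nearly symmetric, nadir minimum.

#' BRDF multiplier parameters
#'
#' Defaults are set once from the angular signatures the generator must
#' emulate (see the methods vignette): visible-band amplitudes within ~40%
#' of nadir with a clear back-/forward asymmetry, green/NIR amplitudes up to
#' ~120%, NIR back/forward symmetric within 2%.
#'
#' @param hotspot_amp back-scatter brightening amplitude (visible bands).
#' @param hotspot_width Gaussian width (degrees) of the hotspot ramp around
#'   the -60 deg extreme.
#' @param forward_slope small forward-scatter gain per degree.
#' @param band_asymmetry multiplier on the visible-band hotspot term.
#' @param noise_sd per-wavelength multiplicative noise standard deviation
#'   (detector/spectral noise; largely removed again by SG smoothing).
#' @param gain_sd per-observation multiplicative gain error standard
#'   deviation: each (sample, VZA) spectrum is scaled by one `1 + N(0,
#'   gain_sd)` draw, emulating reference-board recalibration between angle
#'   positions. Under clear skies the sun still moves several degrees over a
#'   nine-angle sequence, so between-calibration illumination drift of a few
#'   percent is the dominant radiometric error; the default is 4 percent.
#'   A common gain cancels exactly in scale-invariant indices (OPIVI, the
#'   normalized differences) but not in formulas with additive constants
#'   (SAVI, EVI-1, Vlopt).
#' @param sym_amp_vis,sym_amp_nir symmetric (angle-only) amplitude
#'   coefficients for the absorbing visible bands (blue/red troughs) and for
#'   the NIR plateau.
#' @param green_amp extra symmetric amplitude at the 550 nm green peak,
#'   where pigment absorption is weak and multiple scattering makes the
#'   angular signal strong.
#' @return object of class `"brdf_params"`.
#' @export
brdf_params <- function(hotspot_amp = 0.15, hotspot_width = 25,
                        forward_slope = 0.0003, band_asymmetry = 1,
                        noise_sd = 0.02, gain_sd = 0.04, sym_amp_vis = 0.12,
                        sym_amp_nir = 0.55, green_amp = 0.40) {
  stopifnot(hotspot_amp >= 0, hotspot_width > 0, forward_slope >= 0,
            band_asymmetry >= 0, noise_sd >= 0, gain_sd >= 0,
            sym_amp_vis >= 0, sym_amp_nir >= 0, green_amp >= 0)
  structure(list(hotspot_amp = hotspot_amp, hotspot_width = hotspot_width,
                 forward_slope = forward_slope,
                 band_asymmetry = band_asymmetry, noise_sd = noise_sd,
                 gain_sd = gain_sd, sym_amp_vis = sym_amp_vis,
                 sym_amp_nir = sym_amp_nir, green_amp = green_amp),
            class = "brdf_params")
}

#' Canopy scenario
#'
#' One plot-level state: its leaf area index, a relative pigment level
#' driven by the nitrogen treatment, a relative soil/mulch brightness driven
#' by the coverage method, and the growth stage.
#'
#' @param lai leaf area index, cm^2 per cm^2, > 0.
#' @param chl_proxy relative pigment level in `[0, 1]`.
#' @param soil_brightness relative background brightness in `[0, 1]`.
#' @param stage `"budding"` or `"flowering"`.
#' @param flower_fraction fraction of the vegetation signal contributed by
#'   yellow petals in `[0, 1]`; 0 outside flowering. Petal pigment perturbs
#'   the green-to-red reflectance independently of LAI, which is what makes
#'   red-band indices stage-sensitive.
#' @param g_extinction extinction coefficient of the plot's canopy
#'   (mean 0.5 = spherical leaf-angle distribution); plot-level spread
#'   represents architecture differences between plots and mulching methods.
#' @return object of class `"canopy_scenario"`.
#' @export
canopy_scenario <- function(lai, chl_proxy = 0.5, soil_brightness = 0.5,
                            stage = "budding", flower_fraction = 0,
                            g_extinction = 0.5) {
  if (!is.finite(lai) || lai <= 0) {
    opivi_error("lai must be finite and > 0.", "opivi_bad_scenario")
  }
  if (chl_proxy < 0 || chl_proxy > 1) {
    opivi_error("chl_proxy must lie in [0, 1].", "opivi_bad_scenario")
  }
  if (soil_brightness < 0 || soil_brightness > 1) {
    opivi_error("soil_brightness must lie in [0, 1].", "opivi_bad_scenario")
  }
  if (flower_fraction < 0 || flower_fraction > 1) {
    opivi_error("flower_fraction must lie in [0, 1].", "opivi_bad_scenario")
  }
  stage <- match.arg(stage, valid_stages)
  if (!is.finite(g_extinction) || g_extinction <= 0 || g_extinction >= 1) {
    opivi_error("g_extinction must lie in (0, 1).", "opivi_bad_scenario")
  }
  structure(list(lai = lai, chl_proxy = chl_proxy,
                 soil_brightness = soil_brightness, stage = stage,
                 flower_fraction = flower_fraction,
                 g_extinction = g_extinction),
            class = "canopy_scenario")
}

#' Petal reflectance template
#'
#' Yellow oilseed-rape petals: dark in the blue, brightening steeply through
#' the green into the red, bright NIR.
#'
#' @param grid wavelength grid (nm).
#' @return a [spectrum()].
#' @export
flower_template <- function(grid = working_grid()) {
  spectrum(grid, 0.08 + 0.47 / (1 + exp(-(grid - 560) / 45)))
}

# weight = 1 through the visible and the lower red edge (<= 725 nm), 0 in
# the NIR (>= 745 nm), linear ramp across the top of the red edge. The
# plateau up to 725 nm keeps the angular multiplier flat across the blue,
# red and lower red-edge bands (the anisotropy contrast sits between the
# visible block and the NIR block, as in in-plane goniometer measurements).
visible_weight <- function(wl) {
  pmin(1, pmax(0, (745 - wl) / 20))
}

#' Leaf-level reflectance template
#'
#' Piecewise-smooth green-vegetation reflectance on the working grid:
#' pigment absorption troughs in the blue (~445 nm) and red (~670 nm) that
#' deepen with `chl_proxy`, a green peak fixed near 550 nm, a sigmoid red
#' edge centred near 716 nm, and an NIR plateau near 0.45 with a weak water
#' feature near 975 nm.
#'
#' @param chl_proxy relative pigment level in `[0, 1]`.
#' @param grid wavelength grid (nm).
#' @return a [spectrum()].
#' @export
leaf_template <- function(chl_proxy, grid = working_grid()) {
  if (!is.finite(chl_proxy) || chl_proxy < 0 || chl_proxy > 1) {
    opivi_error("chl_proxy must lie in [0, 1].", "opivi_bad_scenario")
  }
  # blue absorbs more strongly than red (chlorophyll + carotenoids), so the
  # blue trough sits well below the red trough: at mid pigment level
  # R450 ~ 0.045, R660 ~ 0.09, R550 ~ 0.15 (typical green-leaf values)
  k <- 1.25 * exp(-(grid - 445)^2 / (2 * 35^2)) +
    0.44 * exp(-(grid - 670)^2 / (2 * 30^2)) + 0.4
  cfac <- 0.6 + 2.2 * chl_proxy
  r_vis <- 0.03 + 0.25 * exp(-k * cfac)
  # red-edge inflection migrates to longer wavelengths as pigment load grows
  # (the classical red-edge shift), carrying growth information that is
  # independent of view geometry
  s <- 1 / (1 + exp(-(grid - (706 + 16 * chl_proxy)) / 9))
  r_nir <- 0.45 * (1 - 0.03 * exp(-(grid - 975)^2 / (2 * 30^2)))
  spectrum(grid, r_vis * (1 - s) + r_nir * s)
}

#' Soil/mulch background reflectance template
#'
#' Linearly brightening background typical of dry soil; `brightness` moves
#' the whole curve (dark bare soil -> bright film mulch).
#'
#' @param brightness relative level in `[0, 1]`.
#' @param grid wavelength grid (nm).
#' @return a [spectrum()].
#' @export
soil_template <- function(brightness = 0.5, grid = working_grid()) {
  if (brightness < 0 || brightness > 1) {
    opivi_error("brightness must lie in [0, 1].", "opivi_bad_scenario")
  }
  base <- 0.10 + 0.18 * (grid - 350) / 950
  spectrum(grid, base * (0.5 + brightness))
}

# BRDF multiplier f(theta, lambda): >= 1 everywhere, minimum exactly at nadir
brdf_multiplier <- function(vza_deg, wl, brdf) {
  symf <- (1 - cos(vza_deg * pi / 180)) / (1 - cos(60 * pi / 180))
  w <- visible_weight(wl)
  # angular sensitivity dips at the absorbing blue/red bands, peaks at the
  # green reflectance maximum and on the NIR plateau
  a_sym <- brdf$sym_amp_nir + (brdf$sym_amp_vis - brdf$sym_amp_nir) * w +
    brdf$green_amp * exp(-(wl - 550)^2 / (2 * 45^2))
  hot <- if (vza_deg < 0) {
    brdf$hotspot_amp * (abs(vza_deg) / 60) *
      exp(-(abs(vza_deg) - 60)^2 / (2 * brdf$hotspot_width^2))
  } else 0
  1 + a_sym * symf + brdf$forward_slope * max(vza_deg, 0) +
    hot * brdf$band_asymmetry * w
}

#' Gap fraction of a turbid-medium canopy
#'
#' `P = exp(-G * LAI / cos(theta))` with extinction coefficient `G = 0.5`
#' (spherical leaf-angle distribution); the probability that a view ray at
#' zenith angle theta passes through the canopy to the background.
#'
#' @param lai leaf area index (> 0 or 0).
#' @param vza_deg view zenith angle, |theta| < 90.
#' @param g extinction coefficient (default 0.5).
#' @return gap fraction in (0, 1].
#' @export
gap_fraction <- function(lai, vza_deg, g = 0.5) {
  if (any(abs(vza_deg) >= 90)) {
    opivi_error("|VZA| must be below 90 degrees.", "opivi_bad_vza")
  }
  exp(-g * lai / cos(vza_deg * pi / 180))
}

#' Simulated canopy reflectance at one view zenith angle
#'
#' @param scenario a [canopy_scenario()].
#' @param vza_deg signed view zenith angle, |theta| < 90.
#' @param brdf a [brdf_params()].
#' @param seed optional seed for the multiplicative noise.
#' @param noise logical; `FALSE` gives the noise-free closed form (a pure
#'   function of scenario, angle and parameters).
#' @param grid wavelength grid (nm).
#' @return a [spectrum()].
#' @export
canopy_reflectance <- function(scenario, vza_deg, brdf = brdf_params(),
                               seed = NULL, noise = TRUE,
                               grid = working_grid()) {
  stopifnot(inherits(scenario, "canopy_scenario"))
  if (abs(vza_deg) >= 90) {
    opivi_error("|VZA| must be below 90 degrees.", "opivi_bad_vza")
  }
  leaf <- leaf_template(scenario$chl_proxy, grid)$reflectance
  ff <- scenario$flower_fraction
  if (ff > 0) {
    leaf <- (1 - ff) * leaf + ff * flower_template(grid)$reflectance
  }
  soil <- soil_template(scenario$soil_brightness, grid)$reflectance
  p_gap <- gap_fraction(scenario$lai, vza_deg, g = scenario$g_extinction)
  f <- brdf_multiplier(vza_deg, grid, brdf)
  r <- f * ((1 - p_gap) * leaf + p_gap * soil)
  if (noise && (brdf$noise_sd > 0 || brdf$gain_sd > 0)) {
    r <- with_seed(seed, {
      gain <- 1 + stats::rnorm(1, 0, brdf$gain_sd)
      eps <- stats::rnorm(length(grid), 0, brdf$noise_sd)
      r * gain * (1 + eps)
    })
  }
  r[r < 0] <- 0
  spectrum(grid, r)
}

# treatment-driven latent levels
chl_from_nitrogen <- function(nitrogen) {
  rank <- match(nitrogen, valid_nitrogen) - 1L
  0.15 + 0.1625 * rank
}

soil_from_coverage <- function(coverage) {
  c(SM = 0.70, FM = 0.95, NM = 0.45)[coverage]
}

# log-normal LAI distributions: medians rise with nitrogen, flowering above
# budding, small coverage effect
lai_median <- function(stage, nitrogen, coverage) {
  rank <- match(nitrogen, valid_nitrogen) - 1L
  base <- if (stage == "flowering") 2.2 + 0.7 * rank else 1.2 + 0.4 * rank
  mult <- c(SM = 1.00, FM = 1.08, NM = 0.92)[coverage]
  unname(base * mult)
}

#' Simulate a full multi-angle factorial dataset
#'
#' Emulates the 5-nitrogen x 3-coverage plot design measured at nine VZAs in
#' the solar principal plane: `reps` replicate plots per treatment and stage,
#' LAI drawn log-normally per (stage, nitrogen, coverage) cell with medians
#' rising N0 -> N4 and flowering > budding (sdlog 0.18), pigment level tied
#' to nitrogen, background brightness tied to coverage.
#'
#' @param reps replicate plots per treatment combination (default 3, i.e.
#'   45 plots per stage).
#' @param stages growth stages to include.
#' @param vzas view zenith angles (non-empty).
#' @param brdf a [brdf_params()].
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param grid wavelength grid (nm).
#' @details The default world contains no petal signal (`flower_fraction`
#'   stays 0): in a two-component leaf/soil mixture even a few percent of
#'   bright-red petal admixture overwhelms the small `R660 - R450`
#'   denominator of OPIVI and severs its LAI relation, which contradicts the
#'   strong flowering-stage correlations the generator must emulate. The
#'   petal mechanism remains available through [canopy_scenario()].
#' @return a `multiangle_dataset` with `reps * 15 * length(stages)` samples.
#' @export
simulate_dataset <- function(reps = 3L, stages = c("budding", "flowering"),
                             vzas = default_vzas(), brdf = brdf_params(),
                             seed = 1L, grid = working_grid()) {
  if (length(vzas) == 0L) {
    opivi_error("vzas must be non-empty.", "opivi_bad_vza")
  }
  reps <- as.integer(reps)
  if (reps < 1L) opivi_error("reps must be >= 1.", "opivi_bad_scenario")
  stages <- match.arg(stages, valid_stages, several.ok = TRUE)

  design <- expand.grid(rep = seq_len(reps), coverage = valid_coverage,
                        nitrogen = valid_nitrogen, stage = stages,
                        stringsAsFactors = FALSE)
  n_samp <- nrow(design)
  design$sample_id <- sprintf("S%04d", seq_len(n_samp))

  with_seed(seed, {
    sdlog <- 0.18
    design$lai <- stats::rlnorm(
      n_samp,
      meanlog = log(mapply(lai_median, design$stage, design$nitrogen,
                           design$coverage)),
      sdlog = sdlog)
    design$flower_fraction <- 0
    design$g_extinction <- 0.5  # spherical leaf-angle distribution
    metadata <- design[, c("sample_id", "stage", "nitrogen", "coverage",
                           "lai")]
    obs <- expand.grid(vza_deg = vzas, sample_id = design$sample_id,
                       stringsAsFactors = FALSE)[, c("sample_id", "vza_deg")]
    mat <- matrix(NA_real_, nrow(obs), length(grid))
    for (i in seq_len(nrow(obs))) {
      d <- design[match(obs$sample_id[i], design$sample_id), ]
      sc <- canopy_scenario(d$lai, chl_from_nitrogen(d$nitrogen),
                            soil_from_coverage(d$coverage), d$stage,
                            d$flower_fraction, d$g_extinction)
      mat[i, ] <- canopy_reflectance(sc, obs$vza_deg[i], brdf, seed = NULL,
                                     noise = TRUE, grid = grid)$reflectance
    }
    new_multiangle_dataset(grid, mat, obs, validate_metadata(metadata))
  })
}
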