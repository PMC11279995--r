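test_that("leaf template has the green-vegetation shape at every pigment
           level", {
  for (chl in seq(0, 1, by = 0.1)) {
    sp <- leaf_template(chl)
    R <- function(wl) band_reflectance(sp, wl)
    expect_gt(R(550), R(450))
    expect_gt(R(550), R(660))
    expect_true(R(700) < R(720) && R(720) < R(740) && R(740) < R(780))
  }
  # red trough deepens with pigment level
  r660 <- vapply(seq(0, 1, by = 0.25),
                 function(c) band_reflectance(leaf_template(c), 660), 0)
  expect_true(all(diff(r660) < 0))
  expect_error(leaf_template(1.2), class = "opivi_bad_scenario")
})

test_that("gap fraction is in (0, 1], decreasing in LAI and in 1/cos(theta)", {
  lais <- c(0.3, 1, 2, 4, 8)
  p <- gap_fraction(lais, 0)
  expect_true(all(p > 0 & p <= 1))
  expect_true(all(diff(p) < 0))
  angles <- c(0, 15, 30, 45, 60)
  pa <- vapply(angles, function(a) gap_fraction(2, a), 0)
  expect_true(all(diff(pa) < 0))
  expect_error(gap_fraction(2, 90), class = "opivi_bad_vza")
})

test_that("BRDF multiplier: nadir minimum, visible asymmetry, NIR
           near-symmetry", {
  brdf <- brdf_params()
  f <- function(a, wl) opivi:::brdf_multiplier(a, wl, brdf)
  for (wl in c(450, 550, 660, 780, 870)) {
    vals <- vapply(default_vzas(), f, 0, wl = wl)
    expect_true(all(vals >= 1))
    expect_equal(which.min(vals), which(default_vzas() == 0))
  }
  for (wl in c(450, 550, 660)) expect_gt(f(-60, wl), f(60, wl))
  for (wl in c(780, 870, 1100)) {
    expect_lte(abs(f(-60, wl) - f(60, wl)) / f(60, wl), 0.02)
  }
})

test_that("canopy_reflectance limits: bare soil, closed canopy, LAI
           monotonicity", {
  brdf <- brdf_params(noise_sd = 0)
  soil <- soil_template(0.6)
  for (a in c(-45, 0, 30)) {
    sc <- canopy_scenario(1e-9, 0.5, 0.6)
    r <- canopy_reflectance(sc, a, brdf, noise = FALSE)
    f <- opivi:::brdf_multiplier(a, soil$wavelength_nm, brdf)
    expect_equal(r$reflectance, f * soil$reflectance, tolerance = 1e-6)
  }
  # closed canopy at nadir: within 1% of the pure leaf-derived value
  dense <- canopy_reflectance(canopy_scenario(50, 0.5, 0.6), 0, brdf,
                              noise = FALSE)
  leaf <- leaf_template(0.5)
  expect_equal(dense$reflectance[leaf$reflectance > 0.01],
               leaf$reflectance[leaf$reflectance > 0.01],
               tolerance = 0.01)
  # NIR reflectance at nadir strictly increasing in LAI
  r780 <- vapply(seq(0.5, 6, by = 0.5), function(l) {
    band_reflectance(canopy_reflectance(canopy_scenario(l, 0.5, 0.6), 0,
                                        brdf, noise = FALSE), 780)
  }, 0)
  expect_true(all(diff(r780) > 0))
  expect_error(canopy_reflectance(canopy_scenario(2), 95, brdf),
               class = "opivi_bad_vza")
})

test_that("noise-free generation is a pure function; seeded noise is
           reproducible", {
  brdf0 <- brdf_params(noise_sd = 0, gain_sd = 0)
  sc <- canopy_scenario(2.5, 0.7, 0.5)
  expect_identical(canopy_reflectance(sc, -30, brdf0)$reflectance,
                   canopy_reflectance(sc, -30, brdf0)$reflectance)
  brdf <- brdf_params(noise_sd = 0.02)
  expect_identical(canopy_reflectance(sc, -30, brdf, seed = 4)$reflectance,
                   canopy_reflectance(sc, -30, brdf, seed = 4)$reflectance)
})

test_that("petal template and scenario extensions validate", {
  fl <- flower_template()
  R <- function(wl) band_reflectance(fl, wl)
  expect_lt(R(450), R(550))           # yellow petals: dark blue
  expect_lt(R(550), R(660))           # bright through green into red
  expect_error(canopy_scenario(2, flower_fraction = 1.4),
               class = "opivi_bad_scenario")
  expect_error(canopy_scenario(2, g_extinction = 0),
               class = "opivi_bad_scenario")
  # petal admixture raises red-band reflectance of the vegetation signal
  b0 <- brdf_params(noise_sd = 0, gain_sd = 0)
  r_leaf <- canopy_reflectance(canopy_scenario(3), 0, b0, noise = FALSE)
  r_bloom <- canopy_reflectance(canopy_scenario(3, flower_fraction = 0.3),
                                0, b0, noise = FALSE)
  expect_gt(band_reflectance(r_bloom, 660), band_reflectance(r_leaf, 660))
})

test_that("simulate_dataset: design counts, determinism, treatment effects", {
  ds <- simulate_dataset(reps = 3, seed = 7)
  expect_equal(nrow(ds$metadata), 90)   # 45 plots x 2 stages
  expect_equal(nrow(ds$obs), 810)       # x 9 VZAs
  expect_equal(nrow(unique(ds$obs)), 810)

  ds2 <- simulate_dataset(reps = 3, seed = 7)
  expect_identical(ds$reflectance, ds2$reflectance)
  expect_identical(write_dataset(ds)$spectra$reflectance,
                   write_dataset(ds2)$spectra$reflectance)
  ds3 <- simulate_dataset(reps = 3, seed = 8)
  expect_false(identical(ds$reflectance, ds3$reflectance))

  # LAI means increase with nitrogen level
  m <- tapply(ds$metadata$lai, ds$metadata$nitrogen, mean)
  expect_true(all(diff(m[paste0("N", 0:4)]) > 0))

  expect_error(simulate_dataset(vzas = numeric(0)), class = "opivi_bad_vza")
  expect_error(simulate_dataset(reps = 0), class = "opivi_bad_scenario")
})

test_that("simulated OPIVI tracks LAI at every angle and is more
           angle-stable than NDDA", {
  ds <- smooth_dataset(simulate_dataset(reps = 3, seed = 7))
  vt <- compute_index_table(ds, c("OPIVI", "NDDA"))
  r_op <- correlation_by_angle(vt, ds$metadata, "OPIVI")
  expect_true(all(r_op$r > 0.6))
  r_nd <- correlation_by_angle(vt, ds$metadata, "NDDA")
  expect_lt(abs(dr_statistic(r_op$r)), abs(dr_statistic(r_nd$r)))
})
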