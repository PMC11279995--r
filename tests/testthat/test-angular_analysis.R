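test_that("amplitude_vs_nadir computes percent change and guards zero nadir", {
  expect_equal(amplitude_vs_nadir(0.7, 0.7), 0)
  expect_equal(amplitude_vs_nadir(0.508, 0.500), 1.60)
  expect_equal(amplitude_vs_nadir(0.250, 0.500), -50)
  expect_equal(amplitude_vs_nadir(c(0.4, 0.6), 0.5), c(-20, 20))
  expect_error(amplitude_vs_nadir(0.3, 0), class = "opivi_undefined_amplitude")
  set.seed(20)
  for (x in runif(10, -3, 3)) {
    if (abs(x) > 1e-6) expect_equal(amplitude_vs_nadir(x, x), 0)
  }
})

test_that("oneway_f matches the brute-force oracle and its identities", {
  # identical groups -> F = 0
  g <- replicate(3, c(1, 2, 3), simplify = FALSE)
  expect_equal(oneway_f(g)$f, 0)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(21)
  a <- rnorm(8); b2 <- rnorm(11, 0.5)
  f2 <- oneway_f(list(a, b2))
  tt <- t.test(a, b2, var.equal = TRUE)
  expect_equal(f2$f, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(f2$p_value, tt$p.value, tolerance = 1e-12)

  # random instances vs explicit sums of squares; shift invariance
  for (rep in 1:20) {
    gs <- lapply(sample(2:6, sample(2:5, 1), replace = TRUE),
                 function(n) rnorm(n + 1))
    res <- oneway_f(gs)
    expect_equal(res$f, oracle_oneway_f(gs), tolerance = 1e-10)
    expect_equal(res$df_between, length(gs) - 1L)
    expect_equal(res$df_within, length(unlist(gs)) - length(gs))
    shifted <- lapply(gs, `+`, 7.3)
    expect_equal(oneway_f(shifted)$f, res$f, tolerance = 1e-8)
    expect_gte(res$f, 0)
  }

  expect_error(oneway_f(list(1, c(1, 2))), class = "opivi_bad_groups")
  expect_error(oneway_f(list(c(1, 2))), class = "opivi_bad_groups")
})

test_that("correlation_by_angle returns per-VZA Pearson r on the subset", {
  toy <- toy_vitable(n = 12, vzas = c(-15, 0, 15))
  r <- correlation_by_angle(toy$vitable, toy$metadata, "VI")
  expect_equal(r$vza_deg, c(-15, 0, 15))
  expect_equal(r$r, rep(1, 3), tolerance = 1e-12)  # VI linear in LAI
  expect_equal(r$n, rep(12L, 3))

  neg <- toy$vitable
  neg$value <- -neg$value
  expect_equal(correlation_by_angle(neg, toy$metadata, "VI")$r, rep(-1, 3),
               tolerance = 1e-12)

  # hand Pearson value on x = (1,2,3), y = (1,2,4)
  vt3 <- data.frame(sample_id = c("a", "b", "c"), vza_deg = 0,
                    index = "VI", value = c(1, 2, 3))
  md3 <- data.frame(sample_id = c("a", "b", "c"), stage = "budding",
                    nitrogen = "N0", coverage = "NM", lai = c(1, 2, 4))
  expect_equal(correlation_by_angle(vt3, md3, "VI")$r, 0.9819805,
               tolerance = 1e-6)

  # degenerate cases
  vt3$value <- 1
  expect_error(correlation_by_angle(vt3, md3, "VI"),
               class = "opivi_undefined_r")
  expect_error(correlation_by_angle(vt3[1:2, ], md3, "VI"),
               class = "opivi_too_few_samples")
})

test_that("dr_statistic implements (max - min)/mean with its invariants", {
  expect_equal(dr_statistic(rep(0.8, 9)), 0)
  expect_equal(dr_statistic(c(0, 1)), 2)
  bolting <- c(0.74, 0.78, 0.81, 0.82, 0.81, 0.81, 0.78, 0.75, 0.74)
  expect_equal(dr_statistic(bolting), 0.08 / mean(bolting))
  expect_equal(round(dr_statistic(bolting), 4), 0.1023)

  set.seed(22)
  for (rep in 1:20) {
    r <- runif(9, 0.1, 0.95)
    c0 <- runif(1, 0.1, 5)
    expect_equal(dr_statistic(c0 * r), dr_statistic(r), tolerance = 1e-12)
    expect_gte(dr_statistic(r), 0)
  }
  expect_error(dr_statistic(numeric(0)), class = "opivi_bad_groups")
  expect_error(dr_statistic(c(-1, 1)), class = "opivi_undefined_dr")
})

test_that("stability_report assembles amplitudes, ANOVA, r and DR", {
  set.seed(23)
  ds <- smooth_dataset(simulate_dataset(reps = 2, seed = 31))
  vt <- compute_index_table(ds, c("OPIVI", "NDDA", "NDRE"))
  rep1 <- stability_report(vt, ds$metadata)
  expect_s3_class(rep1, "stability_report")
  expect_setequal(rep1$amplitudes$index, c("OPIVI", "NDDA", "NDRE"))
  expect_true(all(rep1$anova$f_full >= 0))
  expect_setequal(unique(rep1$dr$subset),
                  c("budding", "flowering", "n_rates", "overlay_mode"))
  # nadir row of every profile is exactly 0
  nadir_rows <- rep1$profile[rep1$profile$vza_deg == 0, ]
  expect_equal(nadir_rows$pct_change, rep(0, nrow(nadir_rows)))

  # permutation invariance to row order
  perm <- sample(nrow(vt))
  rep2 <- stability_report(vt[perm, ], ds$metadata)
  expect_equal(rep2$dr, rep1$dr)
  expect_equal(rep2$amplitudes, rep1$amplitudes)

  # angle-flat index: zero amplitudes, F = 0 (per-sample values identical
  # across VZAs)
  flat <- toy_vitable(n = 10, vzas = c(-15, 0, 15))$vitable
  flat$value <- rep(seq(1, 2, length.out = 10), times = 3)
  meta <- toy_vitable(n = 10, vzas = c(-15, 0, 15))$metadata
  repf <- stability_report(flat, meta,
                           sub_datasets = list(all = rep(TRUE, 10)))
  expect_equal(repf$amplitudes$amplitude_minus60, NA_real_)
  expect_equal(max(abs(repf$profile$pct_change)), 0)
  expect_equal(repf$anova$f_full, 0)

  # missing nadir is an error
  expect_error(stability_report(vt[vt$vza_deg != 0, ], ds$metadata),
               class = "opivi_missing_nadir")
  expect_error(stability_report(vt[vt$vza_deg == 0, ], ds$metadata),
               class = "opivi_missing_obs")
})

test_that("stability report serializes to CSV blocks plus JSON", {
  ds <- smooth_dataset(simulate_dataset(reps = 2, seed = 32))
  vt <- compute_index_table(ds, c("OPIVI", "REP"))
  rep1 <- stability_report(vt, ds$metadata)
  dir <- tempfile()
  paths <- write_stability_report(rep1, dir)
  expect_true(all(file.exists(paths)))
  dr_back <- read.csv(paths["dr"])
  expect_equal(dr_back$dr, rep1$dr$dr, tolerance = 1e-12)
})
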