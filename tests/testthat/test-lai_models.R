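test_that("train_test_split: counts, determinism, disjoint-exhaustive", {
  ids180 <- sprintf("S%03d", 1:180)
  part <- train_test_split(ids180, split_spec(0.7, 1))
  expect_length(part$train, 126)
  expect_length(part$test, 54)

  part10 <- train_test_split(sprintf("x%02d", 1:10), split_spec(0.7, 3))
  expect_length(part10$train, 7)
  expect_length(part10$test, 3)

  expect_identical(train_test_split(ids180, split_spec(0.7, 9)),
                   train_test_split(ids180, split_spec(0.7, 9)))

  for (seed in 1:10) {
    p <- train_test_split(ids180, split_spec(0.7, seed))
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), ids180)
  }

  expect_error(split_spec(0), class = "opivi_bad_split")
  expect_error(split_spec(1.2), class = "opivi_bad_split")
  expect_error(train_test_split("one"), class = "opivi_bad_split")
  expect_error(train_test_split(sprintf("x%d", 1:3), split_spec(0.01, 1)),
               class = "opivi_bad_split")
})

test_that("r_squared and rmse identities and worked example", {
  obs <- c(2.1, 3.4, 1.2, 4.4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(rmse(obs, obs), 0)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(rep(1, 3), c(1, 2, 3)), class = "opivi_undefined_r2")
  set.seed(30)
  for (rep in 1:10) {
    o <- rnorm(20); p <- rnorm(20)
    expect_lte(r_squared(o, p), 1)
    expect_gte(rmse(o, p), 0)
    expect_equal(rmse(o, p) == 0, all(o == p))
  }
})

test_that("fit_linear_per_angle recovers a noiseless linear law and matches
           the normal-equations oracle", {
  toy <- toy_vitable(n = 24, vzas = c(-15, 0, 15))
  vt <- toy$vitable
  # exact law at nadir: value = score, lai = 2 * score + 1
  fit0 <- fit_linear_per_angle(vt, toy$metadata, "VI", 0, split_spec(0.7, 2))
  expect_equal(unname(fit0$parameters["slope"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit0$parameters["intercept"]), 1, tolerance = 1e-10)
  expect_equal(fit0$r2_train, 1, tolerance = 1e-12)
  expect_equal(fit0$r2_test, 1, tolerance = 1e-12)
  expect_equal(fit0$rmse_test, 0, tolerance = 1e-8)

  # noisy data: OLS coefficients equal the closed form on the train subset
  set.seed(31)
  vt$value <- vt$value + rnorm(nrow(vt), 0, 0.05)
  sp <- split_spec(0.7, 4)
  fit <- fit_linear_per_angle(vt, toy$metadata, "VI", -15, sp)
  part <- train_test_split(toy$metadata$sample_id, sp)
  tr <- vt[vt$vza_deg == -15 & vt$sample_id %in% part$train, ]
  beta <- oracle_ols(tr$value,
                     toy$metadata$lai[match(tr$sample_id,
                                            toy$metadata$sample_id)])
  expect_equal(unname(fit$parameters), beta, tolerance = 1e-10)

  # shuffling rows does not change the fit
  fit_sh <- fit_linear_per_angle(vt[sample(nrow(vt)), ], toy$metadata,
                                 "VI", -15, sp)
  expect_equal(fit_sh$parameters, fit$parameters)

  const <- vt
  const$value <- 1
  expect_error(fit_linear_per_angle(const, toy$metadata, "VI", 0, sp),
               class = "opivi_undefined_r")
})

test_that("multi-angle engines fit a noiseless linear target and are
           reproducible", {
  toy <- toy_vitable(n = 150, vzas = c(-30, -15, 0))
  sp <- split_spec(0.7, 7)
  for (mk in c("rf", "gbt", "svr_rbf")) {
    fit <- fit_multiangle(toy$vitable, toy$metadata, "VI",
                          c(-30, -15, 0), mk, sp, seed = 7)
    expect_gte(fit$r2_train, 0.99)
    fit2 <- fit_multiangle(toy$vitable, toy$metadata, "VI",
                           c(-30, -15, 0), mk, sp, seed = 7)
    expect_identical(fit$predictions$pred, fit2$predictions$pred)
  }
  expect_error(fit_multiangle(toy$vitable, toy$metadata, "VI",
                              c(-30, -15, 0), "boost", sp),
               "'arg' should be one of")
  expect_error(fit_multiangle(toy$vitable, toy$metadata, "VI",
                              c(-45, -15, 0), "rf", sp),
               class = "opivi_missing_obs")
})

test_that("engine-level contracts: mtry clamping, bagging limit, SVR tube", {
  set.seed(33)
  x <- matrix(runif(80), ncol = 2)
  y <- 3 * x[, 1] - x[, 2] + rnorm(40, 0, 0.01)
  expect_warning(fit <- rf_reg(x, y, ntree = 50, mtry = 3, seed = 1),
                 "clamped")
  expect_equal(fit$mtry, 2)

  # mtry = p is pure bagging: identical to an explicit mtry = p run
  f1 <- rf_reg(x, y, ntree = 30, mtry = 2, seed = 5)
  f2 <- rf_reg(x, y, ntree = 30, mtry = 2, seed = 5)
  expect_identical(predict(f1, x), predict(f2, x))

  # gbt with enough rounds drives train error far down
  g <- gbt_reg(x, y, nrounds = 400, learning_rate = 0.05, seed = 2)
  expect_gte(r_squared(y, predict(g, x)), 0.97)

  # SVR: most training residuals inside the epsilon tube (plus slack)
  s <- svr_reg(x, y, cost = 10, epsilon = 0.1)
  resid <- abs(y - predict(s, x))
  expect_gte(mean(resid <= 0.1 + 1e-6), 0.8)
})

test_that("fit results serialize to JSON", {
  toy <- toy_vitable(n = 20, vzas = c(-30, -15, 0))
  fit <- fit_multiangle(toy$vitable, toy$metadata, "VI", c(-30, -15, 0),
                        "rf", split_spec(0.7, 1), seed = 1,
                        params = list(ntree = 25))
  path <- tempfile(fileext = ".json")
  write_fit_result(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$model_kind, "rf")
  expect_equal(back$r2_test, fit$r2_test, tolerance = 1e-12)
  expect_equal(nrow(back$predictions), nrow(fit$predictions))
})
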