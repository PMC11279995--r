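# LAI estimation: fixed 70/30 sample split, per-angle univariate linear
# regression, multi-angle ensemble regressors, and R^2/RMSE metrics.

#' Split specification
#'
#' @param train_fraction proportion of samples used for training
#'   (default 0.7, i.e. 126 of 180).
#' @param seed integer seed; identical seeds give identical partitions, and
#'   the same partition is reused across all VZAs and model kinds.
#' @return object of class `"split_spec"`.
#' @export
split_spec <- function(train_fraction = 0.7, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    opivi_error("train_fraction must be strictly between 0 and 1.",
                "opivi_bad_split")
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Deterministic train/test partition of sample ids
#'
#' Train size is `round(train_fraction * N)` (round-half-even, so 180 samples
#' at 0.7 give exactly 126 train / 54 test). The partition is a pure function
#' of the id set and the seed.
#'
#' @param sample_ids character vector of ids (>= 2).
#' @param spec a [split_spec()].
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
train_test_split <- function(sample_ids, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  ids <- sort(unique(as.character(sample_ids)))
  n <- length(ids)
  if (n < 2L) opivi_error("need at least two samples.", "opivi_bad_split")
  n_train <- as.integer(round(spec$train_fraction * n))
  if (n_train < 1L || n_train >= n) {
    opivi_error("train_fraction yields an empty train or test set.",
                "opivi_bad_split")
  }
  perm <- with_seed(spec$seed, sample(ids, n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((O - P)^2) / sum((O - mean(O))^2)` for observations O and
#' predictions P.
#'
#' @param obs,pred numeric vectors of equal length >= 2.
#' @return R-squared value (<= 1; can be negative for bad out-of-sample fits).
#' @export
r_squared <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2L)
  finite_or_error(c(obs, pred), "R^2 input")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot < 1e-12) {
    opivi_error("R^2 undefined: observations are constant.",
                "opivi_undefined_r2")
  }
  1 - sum((obs - pred)^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return RMSE in the units of `obs` (cm^2 per cm^2 for LAI).
#' @export
rmse <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 1L)
  finite_or_error(c(obs, pred), "RMSE input")
  sqrt(mean((obs - pred)^2))
}

# sample x feature matrix of one index at the requested VZAs, joined to LAI
vi_feature_frame <- function(vitable, metadata, index, vzas) {
  metadata <- as.data.frame(metadata)
  vt <- vitable[vitable$index == index & vitable$vza_deg %in% vzas, ]
  missing_vza <- setdiff(vzas, unique(vt$vza_deg))
  if (length(missing_vza)) {
    opivi_error(paste0("requested VZAs absent from the index table: ",
                       paste(missing_vza, collapse = ", ")),
                "opivi_missing_obs")
  }
  wide <- stats::reshape(vt[, c("sample_id", "vza_deg", "value")],
                         idvar = "sample_id", timevar = "vza_deg",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "vza_", names(wide))
  cols <- paste0("vza_", vzas)
  wide <- wide[stats::complete.cases(wide[, cols, drop = FALSE]), ]
  wide$lai <- metadata$lai[match(wide$sample_id, metadata$sample_id)]
  wide <- wide[!is.na(wide$lai), ]
  list(frame = wide, feature_cols = cols)
}

new_fit_result <- function(model_kind, index, vzas, parameters, split,
                           train_df, test_df, extra = list()) {
  res <- c(list(
    model_kind = model_kind, index = index, vzas = vzas,
    parameters = parameters, split = split,
    r2_train = r_squared(train_df$obs, train_df$pred),
    rmse_train = rmse(train_df$obs, train_df$pred),
    r2_test = r_squared(test_df$obs, test_df$pred),
    rmse_test = rmse(test_df$obs, test_df$pred),
    predictions = rbind(cbind(set = "train", train_df),
                        cbind(set = "test", test_df))
  ), extra)
  structure(res, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s on %s @ VZA {%s}\n  train R^2 = %.3f, RMSE = %.3f | test R^2 = %.3f, RMSE = %.3f cm^2/cm^2\n",
    x$model_kind, x$index, paste(x$vzas, collapse = ", "),
    x$r2_train, x$rmse_train, x$r2_test, x$rmse_test))
  invisible(x)
}

#' Per-angle univariate linear LAI model
#'
#' Ordinary least squares `LAI ~ VI` on the training subset of one index at
#' one VZA, with train/test R^2 and RMSE.
#'
#' @param vitable a `vi_table` from [compute_index_table()].
#' @param metadata per-sample metadata with `lai`.
#' @param index index code.
#' @param vza single view zenith angle.
#' @param split a [split_spec()]; the partition is drawn on the full
#'   metadata id set so it is identical across VZAs.
#' @return a `fit_result` with `parameters = c(intercept, slope)`.
#' @export
fit_linear_per_angle <- function(vitable, metadata, index, vza,
                                 split = split_spec()) {
  ff <- vi_feature_frame(vitable, metadata, index, vza)
  part <- train_test_split(as.data.frame(metadata)$sample_id, split)
  col <- ff$feature_cols[1]
  tr <- ff$frame[ff$frame$sample_id %in% part$train, ]
  te <- ff$frame[ff$frame$sample_id %in% part$test, ]
  if (nrow(tr) < 3L) {
    opivi_error("fewer than 3 training samples with a defined index value.",
                "opivi_too_few_samples")
  }
  if (stats::sd(tr[[col]]) < 1e-12) {
    opivi_error("zero index variance in the training set.",
                "opivi_undefined_r")
  }
  fit <- stats::lm(lai ~ vi, data = data.frame(vi = tr[[col]], lai = tr$lai))
  cf <- stats::coef(fit)
  mk_df <- function(d) data.frame(
    sample_id = d$sample_id, obs = d$lai,
    pred = unname(cf[1] + cf[2] * d[[col]]))
  new_fit_result("linear", index, vza,
                 c(intercept = unname(cf[1]), slope = unname(cf[2])),
                 split, mk_df(tr), mk_df(te))
}

#' Multi-angle machine-learning LAI model
#'
#' Fits one index observed at several VZAs (by default the three
#' best-performing back-scatter/nadir angles -30, -15, 0) as the feature
#' matrix of a random forest (`"rf"`, 500 trees, mtry 3), gradient-boosted
#' trees (`"gbt"`, depth 5, learning rate 0.01) or RBF support-vector
#' regression (`"svr_rbf"`, C = 1, epsilon = 0.1).
#'
#' @inheritParams fit_linear_per_angle
#' @param vzas view zenith angles supplying the features.
#' @param model_kind one of `"rf"`, `"gbt"`, `"svr_rbf"`.
#' @param seed seed for the stochastic engines (default: the split seed).
#' @param params named list overriding engine hyperparameters (e.g.
#'   `list(ntree = 100)`).
#' @return a `fit_result`; `parameters` records the hyperparameters used.
#' @export
fit_multiangle <- function(vitable, metadata, index, vzas = c(-30, -15, 0),
                           model_kind = c("rf", "gbt", "svr_rbf"),
                           split = split_spec(), seed = NULL,
                           params = list()) {
  model_kind <- match.arg(model_kind)
  seed <- seed %||% split$seed
  ff <- vi_feature_frame(vitable, metadata, index, vzas)
  part <- train_test_split(as.data.frame(metadata)$sample_id, split)
  tr <- ff$frame[ff$frame$sample_id %in% part$train, ]
  te <- ff$frame[ff$frame$sample_id %in% part$test, ]
  if (nrow(tr) < 5L) {
    opivi_error("too few complete training samples for a multi-angle model.",
                "opivi_too_few_samples")
  }
  xtr <- as.matrix(tr[, ff$feature_cols, drop = FALSE])
  xte <- as.matrix(te[, ff$feature_cols, drop = FALSE])
  model <- switch(model_kind,
    rf = do.call(rf_reg, c(list(x = xtr, y = tr$lai, seed = seed), params)),
    gbt = do.call(gbt_reg, c(list(x = xtr, y = tr$lai, seed = seed), params)),
    svr_rbf = do.call(svr_reg, c(list(x = xtr, y = tr$lai), params))
  )
  hyper <- model[setdiff(names(model), c("trees", "base", "xs", "beta",
                                         "intercept", "center", "scale"))]
  tr_df <- data.frame(sample_id = tr$sample_id, obs = tr$lai,
                      pred = predict(model, xtr))
  te_df <- data.frame(sample_id = te$sample_id, obs = te$lai,
                      pred = predict(model, xte))
  new_fit_result(model_kind, index, vzas, hyper, split, tr_df, te_df,
                 extra = list(model = model, seed = seed))
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(model_kind = fit$model_kind, index = fit$index,
              vzas = fit$vzas,
              hyperparameters = fit$parameters[!vapply(fit$parameters,
                                                       is.null, TRUE)],
              split = unclass(fit$split), seed = fit$seed,
              r2_train = fit$r2_train, rmse_train = fit$rmse_train,
              r2_test = fit$r2_test, rmse_test = fit$rmse_test,
              predictions = fit$predictions)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
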