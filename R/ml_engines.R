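# Regression engines behind fit_multiangle(): random forest and
# gradient-boosted trees (compiled tree builder), and epsilon-SVR with an
# RBF kernel solved exactly through its dual quadratic program.

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) opivi_error("feature matrix contains NA.", "opivi_nonfinite")
  x
}

#' Random-forest regression
#'
#' Bagged CART regression trees with `mtry` candidate features per split.
#' Defaults follow the study settings: 500 trees and 3 candidate features.
#' With `mtry >=` the number of features no feature subsampling remains and
#' the forest is pure bagging.
#'
#' @param x feature matrix (samples x features).
#' @param y numeric response.
#' @param ntree number of trees (default 500).
#' @param mtry candidate features per split (default 3; clamped to
#'   `ncol(x)` with a warning).
#' @param min_leaf minimum observations per leaf (default 5).
#' @param max_depth maximum tree depth (default 25, effectively unpruned).
#' @param sample_frac bootstrap fraction (default 1, with replacement).
#' @param seed integer seed making the fit reproducible.
#' @return object of class `"rf_reg"` with a `predict()` method.
#' @export
rf_reg <- function(x, y, ntree = 500L, mtry = 3L, min_leaf = 5L,
                   max_depth = 25L, sample_frac = 1, seed = NULL) {
  x <- as_feature_matrix(x)
  stopifnot(nrow(x) == length(y))
  if (mtry > ncol(x)) {
    warning(sprintf("mtry = %d exceeds the %d available features; clamped.",
                    mtry, ncol(x)))
    mtry <- ncol(x)
  }
  trees <- with_seed(seed, cpp_rf(x, as.numeric(y), as.integer(ntree),
                                  as.integer(mtry), as.integer(min_leaf),
                                  as.integer(max_depth), sample_frac, TRUE))
  structure(list(trees = trees, ntree = ntree, mtry = mtry,
                 min_leaf = min_leaf, max_depth = max_depth,
                 p = ncol(x), seed = seed),
            class = "rf_reg")
}

#' @export
predict.rf_reg <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  stopifnot(ncol(newdata) == object$p)
  as.numeric(cpp_predict_forest(object$trees, newdata))
}

#' Gradient-boosted tree regression
#'
#' Squared-loss boosting of depth-limited regression trees with shrinkage and
#' L1/L2 leaf regularization (alpha, lambda), in the style of XGBoost.
#' Study settings: `max_depth = 5`, `learning_rate = 0.01`; the number of
#' rounds is not fixed by the study and defaults to 500.
#'
#' @inheritParams rf_reg
#' @param nrounds boosting rounds (default 500).
#' @param learning_rate shrinkage per round (default 0.01).
#' @param max_depth maximum tree depth (default 5).
#' @param lambda L2 leaf-weight regularization (default 1).
#' @param alpha L1 leaf-weight regularization (default 0).
#' @return object of class `"gbt_reg"` with a `predict()` method.
#' @export
gbt_reg <- function(x, y, nrounds = 500L, learning_rate = 0.01,
                    max_depth = 5L, min_leaf = 5L, lambda = 1, alpha = 0,
                    seed = NULL) {
  x <- as_feature_matrix(x)
  stopifnot(nrow(x) == length(y))
  fit <- with_seed(seed, cpp_gbt(x, as.numeric(y), as.integer(nrounds),
                                 learning_rate, as.integer(max_depth),
                                 as.integer(min_leaf), lambda, alpha))
  structure(list(trees = fit$trees, base = fit$base,
                 learning_rate = learning_rate, nrounds = nrounds,
                 max_depth = max_depth, min_leaf = min_leaf,
                 lambda = lambda, alpha = alpha, p = ncol(x), seed = seed),
            class = "gbt_reg")
}

#' @export
predict.gbt_reg <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  stopifnot(ncol(newdata) == object$p)
  as.numeric(cpp_predict_gbt(object$trees, object$base, object$learning_rate,
                             newdata))
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Epsilon support-vector regression with an RBF kernel
#'
#' Solves the epsilon-insensitive SVR dual exactly as a quadratic program
#' (2n variables alpha, alpha* in `[0, C]`, one equality constraint), so the
#' fit is fully deterministic. Features are standardized internally;
#' `gamma` defaults to `1/ncol(x)` on the standardized scale (the usual
#' "scale" heuristic).
#'
#' @inheritParams rf_reg
#' @param cost box constraint C (default 1).
#' @param epsilon insensitivity tube half-width (default 0.1).
#' @param gamma RBF kernel width; default `1/ncol(x)`.
#' @return object of class `"svr_reg"` with a `predict()` method.
#' @export
svr_reg <- function(x, y, cost = 1, epsilon = 0.1, gamma = NULL) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(n == length(y), n >= 2L)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, `/`)
  if (is.null(gamma)) gamma <- 1 / ncol(x)

  K <- rbf_kernel(xs, xs, gamma)
  ridge <- 1e-8
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(ridge, 2 * n)
  d <- c(y - epsilon, -y - epsilon)
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  b0 <- c(0, rep(0, 2 * n), rep(-cost, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)
  z <- sol$solution
  beta <- z[1:n] - z[(n + 1):(2 * n)]
  beta[abs(beta) < 1e-10] <- 0

  f0 <- as.numeric(K %*% beta)
  free <- which(abs(beta) > 1e-8 & abs(beta) < cost - 1e-8)
  if (length(free)) {
    b <- mean(y[free] - f0[free] - epsilon * sign(beta[free]))
  } else {
    b <- stats::median(y - f0)
  }
  structure(list(xs = xs, beta = beta, intercept = b, gamma = gamma,
                 cost = cost, epsilon = epsilon, center = center,
                 scale = scale, p = ncol(x)),
            class = "svr_reg")
}

#' @export
predict.svr_reg <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  stopifnot(ncol(newdata) == object$p)
  ns <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  as.numeric(rbf_kernel(ns, object$xs, object$gamma) %*% object$beta +
               object$intercept)
}
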