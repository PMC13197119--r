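# R interface to the gradient-boosted tree learner (src/gbt.cpp).
# No gradient-boosting package ships with the supported environment, so the
# booster is implemented in-package: second-order logistic boosting with
# exact greedy splits, matching the standard XGBoost parameterization.

#' Booster hyperparameters
#'
#' Defaults follow the reference training configuration: 500 boosting
#' rounds, learning rate 0.05, row subsample 0.8, column subsample 0.8,
#' maximum tree depth 6, min_child_weight 1 (hessian units), L2 leaf
#' penalty lambda 1.
#'
#' @param nrounds number of boosting rounds.
#' @param eta learning rate.
#' @param max_depth maximum tree depth.
#' @param subsample bernoulli row-subsampling rate per round.
#' @param colsample_bytree fraction of features sampled per tree.
#' @param min_child_weight minimum hessian sum in a child.
#' @param lambda L2 regularization on leaf weights.
#' @param base_score initial prediction (probability scale).
#' @return a list of class \code{tfb_gbt_params}.
#' @export
gbt_params <- function(nrounds = 500L, eta = 0.05, max_depth = 6L,
                       subsample = 0.8, colsample_bytree = 0.8,
                       min_child_weight = 1, lambda = 1,
                       base_score = 0.5) {
  stopifnot(nrounds >= 1, eta > 0, max_depth >= 1,
            subsample > 0, subsample <= 1,
            colsample_bytree > 0, colsample_bytree <= 1,
            min_child_weight >= 0, lambda >= 0,
            base_score > 0, base_score < 1)
  structure(list(nrounds = as.integer(nrounds), eta = eta,
                 max_depth = as.integer(max_depth), subsample = subsample,
                 colsample_bytree = colsample_bytree,
                 min_child_weight = min_child_weight, lambda = lambda,
                 base_score = base_score),
            class = "tfb_gbt_params")
}

#' Train a gradient-boosted tree classifier (logistic objective)
#'
#' @param x numeric feature matrix (no NAs; impute upstream).
#' @param y binary 0/1 labels.
#' @param params a \code{\link{gbt_params}} list.
#' @param seed integer seed; training is fully deterministic given
#'   (x, y, params, seed).
#' @param val optional list(x, y) validation set for early stopping on
#'   validation AUPR.
#' @param early_stopping_rounds stop after this many rounds without AUPR
#'   improvement (0 disables; ignored without \code{val}).
#' @return a \code{tfb_gbt} booster.
#' @export
gbt_train <- function(x, y, params = gbt_params(), seed = 1L,
                      val = NULL, early_stopping_rounds = 0L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (any(!is.finite(x))) stop("non-finite feature values; impute first")
  if (sum(y) == 0L || sum(y) == length(y))
    stop("training table must contain both classes")
  xv <- NULL; yv <- NULL
  if (!is.null(val)) {
    xv <- as.matrix(val$x); storage.mode(xv) <- "double"
    yv <- as.integer(val$y)
    stopifnot(nrow(xv) == length(yv))
  }
  set.seed(as.integer(seed))
  fit <- .gbt_train_cpp(x, y, params$nrounds, params$eta, params$max_depth,
                        params$subsample, params$colsample_bytree,
                        params$min_child_weight, params$lambda,
                        params$base_score, xv, yv,
                        as.integer(early_stopping_rounds))
  structure(list(trees = fit$trees, n_trees = fit$n_trees,
                 best_iteration = fit$best_iteration,
                 best_score = fit$best_score, eval_log = fit$eval_log,
                 base_score = fit$base_score,
                 importance_gain = setNames(fit$importance_gain, colnames(x)),
                 importance_frequency = setNames(fit$importance_frequency,
                                                 colnames(x)),
                 feature_names = colnames(x), params = params, seed = seed),
            class = "tfb_gbt")
}

#' @export
print.tfb_gbt <- function(x, ...) {
  cat(sprintf("gradient-boosted trees: %d trees, depth <= %d, eta %.3g\n",
              x$n_trees, x$params$max_depth, x$params$eta))
  invisible(x)
}

#' Predict binding probabilities from a booster
#'
#' @param object a \code{tfb_gbt}.
#' @param newdata matrix or data.frame with the training feature columns.
#' @param output_margin return the raw log-odds margin instead of the
#'   probability.
#' @param ... unused.
#' @return numeric vector in [0, 1] (or margins).
#' @export
predict.tfb_gbt <- function(object, newdata, output_margin = FALSE, ...) {
  newdata <- align_features(newdata, object$feature_names)
  if (nrow(newdata) == 0L) return(numeric(0))
  .gbt_predict_cpp(object$trees, newdata, object$base_score, output_margin)
}

align_features <- function(newdata, feature_names) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(feature_names, names(newdata))
    if (length(missing))
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    newdata <- as.matrix(newdata[, feature_names, drop = FALSE])
  } else {
    newdata <- as.matrix(newdata)
    if (!is.null(colnames(newdata))) {
      missing <- setdiff(feature_names, colnames(newdata))
      if (length(missing))
        stop("missing feature column(s): ", paste(missing, collapse = ", "))
      newdata <- newdata[, feature_names, drop = FALSE]
    } else if (ncol(newdata) != length(feature_names)) {
      stop("feature matrix has ", ncol(newdata), " columns; expected ",
           length(feature_names))
    }
  }
  storage.mode(newdata) <- "double"
  newdata
}
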