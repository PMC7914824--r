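# Production training path: the same boosting contract as the reference
# booster, executed by xgboost for speed, with AUC early stopping on a
# held-out validation set. Agreement with the reference implementation is
# part of the test suite.

xgb_param_list <- function(params, seed, base_score) {
  list(objective = "binary:logistic", eval_metric = "auc",
       eta = params$eta, max_depth = params$max_depth,
       subsample = params$subsample, colsample_bytree = params$colsample_bytree,
       lambda = params$lambda, gamma = params$gamma,
       nthread = 1, seed = as.integer(seed),
       base_score = base_score)
}

#' Fit the production boosted-tree model
#'
#' Trains a gradient-boosted logistic model with the package's
#' [boosting_params()] contract via xgboost. When a validation set is
#' supplied, boosting stops once the validation AUC has not improved for
#' `params$patience` rounds and the model is truncated to the best round;
#' without one it runs `nrounds` rounds.
#'
#' @param X Feature matrix or tibble (training instances).
#' @param y 0/1 labels (or two-level factor/character).
#' @param params [boosting_params()].
#' @param validation Optional list `list(X = , y = )`, patient-disjoint
#'   from the training data.
#' @param nrounds Maximum rounds (defaults to `params$max_rounds`).
#' @param seed Seed controlling row/column subsampling.
#' @return A `pcg_model` object.
#' @export
fit_production_model <- function(X, y, params = boosting_params(),
                                 validation = NULL, nrounds = NULL, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as_binary_label(y)
  if (length(unique(y)) < 2L) abort("both classes must be present")
  nrounds <- nrounds %||% params$max_rounds
  fnames <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  colnames(X) <- fnames
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  # base score = training prevalence (log-odds in margin space), matching
  # the reference booster's convention
  args <- list(params = xgb_param_list(params, seed, mean(y)), data = dtrain,
               nrounds = nrounds, verbose = 0)
  if (!is.null(validation)) {
    Xv <- as.matrix(validation$X)
    storage.mode(Xv) <- "double"
    colnames(Xv) <- colnames(Xv) %||% fnames
    dval <- xgboost::xgb.DMatrix(Xv[, fnames, drop = FALSE],
                                 label = as_binary_label(validation$y), nthread = 1)
    args$evals <- list(val = dval)
    args$early_stopping_rounds <- params$patience
  }
  fit <- do.call(xgboost::xgb.train, args)
  # the stored attribute is a 0-based round index
  best_attr <- xgboost::xgb.attr(fit, "best_iteration")
  best_iter <- if (is.null(best_attr)) nrounds else as.integer(best_attr) + 1L
  best_score <- as.numeric(xgboost::xgb.attr(fit, "best_score") %||% NA_real_)
  imp <- tryCatch(xgboost::xgb.importance(model = fit), error = function(e) NULL)
  gain <- setNames(numeric(length(fnames)), fnames)
  if (!is.null(imp) && nrow(imp)) gain[imp$Feature] <- imp$Gain
  structure(
    list(booster = fit, feature_names = fnames, params = params,
         gain = gain, best_iteration = best_iter, val_auc = best_score,
         evaluation_log = attributes(fit)$evaluation_log, nrounds = nrounds),
    class = "pcg_model"
  )
}

#' @export
print.pcg_model <- function(x, ...) {
  cat(sprintf("<pcg_model> xgboost, best iteration %d%s\n", x$best_iteration,
              if (is.finite(x$val_auc)) sprintf(", validation AUC %.3f", x$val_auc) else ""))
  invisible(x)
}

#' @export
predict.pcg_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) X <- X[, object$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  d <- xgboost::xgb.DMatrix(X, nthread = 1)
  predict(object$booster, d,
          iterationrange = c(1L, object$best_iteration))
}

#' @export
tidy.pcg_model <- function(x, ...) gain_importance(x)

#' @export
glance.pcg_model <- function(x, ...) {
  tibble::tibble(best_iteration = x$best_iteration, val_auc = x$val_auc,
                 eta = x$params$eta, max_depth = x$params$max_depth)
}
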