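# Reference implementation of regularized gradient-boosted trees for
# binary logistic loss.
#
# This is the package's verifiable account of the boosting math: per-round
# gradients/Hessians of the logistic loss, exact greedy split search
# maximizing the regularized gain
#   Gain = 1/2 [ GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda) ] - gamma
# (a split is rejected when that quantity is negative), optimal leaf
# weights w* = -G/(H+lambda) shrunk by the learning rate, row/column
# subsampling, and per-feature cumulative gain for importance ranking.
# It trades speed for transparency; the xgboost-backed production path
# (fit_production_model) is checked against it.

#' Boosting hyperparameters
#'
#' Objective is fixed to binary logistic, evaluation metric to AUC. The
#' default learning rate is 0.03; untuned defaults are max_depth 3,
#' subsample 0.9, colsample_bytree 0.9, lambda 1, gamma 0.
#'
#' @param eta Learning rate in (0, 1].
#' @param max_depth Maximum tree depth (levels of splits).
#' @param subsample,colsample_bytree Row / column sampling fractions (0, 1].
#' @param lambda L2 penalty on leaf weights (>= 0).
#' @param gamma Per-split penalty (>= 0).
#' @param max_rounds Maximum boosting rounds.
#' @param patience Early-stopping patience (rounds without validation AUC
#'   improvement) for the production path.
#' @return A `boosting_params` list.
#' @export
boosting_params <- function(eta = 0.03, max_depth = 3L, subsample = 0.9,
                            colsample_bytree = 0.9, lambda = 1, gamma = 0,
                            max_rounds = 1000L, patience = 50L) {
  p <- list(eta = eta, max_depth = as.integer(max_depth), subsample = subsample,
            colsample_bytree = colsample_bytree, lambda = lambda, gamma = gamma,
            max_rounds = as.integer(max_rounds), patience = as.integer(patience),
            objective = "binary:logistic", eval_metric = "auc")
  if (p$eta <= 0 || p$eta > 1) abort("`eta` must be in (0, 1]")
  if (p$subsample <= 0 || p$subsample > 1 ||
      p$colsample_bytree <= 0 || p$colsample_bytree > 1) {
    abort("sampling fractions must be in (0, 1]")
  }
  if (p$lambda < 0 || p$gamma < 0) abort("`lambda` and `gamma` must be >= 0")
  structure(p, class = "boosting_params")
}

#' Gradient and Hessian of the logistic loss
#'
#' For predicted probability p and label y: g = p - y, h = p (1 - p).
#'
#' @param prob Predicted probabilities in (0, 1).
#' @param y Labels, 0 or 1.
#' @return List with vectors `g` and `h`.
#' @export
logistic_grad_hess <- function(prob, y) {
  list(g = prob - y, h = prob * (1 - prob))
}

#' Optimal leaf weight
#'
#' `w* = -G / (H + lambda)` for a leaf with gradient sum G and Hessian sum
#' H.
#'
#' @param G,H Sums of gradients / Hessians over the leaf's instances.
#' @param lambda L2 penalty.
#' @return The leaf weight.
#' @export
leaf_weight <- function(G, H, lambda) {
  if (H + lambda <= 0) abort("H + lambda must be positive")
  -G / (H + lambda)
}

#' Regularized split gain
#'
#' `1/2 [GL^2/(HL+l) + GR^2/(HR+l) - (GL+GR)^2/(HL+HR+l)] - gamma`; a
#' candidate split is only adopted when this is non-negative.
#'
#' @param GL,HL,GR,HR Gradient / Hessian sums on the left and right side.
#' @param lambda L2 penalty.
#' @param gamma Split penalty.
#' @return The gain.
#' @export
split_gain <- function(GL, HL, GR, HR, lambda, gamma) {
  0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
           (GL + GR)^2 / (HL + HR + lambda)) - gamma
}

# Best (threshold, gain) for one feature at one node, by a linear sweep over
# midpoints between consecutive sorted unique values.
best_split_for_feature <- function(xv, g, h, lambda, gamma) {
  ord <- order(xv)
  xs <- xv[ord]; gs <- g[ord]; hs <- h[ord]
  n <- length(xs)
  new_val <- which(diff(xs) > 0)  # split after position i
  if (!length(new_val)) return(NULL)
  cg <- cumsum(gs); ch <- cumsum(hs)
  G <- cg[n]; H <- ch[n]
  GL <- cg[new_val]; HL <- ch[new_val]
  gains <- split_gain(GL, HL, G - GL, H - HL, lambda, gamma)
  best <- which.max(gains)  # first index on ties -> lower threshold
  list(gain = gains[best],
       threshold = (xs[new_val[best]] + xs[new_val[best] + 1L]) / 2)
}

build_tree <- function(X, g, h, rows, cols, depth, params, gain_acc,
                       keep_rows = FALSE) {
  nodes <- list()
  grow <- function(rows, depth) {
    G <- sum(g[rows]); H <- sum(h[rows])
    make_leaf <- function() {
      nodes[[length(nodes) + 1L]] <<- list(
        leaf = TRUE, value = params$eta * leaf_weight(G, H, params$lambda),
        rows = if (keep_rows) rows)
      length(nodes)
    }
    if (depth >= params$max_depth || length(rows) < 2L) return(make_leaf())
    best <- NULL
    for (j in cols) {
      cand <- best_split_for_feature(X[rows, j], g[rows], h[rows],
                                     params$lambda, params$gamma)
      if (!is.null(cand) && cand$gain >= 0 &&
          (is.null(best) || cand$gain > best$gain)) {
        best <- c(cand, feature = j)  # ties: lower feature index wins (first found)
      }
    }
    if (is.null(best)) return(make_leaf())
    gain_acc[[as.character(best$feature)]] <-
      (gain_acc[[as.character(best$feature)]] %||% 0) + best$gain
    left_rows <- rows[X[rows, best$feature] < best$threshold]
    right_rows <- setdiff(rows, left_rows)
    left_id <- grow(left_rows, depth + 1L)
    right_id <- grow(right_rows, depth + 1L)
    nodes[[length(nodes) + 1L]] <<- list(
      leaf = FALSE, feature = best$feature, threshold = best$threshold,
      gain = best$gain, left = left_id, right = right_id,
      rows = if (keep_rows) rows)
    length(nodes)
  }
  root <- grow(rows, 0L)
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  walk <- function(node_id, rows) {
    node <- tree$nodes[[node_id]]
    if (node$leaf) {
      out[rows] <<- node$value
      return(invisible())
    }
    go_left <- X[rows, node$feature] < node$threshold
    if (any(go_left)) walk(node$left, rows[go_left])
    if (any(!go_left)) walk(node$right, rows[!go_left])
  }
  walk(tree$root, seq_len(n))
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit the reference boosted-tree model
#'
#' Exact greedy boosting: each round fits one tree on (optionally
#' row/column-subsampled) data, choosing at every node the (feature,
#' threshold) pair maximizing the regularized gain over all candidate
#' midpoints, rejecting splits with negative penalized gain, and assigning
#' shrunken optimal leaf weights. The base score is the log-odds of the
#' training prevalence. Deterministic when both sampling fractions are 1;
#' otherwise sampling uses the seeded generator.
#'
#' @param X Numeric matrix or feature tibble (rows = instances).
#' @param y Labels, 0/1 (or a factor/character with two levels, second =
#'   positive).
#' @param params [boosting_params()].
#' @param nrounds Number of boosting rounds (defaults to
#'   `params$max_rounds`).
#' @param seed Seed for row/column subsampling.
#' @param keep_instances Record the training instance rows at every tree
#'   node (for split-by-split auditing of the boosting math; memory grows
#'   with data size, so off by default).
#' @return A `pcg_booster` object.
#' @export
fit_reference_booster <- function(X, y, params = boosting_params(), nrounds = NULL,
                                  seed = 1L, keep_instances = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as_binary_label(y)
  if (length(unique(y)) < 2L) abort("both classes must be present")
  if (nrow(X) < 2L) abort("at least 2 instances are required")
  nrounds <- nrounds %||% params$max_rounds
  n <- nrow(X); p <- ncol(X)
  base_score <- log(mean(y) / (1 - mean(y)))
  margin <- rep(base_score, n)
  trees <- vector("list", nrounds)
  gain_acc <- new.env(parent = emptyenv())
  with_local_seed(seed, {
    for (r in seq_len(nrounds)) {
      gh <- logistic_grad_hess(sigmoid(margin), y)
      rows <- if (params$subsample < 1) {
        sort(sample.int(n, max(2L, round(params$subsample * n))))
      } else seq_len(n)
      cols <- if (params$colsample_bytree < 1) {
        sort(sample.int(p, max(1L, round(params$colsample_bytree * p))))
      } else seq_len(p)
      tree <- build_tree(X, gh$g, gh$h, rows, cols, 0L, params, gain_acc,
                         keep_rows = keep_instances)
      trees[[r]] <- tree
      margin <- margin + predict_tree(tree, X)
    }
  })
  gains <- unlist(as.list(gain_acc))
  fnames <- colnames(X) %||% paste0("f", seq_len(p))
  gain_by_feature <- setNames(numeric(p), fnames)
  if (length(gains)) gain_by_feature[as.integer(names(gains))] <- gains
  structure(
    list(trees = trees, base_score = base_score, params = params,
         feature_names = fnames, gain = gain_by_feature, nrounds = nrounds),
    class = "pcg_booster"
  )
}

as_binary_label <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.double(y))
  }
  f <- as.factor(y)
  if (nlevels(f) != 2L) abort("labels must have exactly two levels")
  as.double(f == levels(f)[2])
}

#' @export
print.pcg_booster <- function(x, ...) {
  n_splits <- sum(vapply(x$trees, function(tr) {
    sum(!vapply(tr$nodes, function(nd) nd$leaf, TRUE))
  }, 1L))
  cat(sprintf("<pcg_booster> %d trees, %d splits, base score %.4f\n",
              length(x$trees), n_splits, x$base_score))
  invisible(x)
}

#' @export
predict.pcg_booster <- function(object, newdata, type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) X <- X[, object$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  margin <- rep(object$base_score, nrow(X))
  for (tree in object$trees) margin <- margin + predict_tree(tree, X)
  if (type == "margin") margin else sigmoid(margin)
}

#' Ensemble probability
#'
#' Arithmetic mean of the member models' predicted probabilities.
#'
#' @param models List of fitted models (`pcg_booster` or `pcg_model`).
#' @param newdata Feature matrix/tibble.
#' @return Probability vector.
#' @export
predict_ensemble <- function(models, newdata) {
  if (!length(models)) abort("at least one model is required")
  probs <- vapply(models, function(m) predict(m, newdata), numeric(nrow(newdata)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}

#' Gain-based feature importance
#'
#' Per-feature gain summed over every split of every tree (and over
#' ensemble members when given a list of models), ranked descending; ties
#' break by canonical feature order. Features that were never split on are
#' omitted.
#'
#' @param model A fitted `pcg_booster`/`pcg_model`, or a list of them.
#' @return Tibble with `feature`, `gain`, `rank`.
#' @export
gain_importance <- function(model) {
  total <- gain_vector(model)
  total <- total[total > 0]
  ord <- order(-total, match(names(total), all_gain_names(model)))
  tibble::tibble(feature = names(total)[ord], gain = unname(total[ord]),
                 rank = seq_along(ord))
}

gain_vector <- function(model) {
  if (inherits(model, "pcg_booster")) return(model$gain)
  if (inherits(model, "pcg_model")) return(model$gain)
  if (is.list(model)) {
    vecs <- lapply(model, gain_vector)
    all_names <- unique(unlist(lapply(vecs, names)))
    out <- setNames(numeric(length(all_names)), all_names)
    for (v in vecs) out[names(v)] <- out[names(v)] + v
    return(out)
  }
  abort("unsupported model type")
}

all_gain_names <- function(model) {
  if (is.list(model) && !inherits(model, c("pcg_booster", "pcg_model"))) {
    return(unique(unlist(lapply(model, all_gain_names))))
  }
  model$feature_names
}

#' Select the Top-N features of a ranking
#'
#' @param ranking Importance tibble from [gain_importance()].
#' @param n Number of features to keep (>= 1); capped at the ranking size.
#' @return Character vector of feature names.
#' @export
select_top_n <- function(ranking, n) {
  if (n < 1) abort("`n` must be >= 1")
  head(ranking$feature, n)
}

#' @export
tidy.pcg_booster <- function(x, ...) gain_importance(x)

#' @export
glance.pcg_booster <- function(x, ...) {
  n_splits <- sum(vapply(x$trees, function(tr) {
    sum(!vapply(tr$nodes, function(nd) nd$leaf, TRUE))
  }, 1L))
  tibble::tibble(n_trees = length(x$trees), n_splits = n_splits,
                 base_score = x$base_score, eta = x$params$eta,
                 max_depth = x$params$max_depth)
}
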