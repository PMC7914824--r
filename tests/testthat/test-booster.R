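# The regularized boosting math: derivatives, leaf weights, split gain,
# the exact greedy reference booster, importance, and agreement with the
# production path.

# Exhaustive (feature, threshold) enumeration oracle for the best split at
# a node, independent of the booster's sweep.
best_split_oracle <- function(X, g, h, rows, lambda, gamma) {
  best <- -Inf
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[rows, j]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      left <- rows[X[rows, j] < thr]
      right <- setdiff(rows, left)
      gain <- split_gain(sum(g[left]), sum(h[left]), sum(g[right]), sum(h[right]),
                         lambda, gamma)
      if (gain > best) best <- gain
    }
  }
  best
}

test_that("logistic gradients and Hessians follow the closed forms", {
  gh <- logistic_grad_hess(0.5, 1)
  expect_equal(gh$g, -0.5); expect_equal(gh$h, 0.25)
  gh <- logistic_grad_hess(0.5, 0)
  expect_equal(gh$g, 0.5); expect_equal(gh$h, 0.25)
  gh <- logistic_grad_hess(0.9, 1)
  expect_equal(gh$g, -0.1)
  expect_equal(gh$h, 0.09, tolerance = 1e-12)
  p <- withr::with_seed(1, runif(50, 0.01, 0.99))
  expect_true(all(logistic_grad_hess(p, 1)$h > 0 & logistic_grad_hess(p, 1)$h <= 0.25))
})

test_that("leaf weights and split gains match the closed forms", {
  expect_equal(leaf_weight(2, 3, 1), -0.5)
  expect_equal(leaf_weight(0, 5, 2), 0)
  withr::with_seed(2, {
    for (i in 1:20) {
      G <- rnorm(1); H <- runif(1, 0.1, 5); lam <- runif(1, 0, 2)
      expect_equal(leaf_weight(G, H, lam), -G / (H + lam), tolerance = 1e-12)
    }
  })
  expect_equal(split_gain(1, 1, 1, 1, 0, 0), 0)
  expect_equal(split_gain(2, 1, -2, 1, 0, 0), 4)
  expect_equal(split_gain(2, 1, -2, 1, 0, 1), 3)
})

test_that("every reference-booster split attains the exhaustive-enumeration maximum", {
  for (ds in 1:5) {
    xy <- toy_xy(50, 8, seed = 100 + ds)
    params <- boosting_params(eta = 0.3, max_depth = 3, subsample = 1,
                              colsample_bytree = 1, lambda = 1, gamma = 0)
    fit <- fit_reference_booster(xy$X, xy$y, params, nrounds = 3, keep_instances = TRUE)
    margin <- rep(fit$base_score, nrow(xy$X))
    for (tree in fit$trees) {
      prob <- 1 / (1 + exp(-margin))
      g <- prob - xy$y; h <- prob * (1 - prob)
      for (node in tree$nodes) {
        if (node$leaf) {
          G <- sum(g[node$rows]); H <- sum(h[node$rows])
          expect_equal(node$value, params$eta * (-G / (H + params$lambda)),
                       tolerance = 1e-12)
        } else {
          oracle <- best_split_oracle(xy$X, g, h, node$rows,
                                      params$lambda, params$gamma)
          expect_equal(node$gain, oracle, tolerance = 1e-9)
        }
      }
      margin <- margin + neopcg:::predict_tree(tree, xy$X)
    }
  }
})

test_that("separable 1-D data reaches training AUC 1 with depth-1 trees", {
  x <- matrix(c(seq(-1, -0.1, length.out = 10), seq(0.1, 1, length.out = 10)), ncol = 1)
  y <- rep(c(0L, 1L), each = 10)
  fit <- fit_reference_booster(x, y, boosting_params(eta = 0.3, max_depth = 1,
                                                     subsample = 1, colsample_bytree = 1),
                               nrounds = 10)
  expect_equal(auc(predict(fit, x), y), 1)
})

test_that("constant features produce no splits and base-score predictions", {
  X <- matrix(1, 30, 4)
  y <- rep(c(0L, 1L), 15)
  fit <- fit_reference_booster(X, y, boosting_params(subsample = 1, colsample_bytree = 1),
                               nrounds = 5)
  expect_equal(sum(gain_importance(fit)$gain), 0)
  expect_equal(unique(predict(fit, X)), 0.5)  # prevalence 0.5
})

test_that("gamma above any achievable gain prunes every split", {
  xy <- toy_xy(40, 4, seed = 9)
  probe <- fit_reference_booster(xy$X, xy$y,
                                 boosting_params(subsample = 1, colsample_bytree = 1,
                                                 gamma = 0, eta = 0.3),
                                 nrounds = 1, keep_instances = TRUE)
  max_gain <- max(vapply(probe$trees[[1]]$nodes,
                         function(nd) if (nd$leaf) -Inf else nd$gain, 1.0))
  pruned <- fit_reference_booster(xy$X, xy$y,
                                  boosting_params(subsample = 1, colsample_bytree = 1,
                                                  gamma = max_gain * 10 + 1, eta = 0.3),
                                  nrounds = 3)
  expect_equal(sum(gain_importance(pruned)$gain), 0)
})

test_that("halving the learning rate and doubling rounds gives similar training loss", {
  xy <- toy_xy(80, 6, seed = 10)
  logloss <- function(fit) {
    p <- pmin(pmax(predict(fit, xy$X), 1e-9), 1 - 1e-9)
    -mean(xy$y * log(p) + (1 - xy$y) * log(1 - p))
  }
  f1 <- fit_reference_booster(xy$X, xy$y, boosting_params(eta = 0.2, subsample = 1,
                                                          colsample_bytree = 1), nrounds = 40)
  f2 <- fit_reference_booster(xy$X, xy$y, boosting_params(eta = 0.1, subsample = 1,
                                                          colsample_bytree = 1), nrounds = 80)
  expect_lt(abs(logloss(f1) - logloss(f2)) / logloss(f1), 0.1)
})

test_that("training AUC is monotone in rounds on separable data", {
  x <- matrix(seq(-1, 1, length.out = 30), ncol = 1)
  y <- as.integer(x[, 1] > 0)
  aucs <- sapply(c(1, 3, 5, 10), function(r) {
    fit <- fit_reference_booster(x, y, boosting_params(eta = 0.1, max_depth = 1,
                                                       subsample = 1, colsample_bytree = 1),
                                 nrounds = r)
    auc(predict(fit, x), y)
  })
  expect_true(all(diff(aucs) >= 0))
})

test_that("the production path agrees with the reference booster", {
  set.seed(3)
  X <- matrix(rnorm(4000), 200, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- as.integer(X[, 3] + 0.5 * X[, 1] - 0.7 * X[, 10] + rnorm(200, 0, 0.5) > 0)
  params <- boosting_params(eta = 0.03, subsample = 1, colsample_bytree = 1)
  ref <- fit_reference_booster(X, y, params, nrounds = 100)
  prod <- fit_production_model(X, y, params, nrounds = 100)
  rms <- sqrt(mean((predict(ref, X) - predict(prod, X))^2))
  expect_lt(rms, 0.05)
  # the two implementations also agree on which features matter
  expect_equal(gain_importance(ref)$feature[1:2], gain_importance(prod)$feature[1:2])
})

test_that("early stopping tracks the best validation AUC", {
  set.seed(4)
  X <- matrix(rnorm(1200), 120, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.integer(X[, 2] - X[, 5] + rnorm(120, 0, 0.8) > 0)
  tr <- 1:80; va <- 81:120
  m <- fit_production_model(X[tr, ], y[tr], boosting_params(eta = 0.1, patience = 20),
                            validation = list(X = X[va, ], y = y[va]), nrounds = 400)
  trace <- m$evaluation_log$val_auc
  expect_lt(m$best_iteration, 400)
  expect_gte(trace[m$best_iteration], max(trace) - 1e-12)
  expect_gte(trace[m$best_iteration], trace[length(trace)] - 0.01)

  # with validation == training and separable data: stops at or before max
  # rounds with non-decreasing training AUC
  xs <- matrix(seq(-1, 1, length.out = 40), ncol = 1, dimnames = list(NULL, "f1"))
  ys <- as.integer(xs[, 1] > 0)
  m2 <- fit_production_model(xs, ys, boosting_params(eta = 0.3, patience = 10),
                             validation = list(X = xs, y = ys), nrounds = 100)
  expect_lte(m2$best_iteration, 100)
  expect_true(all(diff(m2$evaluation_log$val_auc) >= 0))
})

test_that("ensemble predictions are the mean of member probabilities", {
  xy <- toy_xy(40, 4, seed = 20)
  params <- boosting_params(eta = 0.2, subsample = 1, colsample_bytree = 1)
  fits <- lapply(1:3, function(i) fit_reference_booster(xy$X, xy$y, params, nrounds = 5 * i))
  single <- predict_ensemble(fits[1], xy$X)
  expect_equal(single, predict(fits[[1]], xy$X))
  all3 <- predict_ensemble(fits, xy$X)
  oracle <- (predict(fits[[1]], xy$X) + predict(fits[[2]], xy$X) + predict(fits[[3]], xy$X)) / 3
  expect_equal(all3, oracle, tolerance = 1e-12)
  expect_error(predict_ensemble(list(), xy$X), "at least one")
})

test_that("gain importance sums split gains and ranks deterministically", {
  x <- matrix(c(seq(-1, -0.1, length.out = 10), seq(0.1, 1, length.out = 10),
                rep(0, 20)), ncol = 2)
  y <- rep(c(0L, 1L), each = 10)
  fit <- fit_reference_booster(x, y, boosting_params(eta = 0.3, max_depth = 1,
                                                     subsample = 1, colsample_bytree = 1),
                               nrounds = 1)
  imp <- gain_importance(fit)
  expect_equal(nrow(imp), 1)
  expect_equal(imp$feature, "f1")

  # ensemble importance = sum over members, then rank
  xy <- toy_xy(60, 5, seed = 21)
  params <- boosting_params(eta = 0.2, subsample = 1, colsample_bytree = 1)
  f1 <- fit_reference_booster(xy$X, xy$y, params, nrounds = 4)
  f2 <- fit_reference_booster(xy$X, xy$y, params, nrounds = 8)
  both <- gain_importance(list(f1, f2))
  manual <- f1$gain + f2$gain
  manual <- sort(manual[manual > 0], decreasing = TRUE)
  expect_equal(both$gain, unname(manual))
  expect_equal(both$feature, names(manual))
})

test_that("Top-N selection truncates the ranking", {
  ranking <- tibble::tibble(feature = c("f3", "f1", "f2"), gain = c(3, 2, 1), rank = 1:3)
  expect_equal(select_top_n(ranking, 2), c("f3", "f1"))
  expect_equal(select_top_n(ranking, 1), "f3")
  expect_equal(select_top_n(ranking, 10), c("f3", "f1", "f2"))
  expect_error(select_top_n(ranking, 0), ">= 1")
})
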