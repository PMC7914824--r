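# Model evaluation and selection: AUC, stratified patient-independent
# folds, 5x2-fold hyperparameter search, the 10-model early-stopped CV
# ensemble, the three leakage settings, and the Top-N feature sweep.

#' Area under the ROC curve
#'
#' Rank statistic: the probability that a randomly chosen positive
#' instance outscores a randomly chosen negative one, ties counted one
#' half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (or two-level factor/character, second level
#'   positive).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2L) abort("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified patient-independent fold assignment
#'
#' Patients are shuffled within each class and dealt cyclically into `k`
#' folds, so every patient lies wholly in one fold, fold sizes differ by at
#' most one patient, and each fold's class composition matches the cohort
#' to within one patient.
#'
#' @param patients Tibble with `patient_id` and `label` (one row per
#'   patient).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble `patient_id`, `label`, `fold` (0-based fold index).
#' @export
stratified_patient_folds <- function(patients, k = 10L, seed = 1L) {
  patients <- dplyr::distinct(patients, .data$patient_id, .data$label)
  if (nrow(patients) < k) abort("need at least `k` patients")
  with_local_seed(seed, {
    out <- vector("list", 0L)
    offset <- 0L
    for (cl in sort(unique(patients$label))) {
      ids <- patients$patient_id[patients$label == cl]
      ids <- sample(ids)
      folds <- (offset + seq_along(ids) - 1L) %% k
      out[[cl]] <- tibble::tibble(patient_id = ids, label = cl, fold = folds)
      offset <- (offset + length(ids)) %% k
    }
    dplyr::bind_rows(out) |> dplyr::arrange(.data$patient_id)
  })
}

# Row-level (patient-dependent) fold assignment: a seeded shuffle of the
# data rows dealt cyclically into k folds, ignoring patient identity.
row_folds <- function(n, k, seed) {
  with_local_seed(seed, (sample.int(n) - 1L) %% k)
}

# Fold index per data row under either split mode.
data_fold_ids <- function(data, k, mode, seed) {
  if (mode == "patient_independent") {
    fa <- stratified_patient_folds(data[, c("patient_id", "label")], k, seed)
    fa$fold[match(data$patient_id, fa$patient_id)]
  } else {
    row_folds(nrow(data), k, seed)
  }
}

#' Tune hyperparameters by 5x2-fold cross-validation
#'
#' For each grid row, the data are split into 2 patient-independent folds 5
#' times with different shuffles; models are trained on one fold with the
#' other as early-stopping validation, and the mean out-of-fold AUC over
#' the 10 (split, fold) fits selects the winner (ties: first in grid
#' order).
#'
#' @param data Feature table with `patient_id`, `label` and feature
#'   columns.
#' @param grid Tibble of candidate `max_depth`, `subsample`,
#'   `colsample_bytree` rows.
#' @param params Base [boosting_params()].
#' @param seed Integer seed.
#' @return The winning grid row (tibble) with its mean out-of-fold AUC.
#' @export
tune_hyperparameters <- function(data, grid, params = boosting_params(), seed = 1L) {
  if (!nrow(grid)) abort("`grid` must be non-empty")
  fcols <- feature_cols(data)
  scores <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    p <- params
    p$max_depth <- as.integer(grid$max_depth[gi])
    p$subsample <- grid$subsample[gi]
    p$colsample_bytree <- grid$colsample_bytree[gi]
    aucs <- c()
    for (rep in 1:5) {
      folds <- data_fold_ids(data, 2L, "patient_independent",
                             derive_seed(seed, 100L * gi + rep))
      for (f in 0:1) {
        tr <- data[folds != f, ]; va <- data[folds == f, ]
        if (length(unique(tr$label)) < 2L || length(unique(va$label)) < 2L) next
        m <- fit_production_model(tr[, fcols], tr$label, p,
                                  validation = list(X = va[, fcols], y = va$label),
                                  seed = derive_seed(seed, 7L * gi + rep))
        aucs <- c(aucs, auc(predict(m, va[, fcols]), va$label))
      }
    }
    scores[gi] <- mean(aucs)
  }
  best <- which.max(scores)
  dplyr::bind_cols(grid[best, ], tibble::tibble(mean_val_auc = scores[best]))
}

#' Fit the 10-model cross-validation ensemble
#'
#' The training data are split into `k` folds (patient-independent or
#' patient-dependent); each member model trains on k-1 folds with the
#' held-out fold as its early-stopping validation set, fixing that
#' member's number of trees.
#'
#' @param data Feature table with `patient_id`, `label`, feature columns.
#' @param params [boosting_params()].
#' @param k Number of inner folds (10).
#' @param mode `"patient_independent"` or `"patient_dependent"`.
#' @param seed Integer seed.
#' @return List with `models` (length `k`) and `val_auc` (per-member
#'   validation AUC).
#' @export
fit_cv_ensemble <- function(data, params = boosting_params(), k = 10L,
                            mode = "patient_independent", seed = 1L) {
  fcols <- feature_cols(data)
  folds <- data_fold_ids(data, k, mode, seed)
  models <- vector("list", k)
  val_auc <- rep(NA_real_, k)
  for (f in seq_len(k) - 1L) {
    tr <- data[folds != f, ]; va <- data[folds == f, ]
    if (length(unique(tr$label)) < 2L) {
      abort("a training fold lost one of the classes; use fewer folds or more patients")
    }
    if (length(unique(va$label)) < 2L) {
      # validation AUC undefined: train this member without early stopping
      m <- fit_production_model(tr[, fcols], tr$label, params,
                                seed = derive_seed(seed, f + 1L))
      models[[f + 1L]] <- m
    } else {
      m <- fit_production_model(tr[, fcols], tr$label, params,
                                validation = list(X = va[, fcols], y = va$label),
                                seed = derive_seed(seed, f + 1L))
      models[[f + 1L]] <- m
      val_auc[f + 1L] <- auc(predict(m, va[, fcols]), va$label)
    }
  }
  list(models = models, val_auc = val_auc)
}

binary_task_data <- function(features, task = c("pda_vs_healthy", "chd_vs_healthy")) {
  task <- match.arg(task)
  keep <- if (task == "pda_vs_healthy") c("healthy", "PDA") else c("healthy", "CHD")
  out <- features[features$label %in% keep, ]
  out$label <- factor(out$label, levels = keep)  # second level = positive class
  out
}

#' Run one evaluation setting
#'
#' Outer 10-fold evaluation with an inner 10-model early-stopped ensemble
#' per outer fold, under the three split regimes: Setting 1 splits both
#' loops patient-independently (no identity leakage); Setting 2 keeps the
#' outer loop patient-independent but randomizes the inner (model
#' selection) loop at cycle level; Setting 3 randomizes both. Cycle-level
#' test probabilities are reduced to one probability per patient with
#' [aggregate_probabilities()], and the test AUC is computed once over
#' the pooled out-of-fold patient probabilities.
#'
#' @param features Cycle-level feature table from [extract_features()]
#'   (optionally with patient-level aggregation applied via `spec`).
#' @param setting 1, 2 or 3.
#' @param spec [aggregation_spec()] for feature- and decision-level
#'   aggregation.
#' @param params [boosting_params()].
#' @param task `"pda_vs_healthy"` or `"chd_vs_healthy"`; the third class is
#'   excluded.
#' @param grid Optional tuning grid forwarded to [tune_hyperparameters()]
#'   inside each outer training set; `NULL` skips tuning and uses `params`.
#' @param k_outer,k_inner Fold counts (10 each).
#' @param seed Integer seed.
#' @return A `pcg_eval` object.
#' @export
run_setting <- function(features, setting = 1L, spec = aggregation_spec(),
                        params = boosting_params(),
                        task = "pda_vs_healthy", grid = NULL,
                        k_outer = 10L, k_inner = 10L, seed = 1L) {
  if (!setting %in% 1:3) abort("`setting` must be 1, 2 or 3")
  outer_mode <- if (setting == 3L) "patient_dependent" else "patient_independent"
  inner_mode <- if (setting == 1L) "patient_independent" else "patient_dependent"
  data <- binary_task_data(aggregate_features(features, spec), task)
  fcols <- feature_cols(data)
  outer <- data_fold_ids(data, k_outer, outer_mode, derive_seed(seed, 11L))
  val_aucs <- c()
  test_rows <- list()
  chosen <- NULL
  all_models <- list()
  for (f in seq_len(k_outer) - 1L) {
    tr <- data[outer != f, ]; te <- data[outer == f, ]
    p <- params
    if (!is.null(grid)) {
      chosen <- tune_hyperparameters(tr, grid, params, derive_seed(seed, 23L + f))
      p$max_depth <- as.integer(chosen$max_depth)
      p$subsample <- chosen$subsample
      p$colsample_bytree <- chosen$colsample_bytree
    }
    ens <- fit_cv_ensemble(tr, p, k_inner, inner_mode, derive_seed(seed, 37L + f))
    val_aucs <- c(val_aucs, ens$val_auc)
    all_models <- c(all_models, ens$models)
    prob <- predict_ensemble(ens$models, te[, fcols])
    test_rows[[f + 1L]] <- tibble::tibble(
      patient_id = te$patient_id,
      point_id = if ("point_id" %in% names(te)) te$point_id else 1L,
      label = as.character(te$label), prob = prob)
  }
  preds <- dplyr::bind_rows(test_rows)
  patient_probs <- preds |>
    dplyr::group_by(.data$patient_id, .data$label) |>
    dplyr::group_map(function(g, key) {
      dplyr::bind_cols(key, tibble::tibble(prob = aggregate_probabilities(g, spec)))
    }) |>
    dplyr::bind_rows()
  test_auc <- auc(patient_probs$prob,
                  factor(patient_probs$label, levels = levels(data$label)))
  structure(
    list(setting = setting, task = task, spec = spec, params = params,
         chosen = chosen,
         val_auc_mean = mean(val_aucs, na.rm = TRUE),
         val_auc_sd = sd(val_aucs, na.rm = TRUE),
         test_auc = test_auc,
         patient_probs = patient_probs, cycle_probs = preds,
         models = all_models, seed = seed),
    class = "pcg_eval"
  )
}

#' @export
print.pcg_eval <- function(x, ...) {
  cat(sprintf("<pcg_eval> setting %d, %s, %s\n", x$setting, x$task, x$spec$mode))
  cat(sprintf("  validation AUC %.3f +/- %.3f | test AUC %.3f (%d patients)\n",
              x$val_auc_mean, x$val_auc_sd, x$test_auc, nrow(x$patient_probs)))
  invisible(x)
}

#' @export
tidy.pcg_eval <- function(x, ...) x$patient_probs

#' @export
glance.pcg_eval <- function(x, ...) {
  tibble::tibble(setting = x$setting, task = x$task, mode = x$spec$mode,
                 val_auc_mean = x$val_auc_mean, val_auc_sd = x$val_auc_sd,
                 test_auc = x$test_auc, n_patients = nrow(x$patient_probs))
}

#' Top-N feature-reduction sweep
#'
#' Runs the full-feature evaluation, ranks features by cumulative gain over
#' all its ensemble members, then re-runs the evaluation restricted to the
#' Top-N features for each N.
#'
#' @param features Cycle-level feature table.
#' @param n_list Feature-set sizes to sweep.
#' @param spec,params,task,k_outer,k_inner,seed As in [run_setting()].
#' @return List with `full` (the full-feature `pcg_eval`), `ranking` (gain
#'   importance tibble), and `results` (tibble with one row per N:
#'   validation and test AUC).
#' @export
run_topn_sweep <- function(features, n_list = c(60, 30, 15, 10, 5),
                           spec = aggregation_spec(), params = boosting_params(),
                           task = "pda_vs_healthy", k_outer = 10L, k_inner = 10L,
                           seed = 1L) {
  full <- run_setting(features, 1L, spec, params, task,
                      k_outer = k_outer, k_inner = k_inner, seed = seed)
  ranking <- gain_importance(full$models)
  id_cols <- intersect(names(features),
                       c("patient_id", "point_id", "cycle_index", "label"))
  all_fcols <- feature_cols(features)
  rows <- lapply(n_list, function(n) {
    # N covering the whole census reproduces the full-feature run exactly
    keep <- if (n >= length(all_fcols)) all_fcols else select_top_n(ranking, n)
    sub <- features[, c(id_cols, keep)]
    ev <- run_setting(sub, 1L, spec, params, task,
                      k_outer = k_outer, k_inner = k_inner, seed = seed)
    tibble::tibble(n_features = length(keep),
                   val_auc_mean = ev$val_auc_mean, val_auc_sd = ev$val_auc_sd,
                   test_auc = ev$test_auc)
  })
  results <- dplyr::bind_rows(
    tibble::tibble(n_features = length(feature_cols(features)),
                   val_auc_mean = full$val_auc_mean, val_auc_sd = full$val_auc_sd,
                   test_auc = full$test_auc),
    dplyr::bind_rows(rows))
  list(full = full, ranking = ranking, results = results)
}
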