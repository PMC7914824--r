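# Combining cycle-level information across cycles and auscultation points,
# at the feature level (before the model) or at the decision level (after).

feature_cols <- function(tbl) {
  setdiff(names(tbl), c("patient_id", "point_id", "cycle_index", "label"))
}

#' Aggregation specification
#'
#' `mode` picks the feature-level design: `cycle_level_baseline` feeds raw
#' cycle vectors to the model and pools every cycle probability of a
#' patient; `mean_of_features` averages all cycles of a patient (across
#' points) into one vector; `concat_per_point` averages per point and
#' concatenates the five point vectors. The decision rules reduce cycle
#' probabilities within a point and then across the patient.
#'
#' @param mode One of `"cycle_level_baseline"`, `"mean_of_features"`,
#'   `"concat_per_point"`.
#' @param decision_rule_point `"mean"`, `"max"`, or `"none"` (pool cycles).
#' @param decision_rule_patient `"mean"` or `"max"`.
#' @return An `aggregation_spec` list.
#' @export
aggregation_spec <- function(mode = c("cycle_level_baseline", "mean_of_features",
                                      "concat_per_point"),
                             decision_rule_point = c("none", "mean", "max"),
                             decision_rule_patient = c("mean", "max")) {
  structure(list(mode = match.arg(mode),
                 decision_rule_point = match.arg(decision_rule_point),
                 decision_rule_patient = match.arg(decision_rule_patient)),
            class = "aggregation_spec")
}

#' Mean feature vector of one patient
#'
#' Element-wise arithmetic mean over all of a patient's cycle feature
#' vectors, across all auscultation points.
#'
#' @param patient_cycles Feature rows of one patient.
#' @return Named numeric vector (200 entries).
#' @export
mean_of_features <- function(patient_cycles) {
  fcols <- feature_cols(patient_cycles)
  if (nrow(patient_cycles) < 1L) abort("at least one cycle is required")
  colMeans(as.matrix(patient_cycles[, fcols]))
}

#' Concatenated per-point mean vectors of one patient
#'
#' Cycle features are averaged separately per auscultation point and the
#' five point means concatenated in point order 1..5 with `p<k>_` name
#' prefixes, yielding 1000 entries.
#'
#' @param patient_cycles Feature rows of one patient (all 5 points).
#' @return Named numeric vector (1000 entries).
#' @export
concat_per_point <- function(patient_cycles) {
  fcols <- feature_cols(patient_cycles)
  missing_pts <- setdiff(1:5, unique(patient_cycles$point_id))
  if (length(missing_pts)) {
    abort(sprintf("auscultation point %s missing for patient %s",
                  paste(missing_pts, collapse = ", "),
                  patient_cycles$patient_id[1]))
  }
  out <- lapply(1:5, function(pt) {
    v <- colMeans(as.matrix(patient_cycles[patient_cycles$point_id == pt, fcols]))
    setNames(v, paste0("p", pt, "_", fcols))
  })
  unlist(out)
}

#' Patient-level feature table under an aggregation mode
#'
#' Applies the feature-level design of an [aggregation_spec()] to a
#' cycle-level feature table. The baseline mode returns the table
#' unchanged (aggregation then happens at the decision level).
#'
#' @param features Cycle-level feature table from [extract_features()].
#' @param spec An [aggregation_spec()] (or a mode string).
#' @return A tibble: unchanged for the baseline; otherwise one row per
#'   patient with `patient_id`, `label` and 200 or 1000 feature columns.
#' @export
aggregate_features <- function(features, spec = aggregation_spec()) {
  if (is.character(spec)) spec <- aggregation_spec(spec)
  if (spec$mode == "cycle_level_baseline") return(features)
  agg_fun <- if (spec$mode == "mean_of_features") mean_of_features else concat_per_point
  rows <- features |>
    dplyr::group_by(.data$patient_id, .data$label) |>
    dplyr::group_map(function(g, key) {
      g$patient_id <- key$patient_id
      dplyr::bind_cols(key, tibble::as_tibble(as.list(agg_fun(g))))
    })
  dplyr::bind_rows(rows)
}

#' Aggregate cycle probabilities into one patient probability
#'
#' Applies `decision_rule_point` to the cycle probabilities within each
#' auscultation point (or pools all cycles when the rule is `"none"`),
#' then `decision_rule_patient` across the resulting values.
#'
#' @param cycle_probs Tibble with columns `point_id` and `prob`, one row
#'   per cycle, or a named list mapping point ids to probability vectors.
#' @param spec An [aggregation_spec()].
#' @return A single probability in \[0, 1\].
#' @export
aggregate_probabilities <- function(cycle_probs, spec = aggregation_spec()) {
  if (is.list(cycle_probs) && !is.data.frame(cycle_probs)) {
    cycle_probs <- tibble::tibble(
      point_id = rep(as.integer(names(cycle_probs)), lengths(cycle_probs)),
      prob = unlist(cycle_probs, use.names = FALSE))
  }
  if (nrow(cycle_probs) == 0L) abort("no probabilities to aggregate")
  if (any(cycle_probs$prob < 0 | cycle_probs$prob > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  rule <- function(name) switch(name, mean = mean, max = max)
  vals <- if (spec$decision_rule_point == "none") {
    cycle_probs$prob
  } else {
    f <- rule(spec$decision_rule_point)
    tapply(cycle_probs$prob, cycle_probs$point_id, f)
  }
  rule(spec$decision_rule_patient)(vals)
}
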