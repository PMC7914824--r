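# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A small mixed cohort with clear murmurs (4 healthy / 3 PDA / 2 CHD).
small_cohort <- function() {
  cached("small_cohort", function() {
    simulate_cohort(4, 3, 2, sim_params(cycles_per_point = 3), seed = 11)
  })
}

small_features <- function() {
  cached("small_features", function() extract_features(small_cohort()))
}

# Full-size study cohort (60 healthy / 40 PDA / 20 CHD, murmur gain 3) and
# its Setting-1 evaluation; built once and shared by the acceptance checks.
study_features <- function() {
  cached("study_features", function() {
    extract_features(simulate_cohort(60, 40, 20, sim_params(), seed = 2024))
  })
}

study_setting1 <- function() {
  cached("study_setting1", function() {
    run_setting(study_features(), 1, aggregation_spec(), boosting_params(),
                task = "pda_vs_healthy", seed = 2024)
  })
}

# One segmented PDA patient for per-cycle feature checks.
one_patient <- function() {
  cached("one_patient", function() simulate_patient("PX", "PDA", sim_params(), 5))
}

# A valid 2-cycle segmentation table.
toy_segmentation <- function(patient_id = "P1", point_id = 1L) {
  tibble::tibble(
    patient_id = patient_id, point_id = as.integer(point_id),
    cycle_index = 1:2,
    s1_start = c(0, 840), m1_start = c(140, 980),
    s2_start = c(380, 1220), m2_start = c(480, 1320),
    cycle_end = c(840, 1680))
}

# Seeded feature matrix + separable labels for booster checks.
toy_xy <- function(n = 50, p = 8, seed = 1, noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.integer(X[, 3] + 0.5 * X[, 1] + rnorm(n, 0, noise) > 0)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}

# O(n^2) pairwise AUC oracle (ties count one half).
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}

# In-band energy of an interval, computed with the package band-pass.
band_energy <- function(x, band = c(200, 400), rate = 2000) {
  sum(bandpass_filter(x, rate, band[1], band[2])^2)
}

# Slice interval samples out of a patient-row recording.
interval_samples <- function(rec, seg_row, which = "m1") {
  idx <- switch(which,
                S1 = (seg_row$s1_start + 1):seg_row$m1_start,
                m1 = (seg_row$m1_start + 1):seg_row$s2_start,
                S2 = (seg_row$s2_start + 1):seg_row$m2_start,
                m2 = (seg_row$m2_start + 1):seg_row$cycle_end)
  rec$samples[idx]
}
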