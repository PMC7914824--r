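# Synthetic neonatal phonocardiogram simulator.
#
# Generates labelled cohorts with ground-truth segmentation so the whole
# pipeline is testable without clinical recordings. Each heartbeat cycle at
# the 2 kHz analysis rate consists of S1 and S2 valve-closure transients
# (exponentially decaying sinusoid bursts near 90 and 110 Hz) separated by
# the systolic (m1) and diastolic (m2) silent intervals. CHD patients carry
# a band-limited systolic murmur (m1 only); PDA patients a continuous
# murmur (m1 and m2), loudest at the pulmonic auscultation point. Murmur
# noise is shaped with the same Butterworth band-pass operator the feature
# extractor uses, so generator and analyser agree on what "in band" means.

#' Simulation parameters
#'
#' Defaults emulate a term / late-preterm neonatal cohort: heart rate
#' 143 bpm (cycle ~ 0.42 s), S1 70 ms, S2 50 ms, murmur band 200–400 Hz,
#' additive white recording noise of sd 0.01 (full-scale units), five
#' cycles per auscultation point, and PDA/CHD murmurs loudest at the
#' pulmonic point (point 2).
#'
#' @param heart_rate_mean,heart_rate_sd Heart rate distribution (beats/min).
#' @param s1_duration,s2_duration Transient durations (seconds).
#' @param murmur_band Murmur band edges in Hz, within (0, 1000].
#' @param murmur_gain Murmur loudness relative to the recording noise sd
#'   (>= 0; 0 disables the murmur).
#' @param noise_sd Additive white noise sd (dimensionless amplitude).
#' @param point_gains Five per-point murmur loudness multipliers.
#' @param cycles_per_point Cycles simulated per point (>= 2).
#' @param rate Sampling rate; the analysis rate of 2000 Hz.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(heart_rate_mean = 143, heart_rate_sd = 7,
                       s1_duration = 0.070, s2_duration = 0.050,
                       murmur_band = c(200, 400), murmur_gain = 3,
                       noise_sd = 0.01,
                       point_gains = c(0.7, 1, 0.7, 0.7, 0.7),
                       cycles_per_point = 5L, rate = 2000) {
  p <- list(heart_rate_mean = heart_rate_mean, heart_rate_sd = heart_rate_sd,
            s1_duration = s1_duration, s2_duration = s2_duration,
            murmur_band = murmur_band, murmur_gain = murmur_gain,
            noise_sd = noise_sd, point_gains = point_gains,
            cycles_per_point = as.integer(cycles_per_point), rate = rate)
  if (p$cycles_per_point < 2L) abort("`cycles_per_point` must be >= 2")
  if (length(p$murmur_band) != 2L || p$murmur_band[1] <= 0 || p$murmur_band[2] > 1000 ||
      p$murmur_band[1] >= p$murmur_band[2]) {
    abort("`murmur_band` must be (lo, hi) within (0, 1000] Hz")
  }
  if (p$murmur_gain < 0 || any(p$point_gains < 0)) abort("gains must be >= 0")
  if (length(p$point_gains) != 5L) abort("`point_gains` must have 5 entries")
  structure(p, class = "sim_params")
}

decaying_burst <- function(n, freq, rate, amplitude, tau) {
  t <- (seq_len(n) - 1L) / rate
  phase <- runif(1, 0, 2 * pi)
  amplitude * exp(-t / tau) * sin(2 * pi * freq * t + phase)
}

band_noise <- function(n, band, rate, target_sd) {
  if (target_sd <= 0 || n < 8L) return(numeric(n))
  w <- bandpass_filter(rnorm(n), rate, band[1], band[2])
  s <- sd(w)
  if (s < db_floor_eps) return(numeric(n))
  w * (target_sd / s)
}

#' Simulate one heartbeat cycle
#'
#' Draws the cycle duration from the heart-rate distribution (truncated to
#' 60–250 bpm), lays out S1 / m1 / S2 / m2 (systole takes 40% of the
#' non-transient time), synthesizes the transients and additive noise, and
#' injects the murmur according to the label. Uses the current RNG state;
#' seed externally for reproducibility.
#'
#' @param label One of `"healthy"`, `"PDA"`, `"CHD"`.
#' @param params [sim_params()].
#' @param point_gain Murmur loudness multiplier for the auscultation point.
#' @return List with `samples` (numeric) and `cycle` (one segmentation row
#'   of 0-based boundaries `s1_start`, `m1_start`, `s2_start`, `m2_start`,
#'   `cycle_end`).
#' @export
simulate_cycle <- function(label, params = sim_params(), point_gain = 1) {
  label <- match.arg(label, c("healthy", "PDA", "CHD"))
  rate <- params$rate
  hr <- min(max(rnorm(1, params$heart_rate_mean, params$heart_rate_sd), 60), 250)
  n <- round(60 / hr * rate)
  n_s1 <- round(params$s1_duration * rate)
  n_s2 <- round(params$s2_duration * rate)
  rem <- n - n_s1 - n_s2
  n_m1 <- round(0.4 * rem)
  n_m2 <- n - n_s1 - n_m1 - n_s2
  stopifnot(n_m1 >= 2L, n_m2 >= 2L)
  x <- rnorm(n, 0, params$noise_sd)
  i_s1 <- seq_len(n_s1)
  i_m1 <- n_s1 + seq_len(n_m1)
  i_s2 <- n_s1 + n_m1 + seq_len(n_s2)
  i_m2 <- n_s1 + n_m1 + n_s2 + seq_len(n_m2)
  x[i_s1] <- x[i_s1] + decaying_burst(n_s1, 90, rate, 0.8, params$s1_duration / 4)
  x[i_s2] <- x[i_s2] + decaying_burst(n_s2, 110, rate, 0.6, params$s2_duration / 4)
  murmur_sd <- params$murmur_gain * point_gain * params$noise_sd
  if (label == "CHD") {
    x[i_m1] <- x[i_m1] + band_noise(n_m1, params$murmur_band, rate, murmur_sd)
  } else if (label == "PDA") {
    x[i_m1] <- x[i_m1] + band_noise(n_m1, params$murmur_band, rate, murmur_sd)
    x[i_m2] <- x[i_m2] + band_noise(n_m2, params$murmur_band, rate, murmur_sd)
  }
  cycle <- tibble::tibble(s1_start = 0L, m1_start = n_s1,
                          s2_start = n_s1 + n_m1, m2_start = n_s1 + n_m1 + n_s2,
                          cycle_end = n)
  list(samples = x, cycle = cycle)
}

#' Simulate one patient
#'
#' Five auscultation points with `cycles_per_point` consecutive cycles
#' each; the murmur at point k is scaled by `point_gains[k]` (pulmonic
#' point loudest by default, where a PDA's continuous murmur is best
#' heard). All randomness flows through one generator seeded per patient.
#'
#' @param patient_id Identifier string.
#' @param label `"healthy"`, `"PDA"` or `"CHD"`.
#' @param params [sim_params()].
#' @param seed Integer seed for this patient.
#' @return A tibble with one row per point: `patient_id`, `label`,
#'   `point_id`, `recording` (list of [pcg_recording()]), `segmentation`
#'   (list of segmentation tibbles).
#' @export
simulate_patient <- function(patient_id, label, params = sim_params(), seed = 1L) {
  with_local_seed(seed, {
    rows <- lapply(1:5, function(pt) {
      samples <- numeric(0)
      segs <- vector("list", params$cycles_per_point)
      offset <- 0L
      for (ci in seq_len(params$cycles_per_point)) {
        cyc <- simulate_cycle(label, params, params$point_gains[pt])
        seg <- cyc$cycle
        seg[1, ] <- seg[1, ] + offset
        segs[[ci]] <- tibble::tibble(patient_id = patient_id, point_id = pt,
                                     cycle_index = ci) |>
          dplyr::bind_cols(seg)
        samples <- c(samples, cyc$samples)
        offset <- offset + length(cyc$samples)
      }
      tibble::tibble(
        patient_id = patient_id, label = label, point_id = pt,
        recording = list(pcg_recording(samples, params$rate, patient_id, pt)),
        segmentation = list(dplyr::bind_rows(segs))
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a labelled cohort
#'
#' @param n_healthy,n_pda,n_chd Patient counts per diagnosis group.
#' @param params [sim_params()].
#' @param seed Master seed; per-patient seeds are derived deterministically.
#' @return Cohort tibble (rows = patient x point; see [simulate_patient()]).
#' @export
simulate_cohort <- function(n_healthy, n_pda, n_chd, params = sim_params(), seed = 1L) {
  if (n_healthy < 0 || n_pda < 0 || n_chd < 0) abort("counts must be >= 0")
  total <- n_healthy + n_pda + n_chd
  if (total == 0) abort("at least one patient is required")
  labels <- c(rep("healthy", n_healthy), rep("PDA", n_pda), rep("CHD", n_chd))
  rows <- lapply(seq_len(total), function(i) {
    simulate_patient(sprintf("P%04d", i), labels[i], params, derive_seed(seed, i))
  })
  dplyr::bind_rows(rows)
}

#' Write / read a cohort as WAV + CSV trees
#'
#' One directory per patient containing `point_<k>.wav` and
#' `segmentation.csv`, plus a top-level `labels.csv` (`patient_id, label`);
#' everything is re-loadable with the package's own readers.
#'
#' @param cohort Cohort tibble.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- dplyr::distinct(cohort, .data$patient_id, .data$label)
  readr::write_csv(labels, file.path(dir, "labels.csv"), progress = FALSE)
  for (pid in unique(cohort$patient_id)) {
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    sub <- cohort[cohort$patient_id == pid, ]
    for (i in seq_len(nrow(sub))) {
      save_recording(sub$recording[[i]],
                     file.path(pdir, sprintf("point_%d.wav", sub$point_id[i])))
    }
    save_segmentation(dplyr::bind_rows(sub$segmentation), file.path(pdir, "segmentation.csv"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  labels <- readr::read_csv(file.path(dir, "labels.csv"), show_col_types = FALSE,
                            progress = FALSE)
  rows <- list()
  for (i in seq_len(nrow(labels))) {
    pid <- labels$patient_id[i]
    pdir <- file.path(dir, pid)
    seg_all <- load_segmentation(file.path(pdir, "segmentation.csv"))
    for (pt in sort(unique(seg_all$point_id))) {
      rec <- load_recording(file.path(pdir, sprintf("point_%d.wav", pt)), pid, pt)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, label = labels$label[i], point_id = pt,
        recording = list(rec),
        segmentation = list(seg_all[seg_all$point_id == pt, ])
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Inject patient-specific feature offsets
#'
#' Adds, per patient, a constant offset to every feature column drawn from
#' `N(0, (offset_sd * column sd)^2)`. This makes individual patients
#' recognizable from their cycles — a controlled stand-in for
#' patient-identity confounds — and is used to demonstrate how
#' patient-dependent data splits leak identity information and inflate
#' apparent performance.
#'
#' @param features Cycle-level feature table from [extract_features()].
#' @param offset_sd Offset scale relative to each feature's cohort sd.
#' @param seed Integer seed.
#' @return The feature table with offsets added.
#' @export
inject_patient_offsets <- function(features, offset_sd = 2, seed = 1L) {
  fcols <- setdiff(names(features), c("patient_id", "point_id", "cycle_index", "label"))
  pids <- unique(features$patient_id)
  col_sd <- vapply(features[fcols], sd, 1.0)
  col_sd[!is.finite(col_sd)] <- 0
  with_local_seed(seed, {
    for (pid in pids) {
      rows <- features$patient_id == pid
      offs <- rnorm(length(fcols), 0, offset_sd * col_sd)
      features[rows, fcols] <- sweep(features[rows, fcols], 2, offs, "+")
    }
  })
  features
}
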