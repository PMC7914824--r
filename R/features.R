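# Per-cycle feature extraction.
#
# 200 features per segmented heartbeat cycle at the 2 kHz analysis rate:
#   - a common block for all four intervals (S1, m1, S2, m2): raw energy and
#     zero-crossings, wide-band (25-1000 Hz) and five sub-band
#     (25-45, 45-80, 80-200, 200-400, 400-1000 Hz) energies and RMS in
#     linear and dB scale, spectral centroid below 200 Hz, its octave
#     deviation from the per-point average, and relative interval length;
#   - an S1/S2 block of extrema and zero-crossing timing statistics;
#   - an m1/m2 block of envelope polynomial coefficients, quarter-wise
#     energy/mean/sd profiles, zeros per second and position skewness;
#   - two per-point globals: beats per minute and relative cycle length.

pcg_bands <- list(b1 = c(25, 45), b2 = c(45, 80), b3 = c(80, 200),
                  b4 = c(200, 400), b5 = c(400, 1000))
pcg_wide_band <- c(25, 1000)

# Butterworth coefficient cache (design is deterministic; cache per band/rate).
.filter_cache <- new.env(parent = emptyenv())

butter_coeffs <- function(rate, lo, hi) {
  key <- paste(rate, lo, hi, sep = "|")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  ny <- rate / 2
  flt <- if (lo <= 0) {
    signal::butter(4, hi / ny, type = "low")
  } else if (hi >= ny) {
    signal::butter(4, lo / ny, type = "high")
  } else {
    signal::butter(4, c(lo, hi) / ny, type = "pass")
  }
  .filter_cache[[key]] <- flt
  flt
}

#' Zero-phase Butterworth band-pass
#'
#' 4th-order Butterworth applied forward-backward (zero phase). When `hi`
#' reaches the Nyquist frequency the filter degrades to a high-pass at `lo`
#' (the 400–1000 Hz sub-band at a 2 kHz rate); when `lo <= 0` it degrades
#' to a low-pass at `hi`. Output length equals input length.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate (Hz).
#' @param lo,hi Band edges in Hz, `0 <= lo < hi`.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, rate, lo, hi) {
  if (lo < 0 || hi <= lo) abort("band edges must satisfy 0 <= lo < hi")
  as.double(signal::filtfilt(butter_coeffs(rate, lo, hi), x))
}

#' Energy and RMS of a signal
#'
#' Energy is the sum of squared values, RMS its per-sample root mean; dB
#' variants use `10 log10(value + 1e-12)` so silence maps to the -120 dB
#' floor.
#'
#' @param x Numeric signal.
#' @return Named list `energy`, `rms`, `energy_db`, `rms_db`.
#' @export
energy_and_rms <- function(x) {
  energy <- sum(x^2)
  rms <- sqrt(energy / length(x))
  list(energy = energy, rms = rms,
       energy_db = to_db(energy), rms_db = to_db(rms))
}

#' Count zero crossings
#'
#' A crossing is counted when consecutive samples have opposite strict
#' signs, or when a run of exact zeros separates samples of opposite signs
#' (counted once).
#'
#' @param x Numeric signal, length >= 2.
#' @return Integer crossing count.
#' @export
zero_crossing_count <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

# 0-based sample indices (first of each crossing pair, or the last nonzero
# sample before a zero run) where the signal crosses zero.
zero_crossing_positions <- function(x) {
  nz <- which(sign(x) != 0)
  if (length(nz) < 2L) return(integer(0))
  s <- sign(x[nz])
  nz[which(diff(s) != 0)] - 1L
}

#' Spectral centroid below 200 Hz
#'
#' Magnitude-weighted mean frequency over DFT bins in (0, 200] Hz; the DC
#' bin is excluded. Returns 0 when the total in-band magnitude is
#' negligible (degenerate convention).
#'
#' @param x Numeric signal, length >= 8.
#' @param rate Sampling rate (Hz).
#' @return Centroid in Hz.
#' @export
spectral_centroid_0_200 <- function(x, rate) {
  n <- length(x)
  if (n < 8L) abort("spectral centroid needs length >= 8")
  mag <- Mod(fft(x))
  freqs <- (seq_len(n) - 1L) / n * rate
  keep <- freqs > 0 & freqs <= 200 & seq_len(n) <= floor(n / 2) + 1L
  w <- mag[keep]
  if (sum(w) < db_floor_eps) return(0)
  sum(freqs[keep] * w) / sum(w)
}

#' Octave deviation of a centroid from a reference
#'
#' `log2(fc / fc_ref)`; by convention 0 when `fc <= 0` (silent interval).
#'
#' @param fc Centroid (Hz).
#' @param fc_ref Reference centroid (Hz), must be positive.
#' @return Deviation in octaves.
#' @export
octave_deviation <- function(fc, fc_ref) {
  if (fc_ref <= 0) abort("`fc_ref` must be positive")
  if (fc <= 0) return(0)
  log2(fc / fc_ref)
}

# Analytic-signal envelope: FFT Hilbert transform, magnitude, then a 10 ms
# moving average to remove carrier ripple.
signal_envelope <- function(x, rate = 2000) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(fft(X * h, inverse = TRUE) / n)
  w <- max(1L, round(0.010 * rate))
  if (w > 1L) {
    xp <- c(rep(env[1], w), env, rep(env[n], w))  # replicate-pad the edges
    sm <- stats::filter(xp, rep(1 / w, w), sides = 2)
    env <- as.double(sm[(w + 1L):(w + n)])
  }
  env
}

#' Quadratic envelope approximation
#'
#' Least-squares fit of `a0 + a1 t + a2 t^2` (t normalized to \[0, 1\]) to
#' the smoothed analytic-signal envelope.
#'
#' @param x Numeric signal, length >= 4.
#' @param rate Sampling rate (Hz), used for the 10 ms smoothing window.
#' @return Numeric `c(a0, a1, a2)`.
#' @export
envelope_poly_coeffs <- function(x, rate = 2000) {
  n <- length(x)
  if (n < 4L) abort("envelope fit needs length >= 4")
  env <- signal_envelope(x, rate)
  t <- (seq_len(n) - 1L) / (n - 1L)
  fit <- stats::lm.fit(cbind(1, t, t^2), env)
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0
  coefs
}

# Run-length local extrema: a run strictly above (below) both neighbouring
# runs is a maximum (minimum), located at the first sample of the run.
local_extrema <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(list(max = integer(0), min = integer(0)))
  starts <- cumsum(c(1L, r$lengths[-k]))
  inner <- 2:(k - 1L)
  v <- r$values
  is_max <- v[inner] > v[inner - 1L] & v[inner] > v[inner + 1L]
  is_min <- v[inner] < v[inner - 1L] & v[inner] < v[inner + 1L]
  list(max = starts[inner][is_max] - 1L, min = starts[inner][is_min] - 1L)  # 0-based
}

timing_stats <- function(pos0, n) {
  # pos0: 0-based sample indices of events; times normalized by interval length
  t <- pos0 / (n - 1L)
  m_t <- if (length(t)) mean(t) else 0
  s_t <- if (length(t) >= 2L) sd(t) else 0
  dt <- diff(t)
  m_dt <- if (length(dt)) mean(dt) else 0
  s_dt <- if (length(dt) >= 2L) sd(dt) else 0
  c(mean_t = m_t, sd_t = s_t, mean_dt = m_dt, sd_dt = s_dt)
}

#' Extrema and zero-crossing timing statistics
#'
#' Absolute extrema (value and normalized time of the maximum, minimum, and
#' maximum absolute value), local-extrema statistics (mean/sd of normalized
#' times and of successive time differences, counts) for maxima and minima,
#' and the same timing statistics for zero crossings. Local extrema are
#' samples strictly greater (smaller) than both neighbours; plateaus count
#' once at their first sample. Undefined statistics of degenerate inputs
#' (e.g. a constant) are 0.
#'
#' @param x Numeric signal, length >= 3.
#' @return Named list of the statistics.
#' @export
extrema_timing_stats <- function(x) {
  n <- length(x)
  if (n < 3L) abort("extrema statistics need length >= 3")
  denom <- n - 1L
  i_max <- which.max(x); i_min <- which.min(x); i_abs <- which.max(abs(x))
  ext <- local_extrema(x)
  tmx <- timing_stats(ext$max, n)
  tmn <- timing_stats(ext$min, n)
  tz <- timing_stats(zero_crossing_positions(x), n)
  list(
    a_max = x[i_max], t_max = (i_max - 1L) / denom,
    a_min = x[i_min], t_min = (i_min - 1L) / denom,
    max_a = abs(x[i_abs]), max_t = (i_abs - 1L) / denom,
    mean_t_max = unname(tmx["mean_t"]), mean_dt_max = unname(tmx["mean_dt"]),
    std_t_max = unname(tmx["sd_t"]), std_dt_max = unname(tmx["sd_dt"]),
    n_max = length(ext$max),
    mean_t_min = unname(tmn["mean_t"]), mean_dt_min = unname(tmn["mean_dt"]),
    std_t_min = unname(tmn["sd_t"]), std_dt_min = unname(tmn["sd_dt"]),
    n_min = length(ext$min),
    mean_t_zero = unname(tz["mean_t"]), std_t_zero = unname(tz["sd_t"]),
    mean_dt_zero = unname(tz["mean_dt"]), std_dt_zero = unname(tz["sd_dt"])
  )
}

#' Quarter-wise energy and amplitude profile
#'
#' The interval is split into four contiguous quarters (remainder samples go
#' to the last quarter); per-quarter energy, mean and standard deviation are
#' returned together with the whole-interval mean and standard deviation.
#'
#' @param x Numeric signal, length >= 4.
#' @return Named list of 14 values.
#' @export
quarter_profile <- function(x) {
  n <- length(x)
  if (n < 4L) abort("quarter profile needs length >= 4")
  q <- n %/% 4L
  bounds <- c(0L, q, 2L * q, 3L * q, n)
  parts <- lapply(1:4, function(i) x[(bounds[i] + 1L):bounds[i + 1L]])
  sd0 <- function(v) if (length(v) >= 2L) sd(v) else 0
  out <- list()
  for (i in 1:4) out[[paste0("en_q", i)]] <- sum(parts[[i]]^2)
  out$mean <- mean(x)
  out$std <- sd0(x)
  for (i in 1:4) out[[paste0("mean_q", i)]] <- mean(parts[[i]])
  for (i in 1:4) out[[paste0("std_q", i)]] <- sd0(parts[[i]])
  out
}

#' Relative position of the maximum absolute value
#'
#' `2 i*/(n-1) - 1` with `i*` the 0-based index of the maximum absolute
#' value (first occurrence on ties): -1 at the first sample, 0 at the
#' midpoint, +1 at the last sample.
#'
#' @param x Numeric signal, length >= 2.
#' @return Value in \[-1, 1\].
#' @export
position_skewness <- function(x) {
  n <- length(x)
  if (n < 2L) abort("position skewness needs length >= 2")
  2 * (which.max(abs(x)) - 1L) / (n - 1L) - 1
}

#' Count derivative discontinuities
#'
#' Samples whose second difference exceeds `k` times the MAD of the
#' second-difference sequence are flagged; contiguous runs of flagged
#' samples count once.
#'
#' @param x Numeric signal, length >= 4.
#' @param k Threshold multiplier (default 4).
#' @return Integer count.
#' @export
derivative_discontinuity_count <- function(x, k = 4) {
  if (length(x) < 4L) abort("discontinuity count needs length >= 4")
  d2 <- diff(x, differences = 2L)
  # absolute floor guards against counting floating-point jitter on
  # piecewise-exact signals where the MAD collapses to zero
  thr <- max(k * mad(d2), 1e-8 * max(abs(x), 1e-300))
  exceed <- abs(d2) > thr
  r <- rle(exceed)
  sum(r$values)
}

#' Zero crossings per second
#'
#' @param x Numeric signal, length >= 2.
#' @param rate Sampling rate (Hz).
#' @return Crossings per second.
#' @export
frq_zero <- function(x, rate) {
  zero_crossing_count(x) * rate / length(x)
}

# ---- feature vector assembly ------------------------------------------------

common_tags <- c(
  "energy", "n_zero",
  "bw_en_lin", "bw_en_db", "bw_rms_lin", "bw_rms_db",
  paste0("b", 1:5, "_en_lin"), paste0("b", 1:5, "_en_db"),
  paste0("b", 1:5, "_rms_lin"), paste0("b", 1:5, "_rms_db"),
  "fc", "oct", "trel"
)
s_tags <- c("a_max", "t_max", "a_min", "t_min", "max_a", "max_t",
            "mean_t_max", "mean_dt_max", "std_t_max", "std_dt_max", "n_max",
            "mean_t_min", "mean_dt_min", "std_t_min", "std_dt_min", "n_min",
            "mean_t_zero", "std_t_zero", "mean_dt_zero", "std_dt_zero",
            "n_broken", "skewness")
m_tags <- c("a0", "a1", "a2", paste0("en_q", 1:4), "mean", "std",
            paste0("mean_q", 1:4), paste0("std_q", 1:4), "frq_zero", "skewness")

#' Canonical feature names
#'
#' The 200 feature names in canonical order: for each interval S1, m1, S2,
#' m2 the common block (29 names), the S1/S2 timing block (22 names each)
#' or the m1/m2 envelope block (19 names each), then the two per-point
#' globals `bpm` and `cycle_trel`.
#'
#' @return Character vector of length 200.
#' @export
feature_names <- function() {
  c(paste0("S1_", c(common_tags, s_tags)),
    paste0("m1_", c(common_tags, m_tags)),
    paste0("S2_", c(common_tags, s_tags)),
    paste0("m2_", c(common_tags, m_tags)),
    "bpm", "cycle_trel")
}

common_block <- function(x, rate, fc_ref, trel) {
  out <- numeric(29)
  names(out) <- common_tags
  out["energy"] <- sum(x^2)
  out["n_zero"] <- zero_crossing_count(x)
  bw <- energy_and_rms(bandpass_filter(x, rate, pcg_wide_band[1], pcg_wide_band[2]))
  out["bw_en_lin"] <- bw$energy; out["bw_en_db"] <- bw$energy_db
  out["bw_rms_lin"] <- bw$rms; out["bw_rms_db"] <- bw$rms_db
  for (i in 1:5) {
    band <- pcg_bands[[i]]
    e <- energy_and_rms(bandpass_filter(x, rate, band[1], band[2]))
    out[paste0("b", i, "_en_lin")] <- e$energy
    out[paste0("b", i, "_en_db")] <- e$energy_db
    out[paste0("b", i, "_rms_lin")] <- e$rms
    out[paste0("b", i, "_rms_db")] <- e$rms_db
  }
  fc <- if (length(x) >= 8L) spectral_centroid_0_200(x, rate) else 0
  out["fc"] <- fc
  out["oct"] <- if (fc_ref > 0) octave_deviation(fc, fc_ref) else 0
  out["trel"] <- trel
  out
}

s_block <- function(x) {
  st <- extrema_timing_stats(x)
  out <- unlist(st)[s_tags[1:20]]
  c(out,
    n_broken = derivative_discontinuity_count(x),
    skewness = position_skewness(x))
}

m_block <- function(x, rate) {
  coefs <- envelope_poly_coeffs(x, rate)
  qp <- unlist(quarter_profile(x))
  c(a0 = coefs[1], a1 = coefs[2], a2 = coefs[3],
    qp,
    frq_zero = frq_zero(x, rate),
    skewness = position_skewness(x))
}

#' Per-point context for feature extraction
#'
#' Reference quantities computed across all cycles of one auscultation
#' point: the mean cycle duration (hence beats per minute) and the mean
#' spectral centroid per interval label, against which each cycle's `oct`
#' deviation is measured.
#'
#' @param samples Amplitude vector of the point recording (2 kHz).
#' @param seg Segmentation tibble for this point (indices into `samples`).
#' @param rate Sampling rate, 2000.
#' @return A list with `mean_cycle_duration`, `bpm`, `mean_fc` (named by
#'   interval).
#' @export
point_context <- function(samples, seg, rate = 2000) {
  durs <- (seg$cycle_end - seg$s1_start) / rate
  mean_dur <- mean(durs)
  fc_sums <- c(S1 = 0, m1 = 0, S2 = 0, m2 = 0)
  for (i in seq_len(nrow(seg))) {
    iv <- cycle_intervals(samples, seg[i, ])
    for (nm in names(iv)) {
      x <- iv[[nm]]
      fc_sums[nm] <- fc_sums[nm] + if (length(x) >= 8L) spectral_centroid_0_200(x, rate) else 0
    }
  }
  list(mean_cycle_duration = mean_dur, bpm = 60 / mean_dur,
       mean_fc = fc_sums / nrow(seg))
}

# Slice the four intervals (half-open, 0-based boundaries) out of a recording.
cycle_intervals <- function(samples, row) {
  list(
    S1 = samples[(row$s1_start + 1L):row$m1_start],
    m1 = samples[(row$m1_start + 1L):row$s2_start],
    S2 = samples[(row$s2_start + 1L):row$m2_start],
    m2 = samples[(row$m2_start + 1L):row$cycle_end]
  )
}

#' Extract the 200-feature vector for one segmented cycle
#'
#' @param samples Amplitude vector of the point recording at 2000 Hz.
#' @param cycle One segmentation row (see [validate_segmentation()]).
#' @param context Per-point reference quantities from [point_context()].
#' @param rate Sampling rate, 2000.
#' @return Named numeric vector of length 200 in canonical order.
#' @export
extract_cycle_features <- function(samples, cycle, context, rate = 2000) {
  iv <- cycle_intervals(samples, cycle)
  lens <- vapply(iv, length, 1L)
  if (any(lens < 2L)) {
    abort(sprintf("interval %s has fewer than 2 samples", names(iv)[which(lens < 2L)[1]]))
  }
  cyc_dur <- (cycle$cycle_end - cycle$s1_start) / rate
  out <- numeric(0)
  for (nm in c("S1", "m1", "S2", "m2")) {
    x <- iv[[nm]]
    trel <- (length(x) / rate) / context$mean_cycle_duration
    blk <- common_block(x, rate, context$mean_fc[[nm]], trel)
    extra <- if (nm %in% c("S1", "S2")) s_block(x) else m_block(x, rate)
    v <- c(blk, extra)
    names(v) <- paste0(nm, "_", c(common_tags, if (nm %in% c("S1", "S2")) s_tags else m_tags))
    out <- c(out, v)
  }
  out <- c(out, bpm = context$bpm,
           cycle_trel = cyc_dur / context$mean_cycle_duration)
  stopifnot(length(out) == 200L, !anyNA(out))
  out
}

#' Extract features for a whole cohort
#'
#' Walks a cohort table (one row per patient x auscultation point, with
#' `recording` and `segmentation` list-columns, as produced by
#' [simulate_cohort()]) and returns the cycle-level feature table: one row
#' per heartbeat cycle with identifiers, label, and the 200 canonical
#' feature columns.
#'
#' @param cohort Cohort tibble with columns `patient_id`, `label`,
#'   `point_id`, `recording`, `segmentation`.
#' @return A tibble with `patient_id`, `point_id`, `cycle_index`, `label`
#'   and 200 feature columns.
#' @export
extract_features <- function(cohort) {
  rows <- purrr::pmap(cohort, function(patient_id, label, point_id, recording, segmentation, ...) {
    rate <- recording$rate
    if (rate != 2000) {
      segmentation <- rescale_segmentation(segmentation, rate, 2000)
      recording <- resample_recording(recording, 2000)
      rate <- 2000
    }
    ctx <- point_context(recording$samples, segmentation, rate)
    feats <- lapply(seq_len(nrow(segmentation)), function(i) {
      extract_cycle_features(recording$samples, segmentation[i, ], ctx, rate)
    })
    fm <- do.call(rbind, feats)
    dplyr::bind_cols(
      tibble::tibble(patient_id = patient_id, point_id = point_id,
                     cycle_index = segmentation$cycle_index, label = label),
      tibble::as_tibble(fm)
    )
  })
  dplyr::bind_rows(rows)
}
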