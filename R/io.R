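# Audio and segmentation I/O.
#
# Recordings are mono PCM WAV files; segmentations are plain CSV tables of
# half-open, 0-based sample ranges delimiting the four phases of each
# heartbeat cycle (S1, systole m1, S2, diastole m2).

#' Construct a phonocardiogram recording
#'
#' A recording couples an amplitude vector (dimensionless, nominal range
#' \eqn{\pm 1}) with its sampling rate and the patient / auscultation-point
#' identifiers it belongs to. Auscultation points are numbered 1–5
#' (aortic, pulmonic, tricuspid, mitral, left sternal border).
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling rate in samples/second.
#' @param patient_id Patient identifier (string).
#' @param point_id Auscultation point, integer in 1..5.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, rate, patient_id = "unknown", point_id = 1L) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    abort("`samples` must be a non-empty numeric vector")
  }
  stopifnot_scalar_number(rate, "rate")
  if (rate <= 0) abort("`rate` must be positive")
  point_id <- as.integer(point_id)
  if (!point_id %in% 1:5) abort("`point_id` must be an integer in 1..5")
  structure(
    list(samples = as.double(samples), rate = as.double(rate),
         patient_id = as.character(patient_id), point_id = point_id),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> patient %s, point %d: %d samples @ %g Hz (%.2f s)\n",
              x$patient_id, x$point_id, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

read_chunk_header <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

#' Load a mono PCM WAV recording
#'
#' Reads a 16-bit mono PCM WAV file and scales the integer samples to real
#' values in \eqn{\pm 1} (division by full scale 32768); the rate is taken
#' from the header. No gain normalization is applied.
#'
#' @param path Path to a mono 16-bit PCM WAV file.
#' @param patient_id,point_id Identifiers attached to the recording.
#' @return A [pcg_recording()].
#' @export
load_recording <- function(path, patient_id = "unknown", point_id = 1L) {
  if (!file.exists(path)) {
    abort(sprintf("recording file not found: %s", path), class = "neopcg_missing_file")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("not a RIFF/WAVE file: %s", path), class = "neopcg_unsupported_encoding")
  }
  fmt <- NULL
  repeat {
    hdr <- read_chunk_header(con)
    if (length(hdr$id) == 0L || nchar(hdr$id) < 4L) {
      abort(sprintf("no data chunk found in %s", path), class = "neopcg_unsupported_encoding")
    }
    if (hdr$id == "fmt ") {
      raw_fmt <- readBin(con, "raw", hdr$size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1L, size = 2L, endian = "little"),
        channels     = readBin(raw_fmt[3:4], "integer", 1L, size = 2L, endian = "little"),
        rate         = readBin(raw_fmt[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1L, size = 2L, endian = "little")
      )
    } else if (hdr$id == "data") {
      if (is.null(fmt)) {
        abort(sprintf("data chunk before fmt chunk in %s", path),
              class = "neopcg_unsupported_encoding")
      }
      if (fmt$channels != 1L) {
        abort(sprintf("multi-channel audio unsupported (%d channels): %s",
                      fmt$channels, path),
              class = "neopcg_multichannel")
      }
      if (fmt$audio_format != 1L || fmt$bits != 16L) {
        abort(sprintf("unsupported encoding (format %d, %d bit); need 16-bit PCM: %s",
                      fmt$audio_format, fmt$bits, path),
              class = "neopcg_unsupported_encoding")
      }
      n <- hdr$size %/% 2L
      pcm <- readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "little")
      return(pcg_recording(pcm / 32768, fmt$rate, patient_id, point_id))
    } else {
      seek(con, hdr$size + hdr$size %% 2L, origin = "current")
    }
  }
}

#' Save a recording as 16-bit mono PCM WAV
#'
#' Amplitudes are clipped to \eqn{\pm 1} and quantized to 16-bit integers.
#'
#' @param rec A [pcg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pcg_recording"))
  # symmetric with the loader (divide by 32768); +1.0 clips to full scale
  pcm <- pmin(as.integer(round(pmax(pmin(rec$samples, 1), -1) * 32768)), 32767L)
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(rec$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rec$rate) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Resample a recording to the analysis rate
#'
#' Down-samples a recording (default target 2000 Hz, the feature-extraction
#' rate: the highest analysed frequency is 1 kHz). An anti-alias zero-phase
#' low-pass (raised-cosine edge centred at 0.45 times the target rate) is
#' applied in the frequency domain before interpolation onto the new sample
#' grid. The output length is `round(n * target_rate / rate)`.
#'
#' @param rec A [pcg_recording()].
#' @param target_rate Target sampling rate; must not exceed `rec$rate`.
#' @return A [pcg_recording()] at `target_rate`.
#' @export
resample_recording <- function(rec, target_rate = 2000) {
  stopifnot(inherits(rec, "pcg_recording"))
  stopifnot_scalar_number(target_rate, "target_rate")
  if (target_rate > rec$rate) {
    abort("upsampling not supported: `target_rate` exceeds the recording rate")
  }
  if (target_rate == rec$rate) return(rec)
  x <- rec$samples
  n <- length(x)
  m <- round(n * target_rate / rec$rate)
  # zero-phase FFT low-pass: unity below 0.40, cosine roll-off to 0.50 x target
  freqs <- (seq_len(n) - 1L) / n * rec$rate
  freqs <- pmin(freqs, rec$rate - freqs)  # two-sided
  f_lo <- 0.40 * target_rate
  f_hi <- 0.50 * target_rate
  gain <- ifelse(freqs <= f_lo, 1,
                 ifelse(freqs >= f_hi, 0,
                        0.5 * (1 + cos(pi * (freqs - f_lo) / (f_hi - f_lo)))))
  xf <- Re(fft(fft(x) * gain, inverse = TRUE)) / n
  t_out <- (seq_len(m) - 1L) / target_rate
  y <- approx((seq_len(n) - 1L) / rec$rate, xf, xout = t_out, rule = 2)$y
  pcg_recording(y, target_rate, rec$patient_id, rec$point_id)
}

seg_cols <- c("patient_id", "point_id", "cycle_index",
              "s1_start", "m1_start", "s2_start", "m2_start", "cycle_end")

#' Validate a segmentation table
#'
#' A segmentation is a tibble with one row per heartbeat cycle and columns
#' `patient_id, point_id, cycle_index, s1_start, m1_start, s2_start,
#' m2_start, cycle_end` — 0-based, half-open sample ranges at the stored
#' rate. Within a cycle the boundaries must be strictly increasing with
#' every interval at least 2 samples long; within a (patient, point) the
#' cycles must be time-ordered and non-overlapping.
#'
#' @param seg A segmentation tibble.
#' @return `seg`, invisibly, if valid; otherwise an error naming the
#'   offending row.
#' @export
validate_segmentation <- function(seg) {
  missing_cols <- setdiff(seg_cols, names(seg))
  if (length(missing_cols)) {
    abort(sprintf("segmentation lacks columns: %s", paste(missing_cols, collapse = ", ")),
          class = "neopcg_segmentation")
  }
  b <- as.matrix(seg[, c("s1_start", "m1_start", "s2_start", "m2_start", "cycle_end")])
  for (i in seq_len(nrow(seg))) {
    if (any(diff(b[i, ]) < 2)) {
      abort(sprintf("segmentation row %d: boundaries must increase by >= 2 samples per interval", i),
            class = "neopcg_segmentation")
    }
  }
  grp <- paste(seg$patient_id, seg$point_id)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1L) {
      ends <- seg$cycle_end[idx][-length(idx)]
      starts <- seg$s1_start[idx][-1L]
      bad <- which(starts < ends)
      if (length(bad)) {
        abort(sprintf("segmentation row %d: cycle overlaps the previous cycle", idx[bad[1] + 1L]),
              class = "neopcg_segmentation")
      }
    }
  }
  invisible(seg)
}

#' Load / save segmentation annotations
#'
#' Segmentations persist as plain CSV in the column layout described in
#' [validate_segmentation()]; save-then-load reproduces the table exactly.
#'
#' @param path CSV file path.
#' @return A validated segmentation tibble.
#' @export
load_segmentation <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("segmentation file not found: %s", path), class = "neopcg_missing_file")
  }
  seg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           point_id = readr::col_integer(),
                           cycle_index = readr::col_integer(),
                           .default = readr::col_double()))
  seg <- tibble::as_tibble(seg)[, seg_cols]
  validate_segmentation(seg)
  seg
}

#' @rdname load_segmentation
#' @param seg A segmentation tibble.
#' @export
save_segmentation <- function(seg, path) {
  validate_segmentation(seg)
  readr::write_csv(seg[, seg_cols], path, progress = FALSE)
  invisible(path)
}

#' Rescale segmentation boundaries after resampling
#'
#' Annotations are made at the original recording rate; after resampling,
#' boundary indices are rescaled proportionally and rounded.
#'
#' @param seg A segmentation tibble (indices at `from_rate`).
#' @param from_rate,to_rate Original and new sampling rates.
#' @return The segmentation with rescaled indices.
#' @export
rescale_segmentation <- function(seg, from_rate, to_rate) {
  r <- to_rate / from_rate
  for (col in c("s1_start", "m1_start", "s2_start", "m2_start", "cycle_end")) {
    seg[[col]] <- round(seg[[col]] * r)
  }
  validate_segmentation(seg)
  seg
}
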