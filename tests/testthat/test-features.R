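# Feature-extraction operators against brute-force oracles, plus the
# 200-feature census and its internal consistency.

test_that("band-pass filter passes in-band tones and rejects out-of-band ones", {
  t <- (0:1999) / 2000
  expect_equal(bandpass_filter(numeric(500), 2000, 80, 200), numeric(500))
  tone100 <- sin(2 * pi * 100 * t)
  tone20 <- sin(2 * pi * 20 * t)
  rms <- function(x) sqrt(mean(x^2))
  expect_gte(rms(bandpass_filter(tone100, 2000, 80, 200)) / rms(tone100), 0.9)
  expect_lte(rms(bandpass_filter(tone20, 2000, 80, 200)) / rms(tone20), 0.1)
  # 400-1000 band at 2 kHz degrades to a high-pass at 400
  tone700 <- sin(2 * pi * 700 * t)
  expect_gte(rms(bandpass_filter(tone700, 2000, 400, 1000)) / rms(tone700), 0.9)
})

test_that("energy and RMS match their defining formulas and the dB floor", {
  e <- energy_and_rms(c(3, 4))
  expect_equal(e$energy, 25)
  expect_equal(e$rms, sqrt(12.5))

  z <- energy_and_rms(numeric(10))
  expect_equal(z$energy, 0)
  expect_equal(z$energy_db, -120)
  expect_equal(z$rms_db, -120)

  x <- withr::with_seed(2, rnorm(256))
  e2 <- energy_and_rms(x)
  brute <- 0; for (v in x) brute <- brute + v * v
  expect_equal(e2$energy, brute, tolerance = 1e-12)
  expect_equal(e2$rms, sqrt(brute / 256), tolerance = 1e-12)
  expect_equal(e2$energy, 256 * e2$rms^2, tolerance = 1e-9)
})

test_that("zero crossings follow the sign convention", {
  expect_equal(zero_crossing_count(c(1, -1, 1, -1)), 3)
  expect_equal(zero_crossing_count(abs(rnorm(20)) + 0.1), 0)
  expect_equal(zero_crossing_count(c(1, 0, -1)), 1)   # zero separates opposite signs
  expect_equal(zero_crossing_count(c(1, 0, 1)), 0)    # zero touch, no crossing
  x <- withr::with_seed(3, rnorm(500))
  scan <- 0
  s <- sign(x); s <- s[s != 0]
  for (i in seq_len(length(s) - 1)) if (s[i] != s[i + 1]) scan <- scan + 1
  expect_equal(zero_crossing_count(x), scan)
})

test_that("spectral centroid below 200 Hz matches the DFT oracle", {
  t <- (0:1999) / 2000
  expect_equal(spectral_centroid_0_200(rep(1, 64), 2000), 0)  # DC only
  expect_equal(spectral_centroid_0_200(sin(2 * pi * 100 * t), 2000), 100, tolerance = 1)
  two <- sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t)
  expect_equal(spectral_centroid_0_200(two, 2000), 100, tolerance = 2)
})

test_that("octave deviation is a base-2 log ratio", {
  expect_equal(octave_deviation(200, 100), 1)
  expect_equal(octave_deviation(100, 100), 0)
  expect_equal(octave_deviation(50, 100), -1)
  expect_equal(octave_deviation(0, 100), 0)
  expect_error(octave_deviation(100, 0), "positive")
})

test_that("envelope polynomial fits constant and ramped amplitudes", {
  const <- envelope_poly_coeffs(rep(0.7, 200), 2000)
  expect_equal(const[1], 0.7, tolerance = 1e-6)
  expect_equal(const[2], 0, tolerance = 1e-6)
  expect_equal(const[3], 0, tolerance = 1e-6)

  expect_equal(envelope_poly_coeffs(numeric(50), 2000), c(0, 0, 0))

  t <- (0:999) / 1000
  ramp <- t * sin(2 * pi * 100 * t * 2)  # amplitude ramp 0 -> 1 on a carrier
  coefs <- envelope_poly_coeffs(ramp, 2000)
  expect_equal(coefs[2], 1, tolerance = 0.1)
})

test_that("extrema and zero-crossing statistics match a brute-force scan", {
  t <- seq(0, 3, length.out = 3000)
  sine <- sin(2 * pi * t)
  st <- extrema_timing_stats(sine)
  expect_equal(st$n_max, 3)
  expect_equal(st$n_min, 3)

  flat <- extrema_timing_stats(rep(2, 10))
  expect_equal(flat$n_max, 0)
  expect_equal(flat$n_min, 0)
  expect_equal(flat$mean_t_max, 0)
  expect_equal(flat$std_dt_zero, 0)

  x <- withr::with_seed(6, rnorm(200))
  st2 <- extrema_timing_stats(x)
  n <- length(x)
  # independent neighbour-comparison scan (no plateaus in continuous noise)
  maxima <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  minima <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
  expect_equal(st2$n_max, length(maxima))
  expect_equal(st2$n_min, length(minima))
  tm <- (maxima - 1) / (n - 1)
  expect_equal(st2$mean_t_max, mean(tm), tolerance = 1e-12)
  expect_equal(st2$std_t_max, sd(tm), tolerance = 1e-12)
  expect_equal(st2$mean_dt_max, mean(diff(tm)), tolerance = 1e-12)
  expect_equal(st2$std_dt_max, sd(diff(tm)), tolerance = 1e-12)
  tn <- (minima - 1) / (n - 1)
  expect_equal(st2$mean_t_min, mean(tn), tolerance = 1e-12)
  expect_equal(st2$a_max, max(x))
  expect_equal(st2$t_max, (which.max(x) - 1) / (n - 1))
  expect_equal(st2$a_min, min(x))
  expect_equal(st2$max_a, max(abs(x)))
  zc <- which(sign(x[1:(n - 1)]) * sign(x[2:n]) < 0) - 1L
  tz <- zc / (n - 1)
  expect_equal(st2$mean_t_zero, mean(tz), tolerance = 1e-12)
  expect_equal(st2$std_dt_zero, sd(diff(tz)), tolerance = 1e-12)
})

test_that("plateaus count once at their first sample", {
  x <- c(0, 1, 1, 1, 0, -1, -1, 0)
  st <- extrema_timing_stats(x)
  expect_equal(st$n_max, 1)
  expect_equal(st$n_min, 1)
  expect_equal(st$mean_t_max, 1 / 7)  # plateau starts at index 1 (0-based)
})

test_that("quarter profile matches the partition-and-reduce oracle", {
  ones <- quarter_profile(rep(1, 8))
  expect_equal(unlist(ones[paste0("en_q", 1:4)]), rep(2, 4), ignore_attr = TRUE)
  expect_equal(unlist(ones[paste0("mean_q", 1:4)]), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unlist(ones[paste0("std_q", 1:4)]), rep(0, 4), ignore_attr = TRUE)

  imp <- quarter_profile(c(1, rep(0, 7)))
  expect_equal(unlist(imp[paste0("en_q", 1:4)]), c(1, 0, 0, 0), ignore_attr = TRUE)

  x <- withr::with_seed(7, rnorm(103))
  qp <- quarter_profile(x)
  q <- 103 %/% 4  # remainder goes to the last quarter
  parts <- list(x[1:q], x[(q + 1):(2 * q)], x[(2 * q + 1):(3 * q)], x[(3 * q + 1):103])
  for (i in 1:4) {
    expect_equal(qp[[paste0("en_q", i)]], sum(parts[[i]]^2), tolerance = 1e-12)
    expect_equal(qp[[paste0("mean_q", i)]], mean(parts[[i]]), tolerance = 1e-12)
    expect_equal(qp[[paste0("std_q", i)]], sd(parts[[i]]), tolerance = 1e-12)
  }
  expect_equal(qp$mean, mean(x), tolerance = 1e-12)
  expect_equal(qp$std, sd(x), tolerance = 1e-12)
})

test_that("position skewness locates the maximum absolute value in [-1, 1]", {
  expect_equal(position_skewness(c(0, 0, 5, 0, 0)), 0)
  expect_equal(position_skewness(c(0, 0, 0, 9)), 1)
  expect_equal(position_skewness(c(-9, 0, 0, 0)), -1)
})

test_that("derivative discontinuities: smooth signals give zero, a kink gives one", {
  expect_equal(derivative_discontinuity_count(seq(0, 1, length.out = 50)), 0)
  expect_equal(derivative_discontinuity_count(rep(3, 20)), 0)
  smooth <- sin(2 * pi * (0:499) / 500) * 0.1
  d2 <- diff(smooth, differences = 2)
  kinked <- smooth
  kinked[250:500] <- kinked[250:500] + 50 * 4 * mad(d2) * ((250:500) - 250) / 2
  expect_equal(derivative_discontinuity_count(kinked), 1)
})

test_that("zeros per second follow the crossing count", {
  t <- (0:1999) / 2000
  expect_equal(frq_zero(sin(2 * pi * 100 * t), 2000), 200, tolerance = 2)
  expect_equal(frq_zero(abs(rnorm(100)) + 1, 2000), 0)
  expect_equal(frq_zero(c(1, -1), 2), 1)
})

test_that("the feature census is exactly 200 unique canonical names", {
  nm <- feature_names()
  expect_length(nm, 200)
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(sum(startsWith(nm, "S1_")), 51)  # 29 common + 22 timing
  expect_equal(sum(startsWith(nm, "S2_")), 51)
  expect_equal(sum(startsWith(nm, "m1_")), 48)  # 29 common + 19 envelope
  expect_equal(sum(startsWith(nm, "m2_")), 48)
  expect_true(all(c("bpm", "cycle_trel", "m1_b4_en_lin") %in% nm))
})

test_that("cycle feature vectors have 200 finite entries and are deterministic", {
  pat <- one_patient()
  rec <- pat$recording[[1]]; seg <- pat$segmentation[[1]]
  ctx <- point_context(rec$samples, seg)
  v1 <- extract_cycle_features(rec$samples, seg[1, ], ctx)
  v2 <- extract_cycle_features(rec$samples, seg[1, ], ctx)
  expect_length(v1, 200)
  expect_identical(names(v1), feature_names())
  expect_true(all(is.finite(v1)))
  expect_identical(v1, v2)

  short <- seg[1, ]
  short$m1_start <- short$s1_start + 1  # S1 of 1 sample
  expect_error(extract_cycle_features(rec$samples, short, ctx), "S1")
})

test_that("an all-zero cycle yields zero energies and the dB floor", {
  seg <- toy_segmentation()[1, ]
  seg$patient_id <- "Z"; seg$point_id <- 1L
  zeros <- numeric(seg$cycle_end)
  ctx <- list(mean_cycle_duration = seg$cycle_end / 2000, bpm = 60 / (seg$cycle_end / 2000),
              mean_fc = c(S1 = 0, m1 = 0, S2 = 0, m2 = 0))
  v <- extract_cycle_features(zeros, seg, ctx)
  lin <- v[grepl("_(bw|b[1-5])_(en|rms)_lin$", names(v)) | grepl("_energy$", names(v))]
  expect_true(all(lin == 0))
  dbs <- v[grepl("_(en|rms)_db$", names(v))]
  expect_true(all(dbs == -120))
})

test_that("dB features equal 10 log10(linear + eps) throughout real extractions", {
  ft <- small_features()
  for (iv in c("S1", "m1", "S2", "m2")) {
    for (b in c("bw", paste0("b", 1:5))) {
      lin <- ft[[paste0(iv, "_", b, "_en_lin")]]
      db <- ft[[paste0(iv, "_", b, "_en_db")]]
      expect_equal(db, 10 * log10(lin + 1e-12), tolerance = 1e-9)
    }
  }
})

test_that("sub-band energies are mutually consistent with the wide band", {
  ft <- small_features()
  for (iv in c("m1", "m2")) {
    sub_sum <- rowSums(sapply(1:5, function(i) ft[[paste0(iv, "_b", i, "_en_lin")]]))
    expect_true(all(sub_sum <= 1.1 * ft[[paste0(iv, "_bw_en_lin")]] + 1e-9))
  }
})

test_that("systolic 200-400 Hz energy separates murmur cycles from healthy ones", {
  p <- sim_params(murmur_gain = 3)
  vals <- withr::with_seed(91, {
    get_m1b4 <- function(label) {
      sapply(1:60, function(i) {
        cyc <- simulate_cycle(label, p)
        m1 <- cyc$samples[(cyc$cycle$m1_start + 1):cyc$cycle$s2_start]
        band_energy(m1)
      })
    }
    list(chd = get_m1b4("CHD"), hea = get_m1b4("healthy"))
  })
  pv <- stats::wilcox.test(vals$chd, vals$hea, alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})
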