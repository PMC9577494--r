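test_that("FIR band-pass rejects DC and passes mid-band sinusoids", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  mid <- seq(2 * fs, 8 * fs)     # away from edges
  dc <- fir_bandpass(rep(1, length(t)), fs)
  expect_lt(max(abs(dc[mid])), 1e-3)
  s10 <- fir_bandpass(sin(2 * pi * 10 * t), fs)
  gain10 <- sd(s10[mid]) / sd(sin(2 * pi * 10 * t)[mid])
  expect_gt(gain10, 0.95); expect_lt(gain10, 1.05)
  s05 <- fir_bandpass(sin(2 * pi * 0.5 * t), fs)
  expect_lt(sd(s05[mid]) / sd(sin(2 * pi * 0.5 * t)[mid]), 0.1)
  expect_error(fir_bandpass(rnorm(100), fs), "too short")
})

test_that("filtering twice is near-idempotent within the passband", {
  fs <- 250
  e <- simulate_ecg(30, fs, 70, 50, 35, noise_sd = 0, seed = 3)
  f1 <- fir_bandpass(e$waveform, fs)
  f2 <- fir_bandpass(f1, fs)
  mid <- seq(5 * fs, 25 * fs)
  expect_lt(abs(sd(f2[mid]) - sd(f1[mid])) / sd(f1[mid]), 0.05)
})

test_that("R-peak detection recovers noise-free simulated beats exactly", {
  fs <- 250
  e <- simulate_ecg(60, fs, 60, 40, 28, noise_sd = 0, seed = 4)
  rp <- detect_r_peaks(fir_bandpass(e$waveform, fs), fs)
  m <- match_events(rp$times_s, e$true_r_times, 0.02)
  expect_equal(m$recall, 1)
  expect_equal(m$fp, 0L)
})

test_that("R-peak F1 stays >= 0.99 across heart rates on clean signals", {
  fs <- 250
  for (hr in c(50, 75, 120)) {
    e <- simulate_ecg(60, fs, hr, 40, 28, noise_sd = 0, seed = hr)
    rp <- detect_r_peaks(fir_bandpass(e$waveform, fs), fs)
    m <- match_events(rp$times_s, e$true_r_times, 0.02)
    expect_gte(m$f1, 0.99)
  }
})

test_that("degenerate ECG inputs produce empty detections, not errors", {
  expect_warning(rp <- detect_r_peaks(rep(0, 2500), 250), "no R-peaks")
  expect_true(rp$empty)
  expect_length(rp$sample_indices, 0L)
  # two beats 150 ms apart: refractory keeps exactly one
  fs <- 250
  t <- (0:(5 * fs - 1)) / fs
  x <- emofuse:::ecg_template(t - 2) + emofuse:::ecg_template(t - 2.15)
  rp2 <- detect_r_peaks(x, fs)
  expect_equal(length(rp2$sample_indices), 1L)
})

test_that("NN intervals difference, reject artifacts, and match simulator truth", {
  nn <- nn_intervals(structure(list(times_s = c(0, 1, 2), fs = 250),
                               class = "rpeaks"))
  expect_equal(nn$intervals_ms, c(1000, 1000))
  # a 5000 ms gap is outside the admissible range and removed
  nn2 <- nn_intervals(c(0, 1, 2, 7, 8, 9, 10))
  expect_equal(nn2$n_rejected, 1L)
  expect_equal(length(nn2$intervals_ms), 5L)
  expect_true(all(nn2$intervals_ms < 3000))
  fs <- 250
  e <- simulate_ecg(120, fs, 75, 50, 35, noise_sd = 0, seed = 12)
  rp <- detect_r_peaks(fir_bandpass(e$waveform, fs), fs)
  nn3 <- nn_intervals(rp)
  k <- min(length(nn3$intervals_ms), length(e$rr_ms))
  expect_lt(mean(abs(nn3$intervals_ms[1:k] - e$rr_ms[1:k])), 5)
  expect_error(nn_intervals(c(0, 1)), "3 R-peaks")
})

test_that("EDA decomposition separates tonic and phasic with a sparse driver", {
  e0 <- simulate_eda(120, 25, 2, scr_rate_per_min = 0, noise_sd = 0, seed = 1)
  d0 <- eda_decompose(e0$waveform, 25)
  expect_equal(nrow(d0$scr_events), 0L)
  e <- simulate_eda(600, 25, 2, scr_rate_per_min = 6, noise_sd = 0, seed = 3)
  d <- eda_decompose(e$waveform, 25)
  expect_false(d$fallback)
  expect_true(all(d$driver >= 0))
  expect_lt(d$residual_rel, 0.05)
  expect_gte(window_recall(d$scr_events$onset_s, e$true_scr_times, 1), 0.8)
  expect_error(eda_decompose(rep(-1, 1000), 25), "non-negative")
  expect_error(eda_decompose(rep(2, 100), 25), "30 s")
})

test_that("breath segmentation finds the configured cycles", {
  r <- simulate_rsp(60, 25, 12, amp_var = 0, period_jitter = 0,
                    noise_sd = 0, seed = 2)
  bc <- segment_breaths(r$waveform, 25)
  expect_lte(abs(nrow(bc$cycles) - 12), 1)
  expect_true(all(bc$cycles$start_s < bc$cycles$peak_s &
                    bc$cycles$peak_s < bc$cycles$end_s))
  k <- min(nrow(bc$cycles), nrow(r$true_cycle_bounds))
  expect_lt(max(abs(bc$cycles$start_s[1:k] -
                      r$true_cycle_bounds$start_s[1:k])), 0.3)
  expect_warning(bc0 <- segment_breaths(rep(1, 500), 25), "no breath")
  expect_true(bc0$empty)
})

test_that("baseline compensation subtracts per-feature and reduces subject variance", {
  v <- c(a = 1, b = 2)
  expect_equal(baseline_compensate(v, v), c(a = 0, b = 0))
  expect_equal(baseline_compensate(v, c(a = 0, b = 0)), v)
  expect_equal(baseline_compensate(v, c(a = 2, b = 2), "divide"),
               c(a = 0.5, b = 1))
  expect_error(baseline_compensate(v, c(x = 1, b = 2)), "names")
  # zero-effect dataset: all label structure removed, but subject offsets
  # remain; compensation should shrink between-subject spread of a
  # subject-offset-driven feature (tonic_mean)
  cfg <- sim_config(n_subjects = 6, trials_per_subject = 3,
                    trial_duration_s = 34, arousal_effect = 0,
                    valence_effect = 0, seed = 31)
  ds <- simulate_dataset(cfg)
  f_on <- extract_features_dataset(ds, compensate = "subtract")
  f_off <- extract_features_dataset(ds, compensate = "off")
  bsv <- function(df) {
    mu <- tapply(df$tonic_mean, df$subject_id, mean)
    var(as.numeric(mu))
  }
  expect_lt(bsv(f_on), bsv(f_off))
})
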