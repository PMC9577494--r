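test_that("zero-variability ECG degenerates to a metronome", {
  e <- simulate_ecg(60, 250, mean_hr_bpm = 60, sdnn_target_ms = 0,
                    rmssd_target_ms = 0, noise_sd = 0, seed = 1)
  expect_true(length(e$true_r_times) %in% c(60L, 61L))
  expect_equal(diff(e$true_r_times), rep(1, length(e$true_r_times) - 1),
               tolerance = 1e-9)
})

test_that("channel simulators are deterministic given a seed", {
  a <- simulate_ecg(30, 250, 70, 50, 35, seed = 42)
  b <- simulate_ecg(30, 250, 70, 50, 35, seed = 42)
  expect_identical(a$waveform, b$waveform)
  expect_identical(a$true_r_times, b$true_r_times)
  e1 <- simulate_eda(60, 25, 2, 6, 0.5, seed = 7)
  e2 <- simulate_eda(60, 25, 2, 6, 0.5, seed = 7)
  expect_identical(e1$waveform, e2$waveform)
  r1 <- simulate_rsp(60, 25, 14, seed = 9)
  r2 <- simulate_rsp(60, 25, 14, seed = 9)
  expect_identical(r1$waveform, r2$waveform)
})

test_that("RR tachogram hits the SDNN target on average", {
  sdnn <- vapply(1:20, function(s) {
    e <- simulate_ecg(300, 100, 70, sdnn_target_ms = 50,
                      rmssd_target_ms = 35, noise_sd = 0, seed = s)
    sd(e$rr_ms)
  }, numeric(1))
  expect_lt(abs(mean(sdnn) - 50) / 50, 0.15)
})

test_that("infeasible variability targets are rejected", {
  expect_error(simulate_ecg(60, 250, 70, sdnn_target_ms = 10,
                            rmssd_target_ms = 40),
               "infeasible")
  expect_error(simulate_ecg(60, 250, mean_hr_bpm = 20), "mean_hr_bpm")
  expect_error(simulate_ecg(5, 250, 70), "duration")
})

test_that("EDA event counts follow the Poisson rate", {
  counts <- vapply(1:20, function(s) {
    length(simulate_eda(600, 25, 2, scr_rate_per_min = 6, seed = s)$true_scr_times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 60), 3 * sqrt(60))
})

test_that("rate-zero EDA is pure tonic and a single SCR stays below its driver amplitude", {
  e0 <- simulate_eda(60, 25, 2, scr_rate_per_min = 0, noise_sd = 0, seed = 1)
  expect_equal(e0$waveform, e0$tonic)
  # place exactly one unit event: draw until a single event is produced
  s <- 1
  repeat {
    e1 <- simulate_eda(60, 25, 2, scr_rate_per_min = 1, scr_amp_uS = 1,
                       noise_sd = 0, seed = s)
    if (length(e1$true_scr_times) == 1) break
    s <- s + 1
  }
  excess <- max(e1$waveform - e1$tonic)
  expect_gt(excess, 0)
  expect_lte(excess, 1.2)   # driver amplitude (with its 20% jitter) bounds the peak
  expect_error(simulate_eda(60, 25, tonic_level_uS = -1), "tonic")
})

test_that("respiration cycle counts and amplitudes behave as configured", {
  r <- simulate_rsp(60, 25, 12, amp = 1, amp_var = 0, period_jitter = 0,
                    noise_sd = 0, seed = 2)
  expect_equal(nrow(r$true_cycle_bounds), 12L)
  # constant amplitude: all cycle maxima equal
  pk <- tapply(r$waveform,
               findInterval((seq_along(r$waveform) - 1) / 25,
                            r$true_cycle_bounds$start_s),
               max)
  expect_lt(diff(range(pk[1:12])), 1e-6)
  rj <- simulate_rsp(60, 25, 12, amp_var = 0.2, period_jitter = 0.1,
                     seed = 3)
  expect_lte(abs(nrow(rj$true_cycle_bounds) - 12), 2)
  expect_error(simulate_rsp(60, 25, breath_rate_bpm = 2), "breath_rate")
})

test_that("arousal raises heart rate through the score-parameter mapping", {
  cfg <- sim_config(n_subjects = 20, trials_per_subject = 1,
                    trial_duration_s = 34, arousal_effect = 2, seed = 5)
  hr_of <- function(score) {
    vapply(1:20, function(s) {
      tr <- simulate_trial(cfg, s, 1, score, 5, duration_s = 34)
      60000 / mean(tr$ground_truth$rr_ms)
    }, numeric(1))
  }
  expect_gt(mean(hr_of(9)), mean(hr_of(1)))
  # zero effect: parameter means identical across scores
  cfg0 <- sim_config(n_subjects = 2, trials_per_subject = 1,
                     arousal_effect = 0, valence_effect = 0, seed = 6)
  p1 <- simulate_trial(cfg0, 1, 1, 1, 5, duration_s = 34)$ground_truth$parameters
  p9 <- simulate_trial(cfg0, 1, 2, 9, 5, duration_s = 34)$ground_truth$parameters
  expect_identical(p1$mean_hr, p9$mean_hr)
  expect_identical(p1$scr_rate, p9$scr_rate)
  expect_identical(p1$breath, p9$breath)
})

test_that("datasets are reproducible and ground truth lies inside each trial", {
  cfg <- sim_config(n_subjects = 2, trials_per_subject = 2,
                    trial_duration_s = 34, seed = 8)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$trials[[3]]$ecg$waveform, d2$trials[[3]]$ecg$waveform)
  for (tr in d1$trials) {
    gt <- tr$ground_truth
    expect_true(all(gt$r_times >= 0 & gt$r_times <= tr$duration_s))
    expect_true(all(gt$scr_times >= 0 & gt$scr_times <= tr$duration_s))
    expect_true(all(gt$cycle_bounds$end_s <= tr$duration_s + 1e-9))
  }
  expect_equal(nrow(d1$manifest), 4L)
  expect_length(d1$baselines, 2L)
  expect_equal(d1$baselines[["1"]]$arousal_score, 5L)
})

test_that("dataset directories round-trip through CSV + JSON", {
  dir <- file.path(tempdir(), "emofuse-ds")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- sim_config(n_subjects = 1, trials_per_subject = 1,
                    trial_duration_s = 34, seed = 9)
  ds <- simulate_dataset(cfg)
  write_dataset(ds, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 1L)
  ecg <- read.csv(file.path(dir, "sub-001", "trial-001_ecg.csv"))
  expect_equal(ecg$value, ds$trials[[1]]$ecg$waveform, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "sub-001", "trial-001_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$r_times, ds$trials[[1]]$ground_truth$r_times,
               tolerance = 1e-9)
  back <- read_dataset(dir)
  expect_equal(length(back$trials), 1L)
  expect_equal(back$trials[[1]]$ecg$waveform, ds$trials[[1]]$ecg$waveform,
               tolerance = 1e-9)
  expect_equal(back$trials[[1]]$ecg$fs, 250)
  expect_length(back$baselines, 1L)
  expect_equal(back$trials[[1]]$ground_truth$r_times,
               ds$trials[[1]]$ground_truth$r_times, tolerance = 1e-9)
})
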