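test_that("the registry is a closed world of 58 names with the stated counts", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 58L)
  expect_equal(sum(startsWith(reg$domain, "ecg")), 47L)
  expect_equal(as.vector(table(reg$domain)[c("ecg-time", "ecg-frequency",
                                             "ecg-nonlinear", "eda", "rsp")]),
               c(14L, 4L, 29L, 4L, 7L))
  expect_false(any(duplicated(reg$name)))
  expect_equal(length(feature_names_for("ecg")), 47L)
  expect_equal(length(feature_names_for("fusion")), 58L)
})

test_that("time-domain HRV features match hand-computed values", {
  z <- hrv_time(c(800, 800, 800, 800))
  expect_equal(unname(z[c("RMSSD", "SDNN", "pNN50")]), c(0, 0, 0))
  expect_equal(unname(z["MeanNN"]), 800)
  v <- hrv_time(c(800, 810, 790, 805))
  expect_equal(unname(v["RMSSD"]), sqrt((10^2 + 20^2 + 15^2) / 3),
               tolerance = 1e-9)
  expect_equal(unname(v["SDNN"]), sd(c(800, 810, 790, 805)), tolerance = 1e-12)
  expect_equal(unname(v["CVNN"]), unname(v["SDNN"] / v["MeanNN"]))
  w <- hrv_time(c(800, 860, 800, 860))
  expect_equal(unname(w["pNN50"]), 100)
  expect_equal(unname(w["pNN20"]), 100)
  expect_error(hrv_time(c(800, 810)), ">= 4")
})

test_that("frequency features integrate a 0.25 Hz modulation into the HF band", {
  tt <- seq(0, 120, by = 0.8)                # ~75 bpm anchors
  nn <- structure(list(intervals_ms = 800 + 50 * sin(2 * pi * 0.25 * tt),
                       t_anchor_s = tt, n_rejected = 0L),
                  class = "nn_series")
  f <- hrv_frequency(nn)
  tot <- f[["HF"]] + f[["VHF"]]
  expect_gt(f[["HF"]] / tot, 0.9)
  expect_true(f[["HFn"]] >= 0 && f[["HFn"]] <= 1)
  expect_equal(f[["LnHF"]], log(f[["HF"]]))
  # metronomic tachogram: no power, sentinel LnHF
  nn0 <- structure(list(intervals_ms = rep(800, 151),
                        t_anchor_s = seq(0, 120, by = 0.8),
                        n_rejected = 0L), class = "nn_series")
  f0 <- hrv_frequency(nn0)
  expect_lt(f0[["HF"]], 1e-6)
  expect_equal(f0[["LnHF"]], -50)
  expect_error(hrv_frequency(structure(list(intervals_ms = rep(800, 5),
                                            t_anchor_s = 0:4 * 0.8,
                                            n_rejected = 0L),
                                       class = "nn_series")), "30 s")
})

test_that("Poincare identities hold on arbitrary series", {
  set.seed(4)
  for (rep_ in 1:10) {
    x <- 800 + cumsum(rnorm(60, 0, 20))
    nl <- hrv_nonlinear(x)
    d <- diff(x)
    expect_equal(unname(nl["SD1"]), sqrt(mean(d^2)) / sqrt(2),
                 tolerance = 1e-12)
    expect_equal(unname(nl["SD2"]),
                 sqrt(max(2 * sd(x)^2 - nl[["SD1"]]^2, 0)), tolerance = 1e-9)
    expect_equal(unname(nl["S"]), pi * nl[["SD1"]] * nl[["SD2"]],
                 tolerance = 1e-9)
    expect_equal(unname(nl["CSI"]), nl[["SD2"]] / nl[["SD1"]], tolerance = 1e-9)
    # deceleration/acceleration partitions are exact decompositions
    expect_equal(nl[["C1d"]] + nl[["C1a"]], 1, tolerance = 1e-9)
    expect_equal(nl[["C2d"]] + nl[["C2a"]], 1, tolerance = 1e-9)
    expect_equal(nl[["Cd"]] + nl[["Ca"]], 1, tolerance = 1e-9)
    expect_equal(nl[["SD1d"]]^2 + nl[["SD1a"]]^2, nl[["SD1"]]^2,
                 tolerance = 1e-9)
    expect_true(nl[["GI"]] >= 0 && nl[["GI"]] <= 100)
    expect_true(nl[["PI"]] >= 0 && nl[["PI"]] <= 100)
  }
})

test_that("fragmentation and entropy match their defining constructions", {
  alt <- rep(c(800, 850), 15)
  nl <- hrv_nonlinear(alt)
  expect_equal(unname(nl["PIP"]), 100)
  expect_equal(unname(nl["PAS"]), 100)
  ramp <- seq(800, 800 + 49 * 5, by = 5)    # 50-point constant-increment ramp
  expect_equal(sample_entropy(ramp, 2, 0.2 * sd(ramp)), 0)
  # brute-force cross-check of SampEn on a small random series
  set.seed(9)
  x <- rnorm(40)
  r <- 0.2 * sd(x)
  brute_sampen <- function(x, m, r) {
    n <- length(x)
    count <- function(mm) {
      c0 <- 0
      for (i in 1:(n - m)) for (j in 1:(n - m)) {
        if (i == j) next
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) c0 <- c0 + 1
      }
      c0
    }
    -log(count(m + 1) / count(m))
  }
  expect_equal(sample_entropy(x, 2, r), brute_sampen(x, 2, r),
               tolerance = 1e-12)
  expect_gt(approx_entropy(x, 2, r), 0)
})

test_that("EDA and RSP feature vectors follow their definitions", {
  e0 <- simulate_eda(120, 25, 2, scr_rate_per_min = 0, noise_sd = 0, seed = 1)
  f0 <- eda_features(eda_decompose(e0$waveform, 25), 120)
  expect_equal(unname(f0["SCR_count_per_min"]), 0)
  expect_equal(unname(f0["SCR_mean_amplitude"]), 0)
  expect_equal(unname(f0["tonic_mean"]), 2, tolerance = 0.1)
  e6 <- simulate_eda(300, 25, 2, scr_rate_per_min = 6, noise_sd = 0, seed = 5)
  f6 <- eda_features(eda_decompose(e6$waveform, 25), 300)
  expect_lte(abs(f6[["SCR_count_per_min"]] - 6), 2)

  r <- simulate_rsp(60, 25, 12, amp_var = 0, period_jitter = 0,
                    noise_sd = 0, seed = 2)
  fr <- rsp_features(segment_breaths(r$waveform, 25), 60)
  expect_lt(fr[["amplitude_var"]], 1e-3)
  expect_equal(fr[["breath_rate_mean"]], 12, tolerance = 0.05 * 12)
  expect_equal(fr[["cycle_duration_mean"]], 5, tolerance = 0.25)
  expect_gte(fr[["amplitude_max"]], fr[["amplitude_mean"]])
  expect_warning(fe <- rsp_features(segment_breaths(rep(0, 500), 25), 20))
  expect_true(all(is.na(fe)))
})

test_that("the extractor emits exactly the 58 registry features, deterministically", {
  ds <- small_dataset()
  fv1 <- extract_features(ds$trials[[1]])
  fv2 <- extract_features(ds$trials[[1]])
  expect_length(fv1, 58L)
  expect_identical(names(fv1), feature_registry()$name)
  expect_identical(as.numeric(fv1), as.numeric(fv2))
  reg <- feature_registry()
  expect_equal(sum(names(fv1) %in% reg$name[startsWith(reg$domain, "ecg")]),
               47L)
})

test_that("the dataset feature table carries ids, labels and finite features", {
  feats <- extract_features_dataset(small_dataset())
  expect_equal(nrow(feats), 24L)
  expect_true(all(feature_registry()$name %in% colnames(feats)))
  expect_true(all(c("subject_id", "trial_id", "arousal", "valence") %in%
                    colnames(feats)))
  mat <- as.matrix(feats[, feature_registry()$name])
  expect_gt(mean(apply(is.finite(mat), 1, all)), 0.9)
})
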