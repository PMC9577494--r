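#' Simulation configuration for a multi-modal emotion dataset
#'
#' Defines the study conditions emulated by the generator: per-subject trials
#' with three synchronously recorded channels (ECG, electrodermal activity,
#' respiration), per-trial 1-9 arousal/valence self-reports, and a 60-s
#' neutral baseline recording per subject used downstream for baseline
#' compensation.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject trials recorded per subject.
#' @param trial_duration_s trial length in seconds; either a scalar or a
#'   length-2 range within \[34, 201\] from which per-trial durations are drawn
#'   uniformly.
#' @param baseline_duration_s length of the per-subject neutral baseline
#'   recording (seconds).
#' @param fs_ecg,fs_eda,fs_rsp sampling rates (Hz) of the three channels.
#' @param arousal_effect,valence_effect non-negative effect sizes scaling how
#'   strongly the self-report scores shift channel parameters (0 = labels
#'   carry no physiological signal).
#' @param noise_sd named numeric vector of additive noise SDs per channel
#'   (`ecg` in mV, `eda` in microsiemens, `rsp` in arbitrary units).
#' @param seed integer seed fully determining the dataset.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 52L,
                       trials_per_subject = 12L,
                       trial_duration_s = c(34, 201),
                       baseline_duration_s = 60,
                       fs_ecg = 250, fs_eda = 25, fs_rsp = 25,
                       arousal_effect = 1, valence_effect = 1,
                       noise_sd = c(ecg = 0.05, eda = 0.01, rsp = 0.05),
                       seed = 1L) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1)
  if (length(trial_duration_s) == 1L) trial_duration_s <- rep(trial_duration_s, 2)
  if (any(trial_duration_s < 34) || any(trial_duration_s > 201) ||
      trial_duration_s[1] > trial_duration_s[2]) {
    stop("trial_duration_s must lie within [34, 201] seconds")
  }
  if (baseline_duration_s <= 0) stop("baseline_duration_s must be positive")
  if (any(c(fs_ecg, fs_eda, fs_rsp) <= 0)) stop("sampling rates must be positive")
  if (arousal_effect < 0 || valence_effect < 0) stop("effect sizes must be >= 0")
  noise <- c(ecg = 0.05, eda = 0.01, rsp = 0.05)
  noise[names(noise_sd)] <- noise_sd
  structure(list(
    n_subjects = as.integer(n_subjects),
    trials_per_subject = as.integer(trials_per_subject),
    trial_duration_s = trial_duration_s,
    baseline_duration_s = baseline_duration_s,
    fs_ecg = fs_ecg, fs_eda = fs_eda, fs_rsp = fs_rsp,
    arousal_effect = arousal_effect, valence_effect = valence_effect,
    noise_sd = noise, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_subjects, "subjects x", x$trials_per_subject,
      "trials,", paste(x$trial_duration_s, collapse = "-"), "s trials\n")
  cat("  fs (ECG/EDA/RSP):", x$fs_ecg, "/", x$fs_eda, "/", x$fs_rsp, "Hz;",
      "arousal effect", x$arousal_effect, "; valence effect", x$valence_effect,
      "; seed", x$seed, "\n")
  invisible(x)
}

# PQRST template evaluated at offsets (s) relative to the R peak: a sum of
# five Gaussian deflections with clinically plausible timing (single lead,
# R amplitude 1 mV).
ecg_template <- function(t_rel) {
  g <- function(a, mu, s) a * exp(-0.5 * ((t_rel - mu) / s)^2)
  g(0.12, -0.20, 0.025) +   # P
    g(-0.14, -0.035, 0.010) + # Q
    g(1.00, 0.00, 0.011) +  # R
    g(-0.22, 0.035, 0.012) + # S
    g(0.30, 0.25, 0.045)    # T
}

#' Simulate a single-lead ECG waveform with exact R-peak ground truth
#'
#' Places a template PQRST beat at R-times generated from a stochastic RR
#' process: Gaussian innovations with variance `sdnn_target_ms^2` and lag-1
#' autocorrelation chosen so the expected root-mean-square of successive
#' differences matches `rmssd_target_ms` (an AR(1) tachogram). Adds a slow
#' baseline-wander sinusoid and white measurement noise.
#'
#' @param duration_s recording length (s), at least 10.
#' @param fs sampling rate (Hz).
#' @param mean_hr_bpm mean heart rate, in \[30, 200\] bpm.
#' @param sdnn_target_ms,rmssd_target_ms target SDNN / RMSSD of the RR series
#'   (ms). `rmssd_target_ms` may not exceed `2 * sqrt(2) * sdnn_target_ms`.
#' @param noise_sd additive white-noise SD (mV).
#' @param hr_skew optional skew of RR innovations (used to encode valence).
#' @param seed RNG seed.
#' @return list with `waveform`, `fs`, `true_r_times` (s), `rr_ms`.
#' @export
simulate_ecg <- function(duration_s, fs, mean_hr_bpm = 70,
                         sdnn_target_ms = 50, rmssd_target_ms = 35,
                         noise_sd = 0.05, hr_skew = 0, seed = NULL) {
  if (duration_s < 10) stop("duration_s must be >= 10 s")
  if (mean_hr_bpm < 30 || mean_hr_bpm > 200) {
    stop("mean_hr_bpm must lie in [30, 200]")
  }
  if (sdnn_target_ms < 0 || rmssd_target_ms < 0) stop("variability targets must be >= 0")
  if (rmssd_target_ms > 2 * sqrt(2) * sdnn_target_ms &&
      !(sdnn_target_ms == 0 && rmssd_target_ms == 0)) {
    stop("infeasible variability targets: rmssd_target_ms > 2*sqrt(2)*sdnn_target_ms")
  }
  with_seed(seed, {
    rr_mean <- 60000 / mean_hr_bpm
    n_max <- ceiling(duration_s * 1000 / max(rr_mean - 4 * sdnn_target_ms, 300)) + 8L
    if (sdnn_target_ms > 0) {
      # AR(1) with sd = SDNN and phi = 1 - RMSSD^2 / (2 SDNN^2)
      phi <- clamp(1 - rmssd_target_ms^2 / (2 * sdnn_target_ms^2), -0.99, 0.99)
      innov_sd <- sdnn_target_ms * sqrt(1 - phi^2)
      e <- stats::rnorm(n_max, 0, innov_sd)
      if (hr_skew != 0) {
        # mean-zero skewed innovations: mixture tilt preserving the SD target
        e <- e + hr_skew * (stats::rexp(n_max, 1) - 1) * innov_sd * 0.5
        e <- (e - mean(e)) / stats::sd(e) * innov_sd
      }
      z <- stats::filter(e, phi, method = "recursive")
      rr <- rr_mean + as.numeric(z)
    } else {
      rr <- rep(rr_mean, n_max)
    }
    rr <- clamp(rr, 300, 2000)
    r_times <- cumsum(rr) / 1000
    r_times <- r_times[r_times <= duration_s]
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    wave <- numeric(n)
    half <- 0.45  # template support half-width (s)
    for (rt in r_times) {
      i0 <- max(1L, ceiling((rt - half) * fs) + 1L)
      i1 <- min(n, floor((rt + half) * fs) + 1L)
      if (i1 >= i0) {
        idx <- i0:i1
        wave[idx] <- wave[idx] + ecg_template(t[idx] - rt)
      }
    }
    wander <- 0.05 * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi))
    if (noise_sd > 0) wave <- wave + stats::rnorm(n, 0, noise_sd)
    list(waveform = wave + wander, fs = fs, true_r_times = r_times,
         rr_ms = diff(r_times) * 1000)
  })
}

# Bateman skin-conductance response kernel (unit driver impulse).
bateman_kernel <- function(fs, tau_rise = 0.7, tau_decay = 3.0, len_s = 20) {
  t <- seq(0, len_s, by = 1 / fs)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k
}

#' Simulate electrodermal activity with known SCR event times
#'
#' Tonic level plus slow drift, with skin-conductance responses generated by
#' a Poisson event process convolved with a two-exponential Bateman kernel.
#'
#' @param duration_s recording length (s).
#' @param fs sampling rate (Hz).
#' @param tonic_level_uS tonic skin conductance level (microsiemens), >= 0.
#' @param scr_rate_per_min mean SCR event rate (events/min), >= 0.
#' @param scr_amp_uS driver amplitude per event (microsiemens).
#' @param noise_sd additive white-noise SD (microsiemens).
#' @param seed RNG seed.
#' @return list with `waveform`, `fs`, `true_scr_times` (s), `tonic`.
#' @export
simulate_eda <- function(duration_s, fs, tonic_level_uS = 2,
                         scr_rate_per_min = 8, scr_amp_uS = 0.5,
                         noise_sd = 0.01, seed = NULL) {
  if (tonic_level_uS < 0) stop("tonic_level_uS must be >= 0")
  if (scr_rate_per_min < 0) stop("scr_rate_per_min must be >= 0")
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    tonic <- tonic_level_uS +
      0.05 * tonic_level_uS * sin(2 * pi * 0.004 * t + stats::runif(1, 0, 2 * pi))
    n_ev <- stats::rpois(1, scr_rate_per_min * duration_s / 60)
    ev <- sort(stats::runif(n_ev, 0, max(duration_s - 2, 1)))
    k <- bateman_kernel(fs)
    phasic <- numeric(n)
    if (n_ev > 0) {
      idx <- pmin(n, floor(ev * fs) + 1L)
      amp <- scr_amp_uS * stats::runif(n_ev, 0.8, 1.2)
      for (j in seq_len(n_ev)) {
        span <- idx[j]:min(n, idx[j] + length(k) - 1L)
        phasic[span] <- phasic[span] + amp[j] * k[seq_along(span)]
      }
    }
    wave <- tonic + phasic
    if (noise_sd > 0) wave <- wave + stats::rnorm(n, 0, noise_sd)
    list(waveform = wave, fs = fs, true_scr_times = ev, tonic = tonic)
  })
}

#' Simulate a respiration waveform with known cycle boundaries
#'
#' Quasi-sinusoidal breathing: each cycle has its own period and amplitude
#' (log-normal-free Gaussian jitter, truncated), with a continuous phase so
#' cycle boundaries (troughs) are exact ground truth.
#'
#' @param duration_s recording length (s).
#' @param fs sampling rate (Hz).
#' @param breath_rate_bpm mean breathing rate, in \[4, 60\] breaths/min.
#' @param amp mean cycle amplitude (arbitrary units).
#' @param amp_var relative amplitude jitter (coefficient of variation).
#' @param period_jitter relative period jitter.
#' @param noise_sd additive white-noise SD.
#' @param seed RNG seed.
#' @return list with `waveform`, `fs`, `true_cycle_bounds` (data.frame
#'   `start_s`, `end_s`) for complete cycles.
#' @export
simulate_rsp <- function(duration_s, fs, breath_rate_bpm = 14, amp = 1,
                         amp_var = 0.15, period_jitter = 0.08,
                         noise_sd = 0.05, seed = NULL) {
  if (breath_rate_bpm < 4 || breath_rate_bpm > 60) {
    stop("breath_rate_bpm must lie in [4, 60]")
  }
  if (amp < 0 || amp_var < 0 || period_jitter < 0) stop("invalid amplitude/jitter")
  with_seed(seed, {
    period <- 60 / breath_rate_bpm
    n_cyc <- ceiling(duration_s / period) + 3L
    periods <- period * clamp(1 + stats::rnorm(n_cyc, 0, period_jitter), 0.5, 2)
    amps <- amp * clamp(1 + stats::rnorm(n_cyc, 0, amp_var), 0.1, 3)
    bounds <- c(0, cumsum(periods))
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    cyc <- findInterval(t, bounds)             # cycle index per sample
    u <- (t - bounds[cyc]) / periods[cyc]      # phase within cycle, [0, 1)
    # amplitude envelope interpolated between successive cycle amplitudes
    env <- amps[cyc] * (1 - u) + amps[pmin(cyc + 1L, n_cyc)] * u
    wave <- -env * cos(2 * pi * u)
    if (noise_sd > 0) wave <- wave + stats::rnorm(n, 0, noise_sd)
    complete <- which(bounds[-1] <= duration_s)
    list(waveform = wave, fs = fs,
         true_cycle_bounds = data.frame(start_s = bounds[complete],
                                        end_s = bounds[complete + 1L]))
  })
}

# Per-subject physiological offsets, drawn deterministically from the
# config seed and the subject id (independent of call order).
subject_offsets <- function(config, subject_id) {
  with_seed(derive_seed(config$seed, 1000L, subject_id), {
    list(hr = stats::rnorm(1, 0, 3),
         tonic = stats::rnorm(1, 0, 0.3),
         scr_rate = stats::rnorm(1, 0, 0.8),
         breath = stats::rnorm(1, 0, 1))
  })
}

# Map self-report scores to channel parameters. Linear in (score - 5):
# arousal raises mean HR, SCR rate and breathing rate; valence skews the RR
# innovations (heart-rate asymmetry) and perturbs breathing regularity.
trial_parameters <- function(config, offs, arousal_score, valence_score) {
  a <- (arousal_score - 5) * config$arousal_effect
  v <- (valence_score - 5) * config$valence_effect
  list(
    mean_hr = clamp(70 + 3 * a + offs$hr, 40, 180),
    sdnn = 50, rmssd = 35,
    hr_skew = clamp(0.4 * v, -2, 2),
    tonic = max(0.2, 2 + offs$tonic),
    scr_rate = max(0, 8 + 1.0 * a + offs$scr_rate),
    scr_amp = 0.5,
    breath = clamp(14 + 0.8 * a + offs$breath, 5, 40),
    rsp_amp_var = clamp(0.15 + 0.03 * (-v), 0, 0.6),
    rsp_period_jitter = clamp(0.08 + 0.02 * (-v), 0, 0.5)
  )
}

#' Simulate one multi-modal trial
#'
#' @param config a [sim_config()].
#' @param subject_id,trial_id identifiers; `trial_id = 0` denotes the
#'   subject's neutral baseline recording.
#' @param arousal_score,valence_score integer self-reports in 1-9.
#' @param familiarity -1, 0 or 1.
#' @param duration_s trial length (s); defaults drawn from the config range.
#' @param seed RNG seed (defaults to one derived from the config seed and
#'   the identifiers).
#' @return an object of class `mm_trial` with channels `ecg`, `eda`, `rsp`
#'   (each `list(waveform, fs)`), scores, and `ground_truth` (true R times,
#'   SCR event times, breath-cycle bounds).
#' @export
simulate_trial <- function(config, subject_id, trial_id,
                           arousal_score, valence_score, familiarity = 0L,
                           duration_s = NULL, seed = NULL) {
  stopifnot(arousal_score >= 1, arousal_score <= 9,
            valence_score >= 1, valence_score <= 9)
  if (is.null(seed)) seed <- derive_seed(config$seed, subject_id, trial_id)
  offs <- subject_offsets(config, subject_id)
  p <- trial_parameters(config, offs, arousal_score, valence_score)
  if (is.null(duration_s)) {
    duration_s <- with_seed(derive_seed(seed, 7L),
                            stats::runif(1, config$trial_duration_s[1],
                                         config$trial_duration_s[2]))
  }
  ecg <- simulate_ecg(duration_s, config$fs_ecg, p$mean_hr, p$sdnn, p$rmssd,
                      config$noise_sd[["ecg"]], p$hr_skew,
                      seed = derive_seed(seed, 1L))
  eda <- simulate_eda(duration_s, config$fs_eda, p$tonic, p$scr_rate,
                      p$scr_amp, config$noise_sd[["eda"]],
                      seed = derive_seed(seed, 2L))
  rsp <- simulate_rsp(duration_s, config$fs_rsp, p$breath, 1, p$rsp_amp_var,
                      p$rsp_period_jitter, config$noise_sd[["rsp"]],
                      seed = derive_seed(seed, 3L))
  structure(list(
    subject_id = subject_id, trial_id = trial_id,
    ecg = list(waveform = ecg$waveform, fs = config$fs_ecg),
    eda = list(waveform = eda$waveform, fs = config$fs_eda),
    rsp = list(waveform = rsp$waveform, fs = config$fs_rsp),
    arousal_score = as.integer(arousal_score),
    valence_score = as.integer(valence_score),
    familiarity = as.integer(familiarity),
    duration_s = duration_s,
    ground_truth = list(r_times = ecg$true_r_times,
                        rr_ms = ecg$rr_ms,
                        scr_times = eda$true_scr_times,
                        cycle_bounds = rsp$true_cycle_bounds,
                        parameters = p)
  ), class = "mm_trial")
}

#' @export
print.mm_trial <- function(x, ...) {
  cat(sprintf("Multi-modal trial: subject %s, trial %s, %.1f s\n",
              x$subject_id, x$trial_id, x$duration_s))
  cat(sprintf("  arousal %d, valence %d, familiarity %d\n",
              x$arousal_score, x$valence_score, x$familiarity))
  cat(sprintf("  ECG %d samples @ %g Hz | EDA %d @ %g Hz | RSP %d @ %g Hz\n",
              length(x$ecg$waveform), x$ecg$fs,
              length(x$eda$waveform), x$eda$fs,
              length(x$rsp$waveform), x$rsp$fs))
  invisible(x)
}

#' Simulate a full multi-modal emotion dataset
#'
#' Generates `trials_per_subject` scored trials per subject plus one 60-s
#' neutral baseline recording per subject (scores fixed at the scale
#' midpoint 5). Scores are drawn uniformly from 1-9 so mid-scale
#' thresholding yields unbalanced classes, as in typical self-report data.
#'
#' @param config a [sim_config()].
#' @return list with `trials` (list of `mm_trial`), `baselines` (one neutral
#'   `mm_trial` per subject, named by subject id) and `manifest`
#'   (data.frame: subject_id, trial_id, arousal, valence, familiarity,
#'   duration_s).
#' @export
simulate_dataset <- function(config) {
  scores <- with_seed(derive_seed(config$seed, 99L), {
    n <- config$n_subjects * config$trials_per_subject
    data.frame(arousal = sample(1:9, n, replace = TRUE),
               valence = sample(1:9, n, replace = TRUE),
               familiarity = sample(-1:1, n, replace = TRUE))
  })
  trials <- vector("list", nrow(scores))
  baselines <- vector("list", config$n_subjects)
  manifest <- cbind(
    data.frame(subject_id = rep(seq_len(config$n_subjects),
                                each = config$trials_per_subject),
               trial_id = rep(seq_len(config$trials_per_subject),
                              times = config$n_subjects)),
    scores)
  for (i in seq_len(nrow(manifest))) {
    trials[[i]] <- simulate_trial(config, manifest$subject_id[i],
                                  manifest$trial_id[i],
                                  manifest$arousal[i], manifest$valence[i],
                                  manifest$familiarity[i])
  }
  manifest$duration_s <- vapply(trials, function(tr) tr$duration_s, numeric(1))
  for (s in seq_len(config$n_subjects)) {
    baselines[[s]] <- simulate_trial(config, s, 0L, 5L, 5L, 0L,
                                     duration_s = config$baseline_duration_s)
  }
  names(baselines) <- as.character(seq_len(config$n_subjects))
  list(trials = trials, baselines = baselines, manifest = manifest,
       config = config)
}

#' Write a simulated dataset to a directory
#'
#' Layout: `manifest.csv` at the top level; per-trial per-channel CSVs
#' (`time_s,value`) under `sub-<id>/`; ground truth as a sidecar JSON per
#' trial. Baseline recordings use `trial_id = 0`.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trial <- function(tr) {
    sub_dir <- file.path(dir, sprintf("sub-%03d", tr$subject_id))
    dir.create(sub_dir, showWarnings = FALSE)
    stem <- file.path(sub_dir, sprintf("trial-%03d", tr$trial_id))
    for (ch in c("ecg", "eda", "rsp")) {
      w <- tr[[ch]]
      utils::write.csv(
        data.frame(time_s = (seq_along(w$waveform) - 1) / w$fs,
                   value = w$waveform),
        paste0(stem, "_", ch, ".csv"), row.names = FALSE)
    }
    gt <- tr$ground_truth
    jsonlite::write_json(
      list(r_times = gt$r_times, scr_times = gt$scr_times,
           cycle_start_s = gt$cycle_bounds$start_s,
           cycle_end_s = gt$cycle_bounds$end_s),
      paste0(stem, "_truth.json"), digits = NA)
  }
  for (tr in dataset$trials) write_trial(tr)
  for (tr in dataset$baselines) write_trial(tr)
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Reconstructs `mm_trial` objects (without simulator parameters) from the
#' manifest and the per-trial channel CSVs; ground truth is reloaded from
#' the sidecar JSONs when present.
#'
#' @param dir dataset directory.
#' @return list with `trials`, `baselines`, `manifest` as in
#'   [simulate_dataset()] (the `config` element is `NULL`).
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  read_trial <- function(subject_id, trial_id, arousal, valence,
                         familiarity) {
    stem <- file.path(dir, sprintf("sub-%03d", subject_id),
                      sprintf("trial-%03d", trial_id))
    chan <- lapply(c(ecg = "ecg", eda = "eda", rsp = "rsp"), function(ch) {
      d <- utils::read.csv(paste0(stem, "_", ch, ".csv"))
      fs <- 1 / stats::median(diff(d$time_s))
      list(waveform = d$value, fs = round(fs, 6))
    })
    gt_path <- paste0(stem, "_truth.json")
    gt <- if (file.exists(gt_path)) {
      j <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
      list(r_times = j$r_times, scr_times = j$scr_times,
           cycle_bounds = data.frame(start_s = j$cycle_start_s,
                                     end_s = j$cycle_end_s))
    } else NULL
    structure(c(list(subject_id = subject_id, trial_id = trial_id),
                chan,
                list(arousal_score = as.integer(arousal),
                     valence_score = as.integer(valence),
                     familiarity = as.integer(familiarity),
                     duration_s = length(chan$ecg$waveform) / chan$ecg$fs,
                     ground_truth = gt)),
              class = "mm_trial")
  }
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    read_trial(manifest$subject_id[i], manifest$trial_id[i],
               manifest$arousal[i], manifest$valence[i],
               manifest$familiarity[i])
  })
  subjects <- sort(unique(manifest$subject_id))
  baselines <- lapply(subjects, function(s) {
    if (file.exists(file.path(dir, sprintf("sub-%03d", s),
                              "trial-000_ecg.csv"))) {
      read_trial(s, 0L, 5, 5, 0)
    } else NULL
  })
  names(baselines) <- as.character(subjects)
  list(trials = trials, baselines = Filter(Negate(is.null), baselines),
       manifest = manifest, config = NULL)
}
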