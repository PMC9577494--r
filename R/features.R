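# Canonical feature registry: 47 ECG (14 time + 4 frequency + 29 non-linear)
# + 4 EDA + 7 RSP = 58 features. Extraction never emits a name outside this
# registry, and always emits all 58 (non-finite values are flagged, not
# dropped).

.ecg_time_names <- c("RMSSD", "MeanNN", "SDNN", "SDSD", "CVNN", "CVSD",
                     "MedianNN", "MadNN", "MCVNN", "IQRNN", "pNN50", "pNN20",
                     "TINN", "HTI")
.ecg_freq_names <- c("HF", "VHF", "HFn", "LnHF")
.ecg_nonlin_names <- c("SD1", "SD2", "SD1SD2", "S", "CSI", "CVI",
                       "CSI_Modified", "PIP", "IALS", "PSS", "PAS",
                       "GI", "SI", "AI", "PI",
                       "C1d", "C1a", "SD1d", "SD1a", "C2d", "C2a",
                       "SD2d", "SD2a", "Cd", "Ca", "SDNNd", "SDNNa",
                       "ApEn", "SampEn")
.eda_names <- c("SCR_count_per_min", "SCR_mean_amplitude", "tonic_mean",
                "phasic_sd")
.rsp_names <- c("amplitude_mean", "amplitude_max", "amplitude_var",
                "breath_rate_mean", "cycle_duration_mean",
                "cycle_duration_sd", "amplitude_cv")

#' The canonical 58-feature registry
#'
#' @return data.frame with columns `name` and `domain` (`ecg-time`,
#'   `ecg-frequency`, `ecg-nonlinear`, `eda`, `rsp`). 47 ECG + 4 EDA + 7 RSP
#'   features, in canonical extraction order.
#' @export
feature_registry <- function() {
  data.frame(
    name = c(.ecg_time_names, .ecg_freq_names, .ecg_nonlin_names,
             .eda_names, .rsp_names),
    domain = c(rep("ecg-time", length(.ecg_time_names)),
               rep("ecg-frequency", length(.ecg_freq_names)),
               rep("ecg-nonlinear", length(.ecg_nonlin_names)),
               rep("eda", length(.eda_names)),
               rep("rsp", length(.rsp_names))),
    stringsAsFactors = FALSE)
}

# Names belonging to a modality, for modality-restricted classifiers.
feature_names_for <- function(modality = c("ecg", "eda", "rsp", "fusion")) {
  modality <- match.arg(modality)
  reg <- feature_registry()
  switch(modality,
         ecg = reg$name[startsWith(reg$domain, "ecg")],
         eda = reg$name[reg$domain == "eda"],
         rsp = reg$name[reg$domain == "rsp"],
         fusion = reg$name)
}

#' Time-domain heart-rate-variability features
#'
#' Standard definitions on the NN series (ms): RMSSD (root mean square of
#' successive differences), MeanNN, SDNN (sample SD), SDSD (sample SD of
#' successive differences), CVNN = SDNN/MeanNN, CVSD = RMSSD/MeanNN,
#' MedianNN, MadNN (median absolute deviation x 1.4826), MCVNN =
#' MadNN/MedianNN, IQRNN, pNN50/pNN20 (% successive differences > 50/20 ms),
#' and TINN/HTI from the NN histogram with 7.8125 ms bins (triangular
#' interpolation baseline width; total count / modal bin count).
#'
#' @param nn an `nn_series` or numeric vector of NN intervals (ms).
#' @return named numeric vector of 14 features.
#' @export
hrv_time <- function(nn) {
  x <- if (inherits(nn, "nn_series")) nn$intervals_ms else as.numeric(nn)
  if (length(x) < 4L) stop("hrv_time needs >= 4 NN intervals")
  d <- diff(x)
  rmssd <- sqrt(mean(d^2))
  meannn <- mean(x)
  sdnn <- stats::sd(x)
  mediannn <- stats::median(x)
  madnn <- stats::mad(x)             # 1.4826 scaling is R's default
  # histogram on the standard 1/128 s = 7.8125 ms grid
  bw <- 7.8125
  lo <- floor(min(x) / bw) * bw
  cnt <- tabulate(pmin(floor((x - lo) / bw) + 1L,
                       ceiling((max(x) - lo) / bw) + 1L))
  hti <- length(x) / max(cnt)
  tinn <- tinn_width(cnt, bw)
  c(RMSSD = rmssd, MeanNN = meannn, SDNN = sdnn, SDSD = stats::sd(d),
    CVNN = sdnn / meannn, CVSD = rmssd / meannn, MedianNN = mediannn,
    MadNN = madnn, MCVNN = madnn / mediannn,
    IQRNN = unname(stats::IQR(x)),
    pNN50 = 100 * mean(abs(d) > 50), pNN20 = 100 * mean(abs(d) > 20),
    TINN = tinn, HTI = hti)
}

# Triangular interpolation of the NN histogram: least-squares fit of a
# triangle that is zero outside [m, M] and peaks at the modal bin; TINN is
# the base width M - m in ms. Degenerate single-bin histograms give 0.
tinn_width <- function(cnt, bw) {
  nb <- length(cnt)
  if (nb < 2L || sum(cnt > 0) < 2L) return(0)
  peak <- which.max(cnt)
  best <- Inf; best_w <- 0
  for (m in 1:peak) {
    for (M in peak:nb) {
      if (M - m < 1L) next
      tri <- numeric(nb)
      up <- m:peak
      if (peak > m) tri[up] <- cnt[peak] * (up - m) / (peak - m)
      dn <- peak:M
      if (M > peak) tri[dn] <- cnt[peak] * (M - dn) / (M - peak)
      tri[peak] <- cnt[peak]
      err <- sum((cnt - tri)^2)
      if (err < best) { best <- err; best_w <- (M - m) * bw }
    }
  }
  best_w
}

#' Frequency-domain heart-rate-variability features
#'
#' Cubic-spline interpolation of the NN tachogram to uniform 4 Hz sampling,
#' Welch periodogram (Hann windows, 50% overlap), then band powers:
#' HF = \[0.15, 0.4\] Hz, VHF = \[0.4, 0.5\] Hz, HFn = HF / total power in
#' \[0.04, 0.5\] Hz, LnHF = ln(HF). Units: ms^2. A flat tachogram yields HF
#' = 0 and the LnHF sentinel `-50` (documented finite stand-in for -Inf).
#'
#' @param nn an `nn_series` (anchor times required for interpolation).
#' @param fs_interp interpolation rate (Hz).
#' @return named numeric vector: HF, VHF, HFn, LnHF.
#' @export
hrv_frequency <- function(nn, fs_interp = 4) {
  stopifnot(inherits(nn, "nn_series"))
  span <- diff(range(nn$t_anchor_s))
  if (span < 30) stop("hrv_frequency needs an NN span of >= 30 s")
  tt <- seq(min(nn$t_anchor_s), max(nn$t_anchor_s), by = 1 / fs_interp)
  xi <- stats::spline(nn$t_anchor_s, nn$intervals_ms, xout = tt)$y
  psd <- welch_psd(xi - mean(xi), fs_interp,
                   nperseg = min(length(xi), 256L))
  hf <- band_power(psd, 0.15, 0.4)
  vhf <- band_power(psd, 0.4, 0.5)
  tot <- band_power(psd, 0.04, 0.5)
  c(HF = hf, VHF = vhf,
    HFn = if (tot > 0) hf / tot else 0,
    LnHF = if (hf > 0) log(hf) else -50)
}

#' Non-linear heart-rate-variability features
#'
#' Poincare geometry (SD1 = RMSSD/sqrt(2), SD2 = sqrt(2 SDNN^2 - SD1^2),
#' their ratio, ellipse area S = pi SD1 SD2, CSI = SD2/SD1, CVI =
#' log10(16 SD1 SD2), Modified CSI = (4 SD2)^2 / (4 SD1)); heart-rate
#' fragmentation (PIP, IALS, PSS, PAS); heart-rate asymmetry (Guzik, slope,
#' area and Porta indices plus the short/long-term deceleration and
#' acceleration partitions C1d/C1a, SD1d/SD1a, C2d/C2a, SD2d/SD2a, Cd/Ca,
#' SDNNd/SDNNa); approximate and sample entropy with m = 2,
#' r = 0.2 x SD of the series. Degenerate (zero-variance) series return
#' documented sentinels: ratio indices 0, asymmetry percentages 50,
#' entropies 0.
#'
#' @param nn an `nn_series` or numeric NN vector (ms); >= 10 intervals.
#' @return named numeric vector of 29 features.
#' @export
hrv_nonlinear <- function(nn) {
  x <- if (inherits(nn, "nn_series")) nn$intervals_ms else as.numeric(nn)
  if (length(x) < 10L) stop("hrv_nonlinear needs >= 10 NN intervals")
  d <- diff(x)
  n <- length(d)
  rmssd <- sqrt(mean(d^2))
  sdnn <- stats::sd(x)
  sd1 <- rmssd / sqrt(2)
  sd2 <- sqrt(max(2 * sdnn^2 - sd1^2, 0))
  ratio0 <- function(a, b, sentinel = 0) if (b > 0) a / b else sentinel

  # --- fragmentation (sign structure of successive differences)
  s <- sign(d)
  pip <- if (n >= 2) {
    prods <- s[-1] * s[-n]
    100 * mean(prods <= 0 & !(s[-1] == 0 & s[-n] == 0))
  } else 0
  runs <- rle(s)
  nz_runs <- runs$lengths[runs$values != 0]
  ials <- if (length(nz_runs)) 1 / mean(nz_runs) else 0
  pss <- 100 * sum(runs$lengths[runs$lengths < 3]) / n
  # alternation segments: maximal stretches of strict sign alternation
  pas <- 0
  if (n >= 2) {
    alt <- s[-1] == -s[-n] & s[-1] != 0
    ralt <- rle(alt)
    covered <- 0
    pos <- 1L
    for (j in seq_along(ralt$lengths)) {
      if (ralt$values[j] && ralt$lengths[j] + 1L >= 4L) {
        covered <- covered + ralt$lengths[j] + 1L
      }
      pos <- pos + ralt$lengths[j]
    }
    pas <- 100 * min(covered, n) / n
  }

  # --- asymmetry on the Poincare plot (xi, xi+1)
  px <- x[-length(x)]; py <- x[-1]
  dec <- d > 0; acc <- d < 0; nodiff <- d == 0
  D <- abs(d) / sqrt(2)
  theta <- abs(atan2(py, px) - pi / 4)
  r2 <- px^2 + py^2
  area <- 0.5 * theta * r2
  off <- dec | acc
  gi <- if (any(off)) 100 * sum(D[dec]) / sum(D[off]) else 50
  si <- if (any(off) && sum(theta[off]) > 0) {
    100 * sum(theta[dec] * 180 / pi) / sum(theta[off] * 180 / pi)
  } else 50
  ai <- if (any(off) && sum(area[off]) > 0) {
    100 * sum(area[dec]) / sum(area[off])
  } else 50
  pi_idx <- if (any(off)) 100 * sum(acc) / sum(off) else 50
  sd1d <- sqrt(sum(D[dec]^2) / n)
  sd1a <- sqrt(sum(D[acc]^2) / n)
  sd1I <- sqrt(sd1d^2 + sd1a^2)
  D2 <- (px - mean(px) + py - mean(py)) / sqrt(2)
  sd2d <- sqrt((sum(D2[dec]^2) + 0.5 * sum(D2[nodiff]^2)) / n)
  sd2a <- sqrt((sum(D2[acc]^2) + 0.5 * sum(D2[nodiff]^2)) / n)
  sd2I <- sqrt(sd2d^2 + sd2a^2)
  c1d <- ratio0(sd1d^2, sd1I^2); c1a <- ratio0(sd1a^2, sd1I^2)
  c2d <- ratio0(sd2d^2, sd2I^2); c2a <- ratio0(sd2a^2, sd2I^2)
  cd <- ratio0(sd1d^2 + sd2d^2, sd1I^2 + sd2I^2)
  ca <- ratio0(sd1a^2 + sd2a^2, sd1I^2 + sd2I^2)
  sdnnd <- sqrt(0.5 * (sd1d^2 + sd2d^2))
  sdnna <- sqrt(0.5 * (sd1a^2 + sd2a^2))

  r_ent <- 0.2 * stats::sd(x)
  c(SD1 = sd1, SD2 = sd2, SD1SD2 = ratio0(sd1, sd2), S = pi * sd1 * sd2,
    CSI = ratio0(sd2, sd1),
    CVI = if (sd1 * sd2 > 0) log10(16 * sd1 * sd2) else 0,
    CSI_Modified = ratio0((4 * sd2)^2, 4 * sd1),
    PIP = pip, IALS = ials, PSS = pss, PAS = pas,
    GI = gi, SI = si, AI = ai, PI = pi_idx,
    C1d = c1d, C1a = c1a, SD1d = sd1d, SD1a = sd1a,
    C2d = c2d, C2a = c2a, SD2d = sd2d, SD2a = sd2a,
    Cd = cd, Ca = ca, SDNNd = sdnnd, SDNNa = sdnna,
    ApEn = approx_entropy(x, 2L, r_ent),
    SampEn = sample_entropy(x, 2L, r_ent))
}

# Template match counts under the Chebyshev metric: for each i, the number
# of j with max|x[i..i+m-1] - x[j..j+m-1]| <= r.
template_matches <- function(x, m, r, self = TRUE) {
  nt <- length(x) - m + 1L
  if (nt < 1L) return(integer(0))
  dmax <- matrix(0, nt, nt)
  for (k in 0:(m - 1L)) {
    xi <- x[(1L:nt) + k]
    dmax <- pmax(dmax, abs(outer(xi, xi, "-")))
  }
  cnt <- rowSums(dmax <= r)
  if (!self) cnt <- cnt - 1L
  cnt
}

#' Approximate entropy
#'
#' ApEn(m, r) = phi_m - phi_{m+1}, with phi_m the mean natural log of the
#' self-inclusive template match frequency at length m (Chebyshev metric).
#'
#' @param x numeric series.
#' @param m template length (default 2).
#' @param r tolerance, on the scale of `x`.
#' @return scalar ApEn.
#' @export
approx_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2L) stop("series too short for ApEn")
  phi <- function(mm) {
    cnt <- template_matches(x, mm, r, self = TRUE)
    mean(log(cnt / length(cnt)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B and A count self-excluded template
#' pairs within tolerance `r` at lengths m and m+1 over the same template
#' set (Chebyshev metric). Degenerate cases (no matches at either length)
#' return the documented sentinel 0.
#'
#' @inheritParams approx_entropy
#' @return scalar SampEn.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2L) stop("series too short for SampEn")
  nt <- n - m            # common template set for both lengths
  dm <- matrix(0, nt, nt)
  for (k in 0:(m - 1L)) {
    xi <- x[seq_len(nt) + k]
    dm <- pmax(dm, abs(outer(xi, xi, "-")))
  }
  b <- sum(dm <= r) - nt                      # exclude self-matches
  xm <- x[seq_len(nt) + m]
  dm1 <- pmax(dm, abs(outer(xm, xm, "-")))
  a <- sum(dm1 <= r) - nt
  if (a == 0 || b == 0) return(0)
  -log(a / b)
}

#' EDA features from a tonic/phasic decomposition
#'
#' @param d an `eda_decomposition`.
#' @param duration_s trial duration in seconds.
#' @return named numeric vector: SCR_count_per_min, SCR_mean_amplitude,
#'   tonic_mean, phasic_sd.
#' @export
eda_features <- function(d, duration_s) {
  stopifnot(inherits(d, "eda_decomposition"))
  nev <- nrow(d$scr_events)
  c(SCR_count_per_min = nev / (duration_s / 60),
    SCR_mean_amplitude = if (nev > 0) mean(d$scr_events$amplitude_uS) else 0,
    tonic_mean = mean(d$tonic),
    phasic_sd = stats::sd(d$phasic))
}

#' Respiration features from segmented breath cycles
#'
#' Mean, maximum and variance of per-cycle intensity (amplitude), plus
#' breathing rate and cycle-duration statistics. An empty cycle set returns
#' an all-`NA` flagged sentinel vector.
#'
#' @param cyc a `breath_cycles` object.
#' @param duration_s trial duration in seconds (unused by the default
#'   definitions, kept for alternative rate conventions).
#' @return named numeric vector of 7 features.
#' @export
rsp_features <- function(cyc, duration_s = NULL) {
  stopifnot(inherits(cyc, "breath_cycles"))
  if (cyc$empty) {
    out <- rep(NA_real_, length(.rsp_names))
    names(out) <- .rsp_names
    return(out)
  }
  amp <- cyc$cycles$amplitude
  dur <- cyc$cycles$end_s - cyc$cycles$start_s
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  c(amplitude_mean = mean(amp), amplitude_max = max(amp),
    amplitude_var = if (length(amp) > 1) stats::var(amp) else 0,
    breath_rate_mean = 60 / mean(dur),
    cycle_duration_mean = mean(dur), cycle_duration_sd = sd0(dur),
    amplitude_cv = if (mean(amp) > 0) sd0(amp) / mean(amp) else 0)
}

#' Extract the full 58-feature vector for one trial
#'
#' Runs the complete preprocessing chain (FIR band-pass + R-peak detection +
#' NN intervals for ECG; sparse deconvolution for EDA; cycle segmentation
#' for RSP) and evaluates all 58 registry features. Channel failures yield
#' `NA` sentinels for that channel's features plus an entry in the `flags`
#' attribute — never an exception.
#'
#' @param trial an `mm_trial`.
#' @return named numeric vector of exactly 58 registry features, with
#'   attributes `subject_id`, `trial_id`, `flags` (character vector of
#'   failed stages, possibly empty).
#' @export
extract_features <- function(trial) {
  stopifnot(inherits(trial, "mm_trial"))
  reg <- feature_registry()
  out <- rep(NA_real_, nrow(reg))
  names(out) <- reg$name
  flags <- character(0)

  ecg_vals <- tryCatch({
    filt <- fir_bandpass(trial$ecg$waveform, trial$ecg$fs)
    rp <- suppressWarnings(detect_r_peaks(filt, trial$ecg$fs))
    nn <- nn_intervals(rp)
    c(hrv_time(nn), hrv_frequency(nn), hrv_nonlinear(nn))
  }, error = function(e) { flags <<- c(flags, paste0("ecg: ", conditionMessage(e))); NULL })
  if (!is.null(ecg_vals)) out[names(ecg_vals)] <- ecg_vals

  eda_vals <- tryCatch({
    d <- suppressWarnings(eda_decompose(trial$eda$waveform, trial$eda$fs))
    eda_features(d, trial$duration_s)
  }, error = function(e) { flags <<- c(flags, paste0("eda: ", conditionMessage(e))); NULL })
  if (!is.null(eda_vals)) out[names(eda_vals)] <- eda_vals

  rsp_vals <- tryCatch({
    cyc <- suppressWarnings(segment_breaths(trial$rsp$waveform, trial$rsp$fs))
    rsp_features(cyc, trial$duration_s)
  }, error = function(e) { flags <<- c(flags, paste0("rsp: ", conditionMessage(e))); NULL })
  if (!is.null(rsp_vals)) out[names(rsp_vals)] <- rsp_vals

  if (any(!is.finite(out))) {
    flags <- c(flags, paste0("non-finite: ",
                             paste(names(out)[!is.finite(out)], collapse = ",")))
  }
  attr(out, "subject_id") <- trial$subject_id
  attr(out, "trial_id") <- trial$trial_id
  attr(out, "flags") <- flags
  out
}

#' Extract a feature table for a whole simulated dataset
#'
#' Applies [extract_features()] to every trial, optionally compensating each
#' subject's features by the features of the subject's neutral baseline
#' recording ([baseline_compensate()]).
#'
#' @param dataset result of [simulate_dataset()].
#' @param compensate `"subtract"`, `"divide"` or `"off"`.
#' @return data.frame: subject_id, trial_id, arousal, valence, familiarity,
#'   then the 58 feature columns in registry order.
#' @export
extract_features_dataset <- function(dataset,
                                     compensate = c("subtract", "divide", "off")) {
  compensate <- match.arg(compensate)
  base_feats <- if (compensate != "off") {
    lapply(dataset$baselines, extract_features)
  } else NULL
  rows <- lapply(dataset$trials, function(tr) {
    fv <- extract_features(tr)
    if (compensate != "off") {
      bl <- base_feats[[as.character(tr$subject_id)]]
      fv[] <- baseline_compensate(stats::setNames(as.numeric(fv), names(fv)),
                                  stats::setNames(as.numeric(bl), names(bl)),
                                  mode = compensate)
    }
    fv
  })
  feats <- do.call(rbind, lapply(rows, function(r) as.numeric(r)))
  colnames(feats) <- feature_registry()$name
  cbind(dataset$manifest[, c("subject_id", "trial_id", "arousal", "valence",
                             "familiarity")],
        as.data.frame(feats))
}
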