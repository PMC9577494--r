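#' Zero-phase FIR band-pass filter
#'
#' Designs a linear-phase windowed-sinc FIR band-pass (Hamming window via
#' [signal::fir1()]) and applies it forward-backward ([signal::filtfilt()])
#' so the net filter has zero phase and R-peak latencies are preserved. The
#' default 3-45 Hz band targets the QRS complex.
#'
#' @param x numeric waveform.
#' @param fs sampling rate (Hz).
#' @param low_hz,high_hz band edges; must satisfy `0 < low < high < fs/2`.
#' @param numtaps filter order + 1; defaults to 0.5 s of taps (made odd).
#' @return filtered waveform, same length as `x`.
#' @export
fir_bandpass <- function(x, fs, low_hz = 3, high_hz = 45, numtaps = NULL) {
  if (is.null(numtaps)) numtaps <- round(0.5 * fs)
  numtaps <- as.integer(numtaps)
  if (numtaps %% 2L == 0L) numtaps <- numtaps + 1L
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2")
  }
  min_len <- 3L * numtaps
  if (length(x) <= min_len) {
    stop(sprintf("signal too short for filtering: need > %d samples, got %d",
                 min_len, length(x)))
  }
  b <- signal::fir1(numtaps - 1L, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' Hamilton-style R-peak detection
#'
#' Works on a band-passed ECG: differentiate, rectify, smooth with an ~80 ms
#' moving-average envelope, then track an adaptive threshold from running
#' estimates of recent QRS and noise peak heights, enforce a 200 ms
#' refractory period, and finally back-search the local maximum of the
#' filtered ECG around each envelope detection to place the R point.
#'
#' @param x band-passed ECG waveform.
#' @param fs sampling rate (Hz).
#' @return object of class `rpeaks`: list with `sample_indices` (1-based),
#'   `times_s`, `fs`, and `empty` flag (TRUE with a warning when nothing is
#'   detected; never an error).
#' @export
detect_r_peaks <- function(x, fs) {
  refractory <- round(0.2 * fs)
  env <- moving_average(abs(c(0, diff(x))), round(0.08 * fs))
  out <- integer(0)
  cand <- local_maxima(env, min_dist = refractory)
  if (length(cand)) {
    qrs_est <- max(env[seq_len(min(length(env), round(2 * fs)))])
    noise_est <- qrs_est / 8
    thr <- function() noise_est + 0.3125 * (qrs_est - noise_est)
    last <- -Inf
    for (i in cand) {
      if (i - last < refractory) next
      if (env[i] >= thr()) {
        out <- c(out, i)
        last <- i
        qrs_est <- 0.8 * qrs_est + 0.2 * env[i]
      } else {
        noise_est <- 0.8 * noise_est + 0.2 * env[i]
      }
    }
  }
  if (length(out)) {
    # back-search: local max of the filtered ECG near the envelope crossing
    w <- round(0.1 * fs)
    out <- vapply(out, function(i) {
      lo <- max(1L, i - w); hi <- min(length(x), i + w)
      as.integer(lo + which.max(x[lo:hi]) - 1L)
    }, integer(1))
    out <- sort(unique(out))
    # re-apply refractory after back-search
    keep <- c(TRUE, diff(out) >= refractory)
    while (!all(keep)) {
      out <- out[keep]
      keep <- c(TRUE, diff(out) >= refractory)
    }
  }
  empty <- length(out) == 0L
  if (empty) warning("no R-peaks detected")
  structure(list(sample_indices = out, times_s = (out - 1) / fs, fs = fs,
                 empty = empty),
            class = "rpeaks")
}

#' @export
print.rpeaks <- function(x, ...) {
  cat(sprintf("R-peak series: %d peaks @ %g Hz", length(x$sample_indices),
              x$fs))
  if (length(x$times_s) > 1) {
    cat(sprintf(" (mean HR %.1f bpm)", 60 / mean(diff(x$times_s))))
  }
  cat("\n")
  invisible(x)
}

#' Normal-to-normal intervals from detected R-peaks
#'
#' Successive R-R differences in ms, with artifact rejection: intervals
#' outside `(range_ms[1], range_ms[2])` or deviating more than
#' `max_rel_dev` from the running median of the last 11 accepted intervals
#' are removed (and counted in `n_rejected`).
#'
#' @param rpeaks an `rpeaks` object (or numeric R times in seconds).
#' @param range_ms physiological admissible interval range (ms).
#' @param max_rel_dev maximum relative deviation from the running median.
#' @return object of class `nn_series`: `intervals_ms`, `t_anchor_s` (onset
#'   time of each surviving interval), `n_rejected`.
#' @export
nn_intervals <- function(rpeaks, range_ms = c(250, 3000), max_rel_dev = 0.3) {
  times <- if (inherits(rpeaks, "rpeaks")) rpeaks$times_s else as.numeric(rpeaks)
  if (length(times) < 3L) stop("need at least 3 R-peaks to form NN intervals")
  iv <- diff(times) * 1000
  anchor <- times[-length(times)]
  keep <- logical(length(iv))
  accepted <- numeric(0)
  for (i in seq_along(iv)) {
    ok <- iv[i] > range_ms[1] && iv[i] < range_ms[2]
    if (ok && length(accepted) >= 3L) {
      med <- stats::median(utils::tail(accepted, 11L))
      ok <- abs(iv[i] - med) <= max_rel_dev * med
    }
    keep[i] <- ok
    if (ok) accepted <- c(accepted, iv[i])
  }
  if (sum(keep) < 2L) stop("fewer than 2 NN intervals survive artifact rejection")
  structure(list(intervals_ms = iv[keep], t_anchor_s = anchor[keep],
                 n_rejected = sum(!keep)),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("NN series: %d intervals (%d rejected), mean %.1f ms, SDNN %.1f ms\n",
              length(x$intervals_ms), x$n_rejected, mean(x$intervals_ms),
              stats::sd(x$intervals_ms)))
  invisible(x)
}

#' Tonic/phasic EDA decomposition by sparse non-negative deconvolution
#'
#' Models skin conductance as `tonic + bateman_kernel * driver` with a
#' smooth tonic component and a sparse non-negative SCR driver, in the
#' spirit of convex-optimization decompositions. The tonic is a smoothing
#' spline through a running low percentile; the driver solves a
#' non-negative L1-regularized least-squares deconvolution by FISTA.
#' SCR events are driver mass clusters whose reconstructed amplitude
#' exceeds `min_amp_uS`.
#'
#' @param x EDA waveform (microsiemens, non-negative).
#' @param fs sampling rate (Hz).
#' @param min_amp_uS SCR detection threshold (microsiemens).
#' @param lambda L1 penalty weight, relative to the data scale.
#' @param n_iter FISTA iterations.
#' @return object of class `eda_decomposition`: `tonic`, `phasic`, `driver`
#'   waveforms, `scr_events` (data.frame onset_s, amplitude_uS),
#'   `residual_rel` (relative reconstruction error), `fallback` flag.
#' @export
eda_decompose <- function(x, fs, min_amp_uS = 0.01, lambda = 0.01,
                          n_iter = 120L) {
  if (any(x < -1e-6)) stop("EDA must be non-negative")
  if (length(x) / fs < 30) stop("EDA decomposition needs >= 30 s of signal")
  n <- length(x)
  res <- tryCatch({
    # --- tonic: smoothing spline through an 8-s running lower percentile
    win <- max(3L, round(8 * fs))
    q <- stats::runmed(x, k = win + (1 - win %% 2L))
    lowq <- moving_average(pmin(x, q), win)
    t_idx <- seq_len(n)
    sp <- stats::smooth.spline(t_idx, lowq, df = max(4, round(n / fs / 20)))
    tonic <- stats::predict(sp, t_idx)$y
    target <- x - tonic
    # --- FISTA for 0.5||K u - target||^2 + lambda'||u||_1, u >= 0
    k <- bateman_kernel(fs)
    convK <- function(u) fft_conv(u, k)
    corrK <- function(r) fft_corr(r, k)
    # Lipschitz bound for K^T K: peak spectral power of the kernel
    m_fft <- stats::nextn(n + length(k), 2)
    L <- max(Mod(stats::fft(c(k, numeric(m_fft - length(k)))))^2) * 1.05
    lam <- lambda * max(abs(target)) * sum(k)
    u <- numeric(n); z <- u; tk <- 1
    for (it in seq_len(n_iter)) {
      grad <- corrK(convK(z) - target)
      u_new <- pmax(z - grad / L - lam / L, 0)
      tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- u_new + ((tk - 1) / tk_new) * (u_new - u)
      u <- u_new; tk <- tk_new
    }
    phasic <- convK(u)
    # --- cluster driver mass into events (gaps > 0.5 s split events)
    nz <- which(u > 1e-6)
    events <- data.frame(onset_s = numeric(0), amplitude_uS = numeric(0))
    if (length(nz)) {
      grp <- cumsum(c(1, diff(nz) > 0.5 * fs))
      on <- tapply(nz, grp, function(ii) sum(ii * u[ii]) / sum(u[ii]))
      amp <- tapply(nz, grp, function(ii) sum(u[ii])) * max(k)
      keep <- amp >= min_amp_uS
      events <- data.frame(onset_s = (as.numeric(on[keep]) - 1) / fs,
                           amplitude_uS = as.numeric(amp[keep]))
    }
    list(tonic = tonic, phasic = phasic, driver = u, scr_events = events,
         fallback = FALSE)
  }, error = function(e) {
    warning("EDA deconvolution failed (", conditionMessage(e),
            "); falling back to low-pass/high-pass split")
    k_smooth <- max(3L, round(10 * fs))
    tonic <- moving_average(x, k_smooth)
    phasic <- pmax(x - tonic, 0)
    list(tonic = tonic, phasic = phasic, driver = numeric(n),
         scr_events = data.frame(onset_s = numeric(0),
                                 amplitude_uS = numeric(0)),
         fallback = TRUE)
  })
  res$residual_rel <- sqrt(sum((x - res$tonic - res$phasic)^2) / sum(x^2))
  structure(res, class = "eda_decomposition")
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf("EDA decomposition: %d SCR events, tonic mean %.2f uS, relative residual %.3f%s\n",
              nrow(x$scr_events), mean(x$tonic), x$residual_rel,
              if (x$fallback) " (fallback split)" else ""))
  invisible(x)
}

#' Breath-cycle segmentation
#'
#' Detrends and smooths the respiration trace, then segments trough-to-trough
#' cycles from alternating extrema with a minimum period of 1 s and a
#' minimum prominence of `prominence_frac` of the signal SD.
#'
#' @param x respiration waveform.
#' @param fs sampling rate (Hz).
#' @param min_period_s minimum admissible cycle period (s).
#' @param prominence_frac minimum extremum prominence, as a fraction of the
#'   detrended signal SD.
#' @return object of class `breath_cycles`: data.frame `cycles` with
#'   `start_s`, `peak_s`, `end_s`, `amplitude`, plus `empty` flag (with a
#'   warning when no cycle is found).
#' @export
segment_breaths <- function(x, fs, min_period_s = 1, prominence_frac = 0.1) {
  if (length(x) / fs < 10) stop("breath segmentation needs >= 10 s of signal")
  xd <- x - moving_average(x, round(20 * fs))     # remove slow drift
  xs <- moving_average(xd, max(1L, round(0.25 * fs)))
  sdx <- stats::sd(xs)
  cycles <- data.frame(start_s = numeric(0), peak_s = numeric(0),
                       end_s = numeric(0), amplitude = numeric(0))
  if (sdx > 1e-12) {
    dist <- round(min_period_s * fs)
    peaks <- local_maxima(xs, dist, min_height = prominence_frac * sdx)
    troughs <- local_maxima(-xs, dist, min_height = prominence_frac * sdx)
    # boundary samples count as troughs when the signal starts/ends low
    # (otherwise the first and last breath cycles are systematically lost)
    n_s <- length(xs)
    low <- stats::quantile(xs, 0.25)
    if (xs[1] <= low && (!length(troughs) || min(troughs) > dist)) {
      troughs <- c(1L, troughs)
    }
    if (xs[n_s] <= low && (!length(troughs) || max(troughs) < n_s - dist)) {
      troughs <- c(troughs, n_s)
    }
    ext <- rbind(data.frame(i = peaks, kind = 1), data.frame(i = troughs, kind = -1))
    ext <- ext[order(ext$i), ]
    # enforce alternation: within a run of equal kind keep the most extreme
    if (nrow(ext) > 1) {
      run <- cumsum(c(1, diff(ext$kind) != 0))
      pick <- tapply(seq_len(nrow(ext)), run, function(ii) {
        if (ext$kind[ii[1]] == 1) ii[which.max(xs[ext$i[ii]])]
        else ii[which.min(xs[ext$i[ii]])]
      })
      ext <- ext[as.integer(pick), ]
    }
    ti <- ext$i[ext$kind == -1]
    for (j in seq_len(max(0, length(ti) - 1L))) {
      seg <- ext[ext$i > ti[j] & ext$i < ti[j + 1] & ext$kind == 1, ]
      if (nrow(seg) != 1L) next
      amp <- xs[seg$i] - (xs[ti[j]] + xs[ti[j + 1]]) / 2
      if (amp < prominence_frac * sdx) next
      cycles <- rbind(cycles,
                      data.frame(start_s = (ti[j] - 1) / fs,
                                 peak_s = (seg$i - 1) / fs,
                                 end_s = (ti[j + 1] - 1) / fs,
                                 amplitude = amp))
    }
  }
  empty <- nrow(cycles) == 0L
  if (empty) warning("no breath cycles detected")
  structure(list(cycles = cycles, empty = empty), class = "breath_cycles")
}

#' @export
print.breath_cycles <- function(x, ...) {
  if (x$empty) cat("Breath cycles: none detected\n")
  else cat(sprintf("Breath cycles: %d cycles, mean duration %.2f s, mean amplitude %.2f\n",
                   nrow(x$cycles), mean(x$cycles$end_s - x$cycles$start_s),
                   mean(x$cycles$amplitude)))
  invisible(x)
}

#' Per-subject baseline compensation of a feature vector
#'
#' Removes between-subject offsets by referencing each trial's features to
#' the subject's 60-s neutral baseline recording.
#'
#' @param trial_features,baseline_features named numeric vectors with
#'   identical names.
#' @param mode `"subtract"` (default), `"divide"`, or `"off"`.
#' @return compensated named numeric vector.
#' @export
baseline_compensate <- function(trial_features, baseline_features,
                                mode = c("subtract", "divide", "off")) {
  mode <- match.arg(mode)
  if (!identical(names(trial_features), names(baseline_features))) {
    stop("feature names of trial and baseline vectors do not match")
  }
  switch(mode,
         off = trial_features,
         subtract = trial_features - baseline_features,
         divide = trial_features / ifelse(abs(baseline_features) < 1e-12,
                                          1, baseline_features))
}
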