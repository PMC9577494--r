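#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic per-(seed, id) sub-seed, kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.numeric(seed)
  for (id in ids) s <- (s * 69069 + as.numeric(id) * 7919 + 1) %% 2147483647
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Linear resampling of a waveform to a fixed number of samples
#'
#' @param x numeric waveform.
#' @param n_out target length.
#' @return numeric vector of length `n_out`.
#' @keywords internal
resample_linear <- function(x, n_out) {
  n <- length(x)
  if (n == n_out) return(x)
  if (n == 1L) return(rep(x, n_out))
  stats::approx(seq_len(n), x, xout = seq(1, n, length.out = n_out))$y
}

# Centered moving average with edge shrinkage.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of strict local maxima with a minimum separation (in samples) and
# minimum height. Greedy by descending height, as in standard peak pickers.
local_maxima <- function(x, min_dist = 1L, min_height = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand) || min_dist <= 1L) return(cand)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  sel <- integer(0)
  for (i in cand) {
    if (!length(sel) || all(abs(sel - i) >= min_dist)) sel <- c(sel, i)
  }
  sort(sel)
}

# Welch power spectral density with Hann windows and 50% overlap.
# Returns a data.frame(freq, psd) with psd in x-units^2 per Hz.
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, 256L)
  nperseg <- min(n, as.integer(nperseg))
  step <- max(1L, nperseg %/% 2L)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(win^2)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- stats::fft(seg)[seq_len(nfreq)]
    p <- (Mod(sp)^2) / (fs * u)
    # one-sided: double everything except DC (and Nyquist when nperseg even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  data.frame(freq = (seq_len(nfreq) - 1L) * fs / nperseg,
             psd = acc / length(starts))
}

# Fast causal convolution y[t] = sum_i u[i] k[t-i+1], first n samples.
fft_conv <- function(u, k) {
  n <- length(u)
  m <- stats::nextn(n + length(k), 2)
  Fu <- stats::fft(c(u, numeric(m - n)))
  Fk <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(Fu * Fk, inverse = TRUE))[seq_len(n)] / m
}

# Adjoint of fft_conv: cross-correlation (K^T r)[i] = sum_t k[t-i+1] r[t].
fft_corr <- function(r, k) {
  n <- length(r)
  m <- stats::nextn(n + length(k), 2)
  Fr <- stats::fft(c(r, numeric(m - n)))
  Fk <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(Fr * Conj(Fk), inverse = TRUE))[seq_len(n)] / m
}

# Trapezoidal band power from a welch_psd() frame over [lo, hi] Hz.
band_power <- function(psd, lo, hi) {
  f <- psd$freq; p <- psd$psd
  sel <- f >= lo & f <= hi
  if (sum(sel) < 2L) return(0)
  fi <- f[sel]; pi_ <- p[sel]
  sum(diff(fi) * (pi_[-1] + pi_[-length(pi_)]) / 2)
}
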