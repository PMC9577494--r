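# Shared fixtures, built lazily and memoised so heavy simulations run once
# per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 20 subjects x 12 trials of 60 s with a strong arousal effect and low
# noise: the separable study condition.
strong_dataset <- function() {
  fixture("strong_ds", function() {
    cfg <- sim_config(n_subjects = 20, trials_per_subject = 12,
                      trial_duration_s = 60, arousal_effect = 3,
                      noise_sd = c(ecg = 0.02, eda = 0.005, rsp = 0.02),
                      seed = 11)
    simulate_dataset(cfg)
  })
}

strong_features <- function() {
  fixture("strong_feats", function() extract_features_dataset(strong_dataset()))
}

# small quick dataset for plumbing tests
small_dataset <- function() {
  fixture("small_ds", function() {
    cfg <- sim_config(n_subjects = 4, trials_per_subject = 6,
                      trial_duration_s = 34, arousal_effect = 3, seed = 21)
    simulate_dataset(cfg)
  })
}

# Fraction of true events with at least one detection within tol_s
# (window-based recall, the natural reading for clustered events).
window_recall <- function(detected, truth, tol_s) {
  if (!length(truth)) return(1)
  if (!length(detected)) return(0)
  mean(vapply(truth, function(t0) min(abs(detected - t0)) <= tol_s,
              logical(1)))
}

# Match detected event times against ground truth within a tolerance;
# greedy one-to-one matching in time order.
match_events <- function(detected, truth, tol_s) {
  used <- logical(length(detected))
  tp <- 0L
  for (t0 in truth) {
    d <- abs(detected - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  fp <- sum(!used)
  fn <- length(truth) - tp
  list(tp = tp, fp = fp, fn = fn,
       recall = tp / max(1, length(truth)),
       precision = tp / max(1, length(detected)),
       f1 = 2 * tp / max(1, 2 * tp + fp + fn))
}

# Brute-force reference implementations for layer-oracle tests.
naive_conv1d <- function(x, W, b, stride) {
  L <- dim(x)[1]; C <- dim(x)[2]; B <- dim(x)[3]
  K <- dim(W)[1]; F_ <- dim(W)[3]
  Lout <- ceiling(L / stride)
  pad <- max((Lout - 1) * stride + K - L, 0)
  pl <- pad %/% 2
  out <- array(0, c(Lout, F_, B))
  for (bb in seq_len(B)) for (f in seq_len(F_)) for (j in seq_len(Lout)) {
    s <- 0
    for (k in seq_len(K)) for (c_ in seq_len(C)) {
      p <- (j - 1) * stride + k - pl
      if (p >= 1 && p <= L) s <- s + W[k, c_, f] * x[p, c_, bb]
    }
    out[j, f, bb] <- s + b[f]
  }
  out
}

naive_max_pool <- function(x, pool) {
  L2 <- dim(x)[1] %/% pool
  out <- array(0, c(L2, dim(x)[2], dim(x)[3]))
  for (bb in seq_len(dim(x)[3])) for (c_ in seq_len(dim(x)[2])) {
    for (j in seq_len(L2)) {
      out[j, c_, bb] <- max(x[((j - 1) * pool + 1):(j * pool), c_, bb])
    }
  }
  out
}

naive_gap <- function(x) {
  out <- matrix(0, dim(x)[2], dim(x)[3])
  for (bb in seq_len(dim(x)[3])) for (c_ in seq_len(dim(x)[2])) {
    out[c_, bb] <- sum(x[, c_, bb]) / dim(x)[1]
  }
  out
}
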