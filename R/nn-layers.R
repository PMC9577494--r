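# 1D CNN layer primitives. Conventions: a conv feature map is an array
# (length, channels, batch); dense activations are (units, batch). All
# layers provide exact analytic backward passes; the conv uses an im2col
# gather plus one BLAS matrix product per call.

#' 1D convolution with same padding
#'
#' `out[j, f, b] = sum_{k, c} W[k, c, f] * x[(j-1)*stride + k - pad, c, b]
#' + bias[f]`, with zero padding chosen so the output length is
#' `ceiling(L / stride)`.
#'
#' @param x input array `(L, C, B)` (a plain vector or `(L, C)` matrix is
#'   promoted).
#' @param W kernel array `(K, C, F)`.
#' @param bias numeric length `F`.
#' @param stride positive integer.
#' @param cache logical; keep the gathered input for a backward pass.
#' @return array `(Lout, F, B)`; with `cache = TRUE`, attribute `"cache"`
#'   holds what [conv1d_backward()] needs.
#' @export
conv1d_forward <- function(x, W, bias = NULL, stride = 1L, cache = FALSE) {
  x <- promote3(x)
  d <- dim(x); L <- d[1]; C <- d[2]; B <- d[3]
  K <- dim(W)[1]; F_ <- dim(W)[3]
  if (dim(W)[2] != C) stop(sprintf("channel mismatch: input has %d, kernel expects %d",
                                   C, dim(W)[2]))
  if (is.null(bias)) bias <- numeric(F_)
  stride <- as.integer(stride)
  Lout <- as.integer(ceiling(L / stride))
  pad <- max((Lout - 1L) * stride + K - L, 0L)
  pl <- pad %/% 2L
  idx <- outer(seq_len(K), (seq_len(Lout) - 1L) * stride, "+") - pl
  idx[idx < 1L | idx > L] <- L + 1L
  Xp <- rbind(matrix(x, L, C * B), 0)
  Xg <- Xp[as.vector(idx), , drop = FALSE]
  dim(Xg) <- c(K, Lout, C, B)
  Xg <- aperm(Xg, c(1, 3, 2, 4))
  dim(Xg) <- c(K * C, Lout * B)
  Y <- crossprod(Xg, matrix(W, K * C, F_))
  Y <- Y + rep(bias, each = Lout * B)
  dim(Y) <- c(Lout, B, F_)
  out <- aperm(Y, c(1, 3, 2))
  if (cache) {
    attr(out, "cache") <- list(Xg = Xg, idx = idx, L = L, C = C, B = B,
                               K = K, F_ = F_, Lout = Lout, W = W)
  }
  out
}

# Gradients of conv1d_forward. dout: (Lout, F, B). Returns list(dx, dW, db).
conv1d_backward <- function(dout, cache) {
  with(cache, {
    dYm <- matrix(aperm(dout, c(1, 3, 2)), Lout * B, F_)  # (Lout*B, F)
    dWm <- Xg %*% dYm                                     # (K*C, F)
    db <- colSums(dYm)
    dXg <- matrix(W, K * C, F_) %*% t(dYm)                # (K*C, Lout*B)
    dim(dXg) <- c(K, C, Lout, B)
    dXg <- aperm(dXg, c(1, 3, 2, 4))                      # (K, Lout, C, B)
    dXp <- matrix(0, L + 1L, C * B)
    for (k in seq_len(K)) {
      slice <- matrix(dXg[k, , , ], Lout, C * B)
      rows <- idx[k, ]
      dXp[rows, ] <- dXp[rows, ] + slice
    }
    dx <- array(dXp[seq_len(L), , drop = FALSE], c(L, C, B))
    list(dx = dx, dW = array(dWm, c(K, C, F_)), db = db)
  })
}

#' Rectified linear unit
#' @param x numeric array.
#' @return elementwise `max(x, 0)`, shape preserved.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# New batch-norm state for n_features channels/units.
bn_state <- function(n_features) {
  list(gamma = rep(1, n_features), beta = rep(0, n_features),
       run_mean = rep(0, n_features), run_var = rep(1, n_features))
}

#' Batch normalization
#'
#' Per-feature standardization `(x - mu_B)/sqrt(sigma2_B + eps)` followed by
#' the learned affine map `gamma * xhat + beta`. For conv maps `(L, C, B)`
#' the feature axis is the channel and statistics pool over length and
#' batch; for dense activations `(D, B)` statistics pool over the batch.
#' Training mode uses batch statistics (batch size >= 2 required) and
#' updates running statistics; inference mode uses the running statistics.
#'
#' @param x array `(L, C, B)` or matrix `(D, B)`.
#' @param state list from `bn_state()`: gamma, beta, run_mean, run_var.
#' @param training logical.
#' @param eps numerical guard added to the variance.
#' @param momentum running-statistics decay.
#' @return list with `out`, updated `state`, and `cache` for the backward
#'   pass (training mode).
#' @export
batch_norm <- function(x, state, training = TRUE, eps = 1e-5,
                       momentum = 0.9) {
  conv <- length(dim(x)) == 3L
  xm <- if (conv) {
    d <- dim(x)
    matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])   # (L*B, C)
  } else t(x)                                          # (B, D)
  m <- nrow(xm)
  if (training && m < 2L) stop("batch normalization in training mode needs a batch of >= 2")
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2           # biased batch variance
    state$run_mean <- momentum * state$run_mean + (1 - momentum) * mu
    state$run_var <- momentum * state$run_var + (1 - momentum) * va
  } else {
    mu <- state$run_mean
    va <- state$run_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
  ym <- sweep(sweep(xhat, 2, state$gamma, "*"), 2, state$beta, "+")
  out <- if (conv) {
    d <- dim(x)
    aperm(array(ym, c(d[1], d[3], d[2])), c(1, 3, 2))
  } else t(ym)
  list(out = out, state = state,
       cache = if (training) list(xhat = xhat, invstd = invstd,
                                  gamma = state$gamma, conv = conv,
                                  dims = dim(x)) else NULL)
}

# Backward for batch_norm. dout has the shape of the forward input.
batch_norm_backward <- function(dout, cache) {
  dym <- if (cache$conv) {
    d <- cache$dims
    matrix(aperm(dout, c(1, 3, 2)), d[1] * d[3], d[2])
  } else t(dout)
  m <- nrow(dym)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$gamma, "*")
  dxm <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dym), byrow = TRUE) -
                 sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
               2, cache$invstd, "*")
  dx <- if (cache$conv) {
    d <- cache$dims
    aperm(array(dxm, c(d[1], d[3], d[2])), c(1, 3, 2))
  } else t(dxm)
  dx <- unname(dx)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Non-overlapping 1D max pooling
#'
#' Maps each window of `pool_size` consecutive samples to its maximum;
#' output length is `floor(L / pool_size)` (tail samples beyond the last
#' full window are dropped).
#'
#' @param x array `(L, C, B)` (vector/matrix promoted).
#' @param pool_size window length.
#' @param cache keep argmax positions for a backward pass.
#' @return array `(floor(L/pool_size), C, B)`.
#' @export
max_pool <- function(x, pool_size = 2L, cache = FALSE) {
  x <- promote3(x)
  d <- dim(x); L <- d[1]
  if (L < pool_size) stop("input shorter than pool_size")
  L2 <- L %/% pool_size
  xr <- array(x[seq_len(L2 * pool_size), , , drop = FALSE],
              c(pool_size, L2, d[2], d[3]))
  out <- apply(xr, c(2, 3, 4), max)
  if (cache) {
    arg <- apply(xr, c(2, 3, 4), which.max)
    attr(out, "cache") <- list(arg = arg, pool_size = pool_size, dims = d,
                               L2 = L2)
  }
  out
}

max_pool_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  arg <- cache$arg
  pos <- (slice.index(arg, 1) - 1L) * cache$pool_size + arg
  off <- ((slice.index(arg, 2) - 1L) + (slice.index(arg, 3) - 1L) * d[2]) * d[1]
  dx[as.vector(pos + off)] <- as.vector(dout)
  dx
}

#' Global average pooling
#'
#' Per-filter temporal mean, reducing an `(L, C, B)` feature map to a
#' `(C, B)` matrix.
#'
#' @param x array `(L, C, B)` (matrix promoted as a single-batch map).
#' @return matrix `(C, B)`.
#' @export
global_avg_pool <- function(x) {
  x <- promote3(x)
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1], d[2] * d[3])), d[2], d[3])
}

global_avg_pool_backward <- function(dout, dims) {
  array(rep(as.vector(dout), each = dims[1]) / dims[1], dims)
}

# Promote vector -> (L,1,1), matrix (L,C) -> (L,C,1).
promote3 <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  else if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

# Softmax cross-entropy head. logits (n_classes, B), y integer 1..n_classes.
softmax_xent <- function(logits, y) {
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  p <- sweep(ex, 2, colSums(ex), "/")
  B <- ncol(logits)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-12)))
  onehot <- matrix(0, nrow(logits), B)
  onehot[cbind(y, seq_len(B))] <- 1
  list(loss = loss, probs = p, dlogits = (p - onehot) / B)
}

# --- Adam optimizer over a flat named list of numeric arrays -------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
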