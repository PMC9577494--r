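#' Convolution block specification
#'
#' One block = two same-padding 1D conv layers (each followed by ReLU and
#' batch normalization) and a trailing max-pool.
#'
#' @param filters number of filters (both conv layers).
#' @param kernel_size kernel length (both conv layers).
#' @param strides integer vector of length 2: stride of each conv layer.
#' @param pool_size max-pool window (default 2).
#' @return list of class `conv_block_spec`.
#' @export
conv_block_spec <- function(filters, kernel_size, strides = c(1L, 1L),
                            pool_size = 2L) {
  stopifnot(filters >= 1, kernel_size >= 1, length(strides) == 2,
            all(strides >= 1), pool_size >= 1)
  structure(list(filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 strides = as.integer(strides),
                 pool_size = as.integer(pool_size)),
            class = "conv_block_spec")
}

#' Branch configuration for one input modality
#'
#' @param input_name one of `"ecg"`, `"eda"`, `"rsp"`, `"stacked"`.
#' @param input_length number of input samples consumed by the branch.
#' @param blocks list of three [conv_block_spec()].
#' @param in_channels input channels (3 for the stacked variant).
#' @return list of class `branch_config` with the derived `gap_width`
#'   (= last block's filter count) and the branch's minimum valid input
#'   length.
#' @export
branch_config <- function(input_name, input_length, blocks,
                          in_channels = 1L) {
  stopifnot(length(blocks) >= 1)
  min_len <- branch_min_length(blocks)
  if (input_length < min_len) {
    stop(sprintf("branch '%s': input length %d below the minimum %d required by its stride/pool schedule",
                 input_name, input_length, min_len))
  }
  structure(list(input_name = input_name,
                 input_length = as.integer(input_length),
                 in_channels = as.integer(in_channels),
                 blocks = blocks,
                 gap_width = blocks[[length(blocks)]]$filters,
                 min_input_length = min_len),
            class = "branch_config")
}

# Smallest input length for which every pooled map keeps >= 1 sample:
# work backwards through the stride/pool schedule.
branch_min_length <- function(blocks) {
  need <- 1L
  for (blk in rev(blocks)) {
    need <- need * blk$pool_size                  # before pooling
    for (s in rev(blk$strides)) {
      need <- (need - 1L) * s + 1L                # before that conv stride
    }
  }
  need
}

# Per-branch output length schedule (after each block's pool).
branch_shapes <- function(branch) {
  L <- branch$input_length
  out <- list()
  for (j in seq_along(branch$blocks)) {
    blk <- branch$blocks[[j]]
    for (s in blk$strides) L <- as.integer(ceiling(L / s))
    L <- L %/% blk$pool_size
    out[[j]] <- c(length = L, filters = blk$filters)
  }
  out
}

# The three-branch default parameterization: filters x kernel per block
# (128x32, 128x32, 128x16 | 64x16, 64x16, 32x4 | 128x16, 64x16, 64x8), with
# per-branch stride schedules (2,2)/(2,1)/(1,1), (2,2)/(3,3)/(1,1) and
# (3,3)/(2,2)/(1,1), GAP widths 128/32/64 and concatenated width 224.
default_branches <- function(input_lengths = c(ecg = 2560L, eda = 640L,
                                               rsp = 640L)) {
  list(
    branch_config("ecg", input_lengths[["ecg"]], list(
      conv_block_spec(128, 32, c(2, 2)),
      conv_block_spec(128, 32, c(2, 1)),
      conv_block_spec(128, 16, c(1, 1)))),
    branch_config("eda", input_lengths[["eda"]], list(
      conv_block_spec(64, 16, c(2, 2)),
      conv_block_spec(64, 16, c(3, 3)),
      conv_block_spec(32, 4, c(1, 1)))),
    branch_config("rsp", input_lengths[["rsp"]], list(
      conv_block_spec(128, 16, c(3, 3)),
      conv_block_spec(64, 16, c(2, 2)),
      conv_block_spec(64, 8, c(1, 1))))
  )
}

#' Multi-input DCNN architecture specification
#'
#' One branch per modality (filters not shared between branches), each
#' ending in global average pooling; branch outputs are concatenated and
#' fed to two fully connected layers (hidden ReLU layer + softmax output).
#' The default parameterization concatenates GAP widths 128 + 32 + 64 =
#' 224.
#'
#' @param branches list of [branch_config()]; defaults to the three-branch
#'   default parameterization.
#' @param fc_hidden hidden fully connected width.
#' @param n_classes output classes (2).
#' @return object of class `midcnn_spec` with derived `concat_width`.
#' @export
midcnn_spec <- function(branches = default_branches(), fc_hidden = 64L,
                        n_classes = 2L) {
  stopifnot(length(branches) >= 1)
  structure(list(branches = branches,
                 fc_hidden = as.integer(fc_hidden),
                 n_classes = as.integer(n_classes),
                 concat_width = sum(vapply(branches, `[[`, integer(1),
                                           "gap_width"))),
            class = "midcnn_spec")
}

#' Reduced desk-scale architecture preset
#'
#' Same three-branch, three-block topology as the default specification but
#' with fewer filters and shorter inputs, sized for CPU training in
#' simulation studies.
#'
#' @param input_lengths named lengths for the ecg/eda/rsp branches.
#' @return a `midcnn_spec`.
#' @export
midcnn_spec_desk <- function(input_lengths = c(ecg = 512L, eda = 128L,
                                               rsp = 128L)) {
  mk <- function(name, len, f) {
    branch_config(name, len, list(
      conv_block_spec(f[1], 8, c(2, 1)),
      conv_block_spec(f[2], 8, c(1, 1)),
      conv_block_spec(f[3], 4, c(1, 1))))
  }
  midcnn_spec(list(mk("ecg", input_lengths[["ecg"]], c(16, 16, 16)),
                   mk("eda", input_lengths[["eda"]], c(8, 8, 8)),
                   mk("rsp", input_lengths[["rsp"]], c(8, 8, 8))),
              fc_hidden = 32L)
}

#' Single-input DCNN specification
#'
#' One trunk shaped like the first default branch, consuming either a
#' single modality or the three modalities resampled to a common length and
#' stacked as channels of one input (whose first-layer kernels then span
#' all channels, unlike the multi-input model).
#'
#' @param modality `"ecg"`, `"eda"`, `"rsp"` or `"stacked"`.
#' @param input_length input samples.
#' @param filters per-block filter counts (length 3).
#' @param kernels per-block kernel sizes (length 3).
#' @param strides list of 3 stride pairs.
#' @param fc_hidden hidden fully connected width.
#' @return a `midcnn_spec` with a single branch.
#' @export
single_dcnn_spec <- function(modality = c("ecg", "eda", "rsp", "stacked"),
                             input_length = 2560L,
                             filters = c(128L, 128L, 128L),
                             kernels = c(32L, 32L, 16L),
                             strides = list(c(2, 2), c(2, 1), c(1, 1)),
                             fc_hidden = 64L) {
  modality <- match.arg(modality)
  blocks <- lapply(1:3, function(j) {
    conv_block_spec(filters[j], kernels[j], strides[[j]])
  })
  midcnn_spec(list(branch_config(modality, input_length, blocks,
                                 in_channels = if (modality == "stacked") 3L else 1L)),
              fc_hidden = fc_hidden)
}

#' Instantiate an untrained multi-input DCNN
#'
#' Allocates He-initialized kernels, biases and batch-norm states for every
#' layer of the specification. Two builds with the same seed are identical.
#'
#' @param spec a [midcnn_spec()].
#' @param seed RNG seed for the initialization.
#' @return object of class `midcnn` (untrained; see [fit_midcnn()]).
#' @export
build_midcnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "midcnn_spec"))
  params <- list()
  run <- list()
  with_seed(seed, {
    for (i in seq_along(spec$branches)) {
      br <- spec$branches[[i]]
      cin <- br$in_channels
      for (j in seq_along(br$blocks)) {
        blk <- br$blocks[[j]]
        for (l in 1:2) {
          p <- sprintf("br%d.b%d.c%d.", i, j, l)
          fan_in <- blk$kernel_size * cin
          params[[paste0(p, "W")]] <-
            array(stats::rnorm(blk$kernel_size * cin * blk$filters,
                               0, sqrt(2 / fan_in)),
                  c(blk$kernel_size, cin, blk$filters))
          params[[paste0(p, "b")]] <- numeric(blk$filters)
          params[[paste0(p, "gamma")]] <- rep(1, blk$filters)
          params[[paste0(p, "beta")]] <- numeric(blk$filters)
          run[[paste0(p, "mean")]] <- numeric(blk$filters)
          run[[paste0(p, "var")]] <- rep(1, blk$filters)
          cin <- blk$filters
        }
      }
    }
    params$fc1.W <- matrix(stats::rnorm(spec$fc_hidden * spec$concat_width,
                                        0, sqrt(2 / spec$concat_width)),
                           spec$fc_hidden, spec$concat_width)
    params$fc1.b <- numeric(spec$fc_hidden)
    params$fc2.W <- matrix(stats::rnorm(spec$n_classes * spec$fc_hidden,
                                        0, sqrt(2 / spec$fc_hidden)),
                           spec$n_classes, spec$fc_hidden)
    params$fc2.b <- numeric(spec$n_classes)
  })
  structure(list(spec = spec, params = params, run = run, norm = NULL,
                 classes = NULL, history = NULL, fitted = FALSE,
                 seed = seed),
            class = "midcnn")
}

# Batch-norm state view for one conv layer.
layer_bn <- function(model, p) {
  list(gamma = model$params[[paste0(p, "gamma")]],
       beta = model$params[[paste0(p, "beta")]],
       run_mean = model$run[[paste0(p, "mean")]],
       run_var = model$run[[paste0(p, "var")]])
}

# Full forward pass. xs: list of (L, C, B) arrays, one per branch.
# Returns logits, per-layer caches (training mode) and updated running
# statistics.
midcnn_forward <- function(model, xs, training = FALSE) {
  spec <- model$spec
  caches <- list()
  gaps <- vector("list", length(spec$branches))
  for (i in seq_along(spec$branches)) {
    br <- spec$branches[[i]]
    h <- xs[[i]]
    for (j in seq_along(br$blocks)) {
      blk <- br$blocks[[j]]
      for (l in 1:2) {
        p <- sprintf("br%d.b%d.c%d.", i, j, l)
        h <- conv1d_forward(h, model$params[[paste0(p, "W")]],
                            model$params[[paste0(p, "b")]],
                            stride = blk$strides[l], cache = training)
        if (training) caches[[paste0(p, "conv")]] <- attr(h, "cache")
        attr(h, "cache") <- NULL
        mask <- h > 0
        h <- relu(h)
        if (training) caches[[paste0(p, "relu")]] <- mask
        bn <- batch_norm(h, layer_bn(model, p), training = training)
        h <- bn$out
        if (training) {
          caches[[paste0(p, "bn")]] <- bn$cache
          model$run[[paste0(p, "mean")]] <- bn$state$run_mean
          model$run[[paste0(p, "var")]] <- bn$state$run_var
        }
      }
      pp <- sprintf("br%d.b%d.", i, j)
      h <- max_pool(h, blk$pool_size, cache = training)
      if (training) caches[[paste0(pp, "pool")]] <- attr(h, "cache")
      attr(h, "cache") <- NULL
    }
    caches[[sprintf("br%d.gapdims", i)]] <- dim(h)
    gaps[[i]] <- global_avg_pool(h)
  }
  feat <- do.call(rbind, gaps)                       # (concat, B)
  z1 <- model$params$fc1.W %*% feat + model$params$fc1.b
  a1 <- relu(z1)
  logits <- model$params$fc2.W %*% a1 + model$params$fc2.b
  if (training) {
    caches$feat <- feat
    caches$z1mask <- z1 > 0
    caches$a1 <- a1
  }
  list(logits = logits, caches = caches, model = model)
}

# Full backward pass; returns gradients named like the parameters.
midcnn_backward <- function(model, caches, dlogits) {
  spec <- model$spec
  g <- list()
  g$fc2.W <- dlogits %*% t(caches$a1)
  g$fc2.b <- rowSums(dlogits)
  da1 <- t(model$params$fc2.W) %*% dlogits
  dz1 <- da1 * caches$z1mask
  g$fc1.W <- dz1 %*% t(caches$feat)
  g$fc1.b <- rowSums(dz1)
  dfeat <- t(model$params$fc1.W) %*% dz1
  offset <- 0L
  for (i in seq_along(spec$branches)) {
    br <- spec$branches[[i]]
    w <- br$gap_width
    dgap <- dfeat[offset + seq_len(w), , drop = FALSE]
    offset <- offset + w
    dh <- global_avg_pool_backward(dgap, caches[[sprintf("br%d.gapdims", i)]])
    for (j in rev(seq_along(br$blocks))) {
      pp <- sprintf("br%d.b%d.", i, j)
      dh <- max_pool_backward(dh, caches[[paste0(pp, "pool")]])
      for (l in 2:1) {
        p <- sprintf("br%d.b%d.c%d.", i, j, l)
        bb <- batch_norm_backward(dh, caches[[paste0(p, "bn")]])
        g[[paste0(p, "gamma")]] <- bb$dgamma
        g[[paste0(p, "beta")]] <- bb$dbeta
        dh <- bb$dx * caches[[paste0(p, "relu")]]
        cb <- conv1d_backward(dh, caches[[paste0(p, "conv")]])
        g[[paste0(p, "W")]] <- cb$dW
        g[[paste0(p, "b")]] <- cb$db
        dh <- cb$dx
      }
    }
  }
  g
}

# Standardize branch inputs with stored per-channel statistics.
apply_norm <- function(xs, norm) {
  if (is.null(norm)) return(xs)
  lapply(seq_along(xs), function(i) {
    x <- xs[[i]]
    for (c_ in seq_len(dim(x)[2])) {
      x[, c_, ] <- (x[, c_, ] - norm[[i]]$mean[c_]) / norm[[i]]$sd[c_]
    }
    x
  })
}

#' Train a multi-input DCNN with Adam and cross-entropy
#'
#' Mini-batch training of a [build_midcnn()] model (or directly from a
#' specification). Inputs are standardized per branch channel with
#' statistics computed on the training set and stored in the model for
#' prediction. Optionally stops early when the training loss has not
#' improved for `patience` epochs.
#'
#' @param x list of input arrays `(L_i, C_i, N)`, one per branch (see
#'   [trial_tensors()]).
#' @param y two-level factor of length N.
#' @param spec a `midcnn_spec` (ignored when `model` is given).
#' @param model optionally an existing `midcnn` to continue training.
#' @param epochs,batch_size,lr training schedule (Adam, default lr 1e-3).
#' @param patience early-stopping patience in epochs (`Inf` = off).
#' @param seed RNG seed for initialization and shuffling.
#' @param verbose print per-epoch progress.
#' @return the fitted `midcnn`: parameters, running batch-norm statistics,
#'   normalization constants, class levels and a `history` data.frame
#'   (epoch, loss, accuracy).
#' @export
fit_midcnn <- function(x, y, spec = NULL, model = NULL, epochs = 30L,
                       batch_size = 32L, lr = 1e-3, patience = Inf,
                       seed = 1L, verbose = FALSE) {
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("binary classification expects 2 classes")
  if (is.null(model)) {
    if (is.null(spec)) stop("either spec or model must be supplied")
    model <- build_midcnn(spec, seed = seed)
  }
  n <- dim(x[[1]])[3]
  stopifnot(length(y) == n)
  model$classes <- levels(y)
  yi <- as.integer(y)
  model$norm <- lapply(x, function(a) {
    list(mean = apply(a, 2, mean),
         sd = pmax(apply(a, 2, stats::sd), 1e-8))
  })
  xs <- apply_norm(x, model$norm)
  opt <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  best <- Inf; wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 500L, ep), sample.int(n))
    ep_loss <- 0; ep_hits <- 0
    for (start in seq(1L, n, by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, n)]
      if (length(bi) < 2L) next    # batch norm needs >= 2
      xb <- lapply(xs, function(a) a[, , bi, drop = FALSE])
      fw <- midcnn_forward(model, xb, training = TRUE)
      model <- fw$model
      sx <- softmax_xent(fw$logits, yi[bi])
      if (!is.finite(sx$loss)) {
        stop(sprintf("non-finite loss at epoch %d (batch starting %d); try a lower learning rate",
                     ep, start))
      }
      grads <- midcnn_backward(model, fw$caches, sx$dlogits)
      upd <- adam_step(model$params, grads, opt, lr = lr)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + sx$loss * length(bi)
      ep_hits <- ep_hits + sum(apply(sx$probs, 2, which.max) == yi[bi])
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                   accuracy = ep_hits / n))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, ep_loss / n,
                      ep_hits / n))
    }
    if (ep_loss / n < best - 1e-5) { best <- ep_loss / n; wait <- 0L }
    else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$history <- hist
  model$fitted <- TRUE
  model
}

#' @export
predict.midcnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- apply_norm(newdata, object$norm)
  logits <- midcnn_forward(object, xs, training = FALSE)$logits
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  p <- sweep(ex, 2, colSums(ex), "/")
  cls <- object$classes
  if (is.null(cls)) cls <- paste0("class", seq_len(nrow(p)))
  rownames(p) <- cls
  if (type == "prob") return(t(p))
  factor(cls[apply(p, 2, which.max)], levels = cls)
}

#' @export
print.midcnn <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("Multi-input DCNN: %d branch(es), concat width %d, fc %d -> %d\n",
              length(sp$branches), sp$concat_width, sp$fc_hidden,
              sp$n_classes))
  cat(sprintf("  parameters: %s; %s\n",
              format(sum(vapply(x$params, length, numeric(1))),
                     big.mark = ","),
              if (x$fitted) sprintf("fitted (%d epochs, final loss %.4f)",
                                    nrow(x$history),
                                    utils::tail(x$history$loss, 1))
              else "untrained"))
  invisible(x)
}

#' @export
summary.midcnn <- function(object, ...) {
  sp <- object$spec
  rows <- do.call(rbind, lapply(seq_along(sp$branches), function(i) {
    br <- sp$branches[[i]]
    sh <- branch_shapes(br)
    do.call(rbind, lapply(seq_along(sh), function(j) {
      data.frame(branch = br$input_name, block = j,
                 filters = sh[[j]]["filters"], out_length = sh[[j]]["length"])
    }))
  }))
  rownames(rows) <- NULL
  res <- list(layers = rows, concat_width = sp$concat_width,
              gap_widths = vapply(sp$branches, `[[`, integer(1), "gap_width"),
              n_params = sum(vapply(object$params, length, numeric(1))),
              history = object$history)
  class(res) <- "summary.midcnn"
  res
}

#' @export
print.summary.midcnn <- function(x, ...) {
  print(x$layers)
  cat("GAP widths:", paste(x$gap_widths, collapse = " + "), "=>",
      x$concat_width, "concatenated features;",
      format(x$n_params, big.mark = ","), "parameters\n")
  invisible(x)
}

#' @export
plot.midcnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  invisible(x)
}

#' Assemble branch input tensors from simulated trials
#'
#' Resamples each trial's channel waveform(s) to the branch input length by
#' linear interpolation (the raw-sample input representation used by the
#' network). For a `"stacked"` branch all three channels are resampled to
#' the branch length and stacked as input channels.
#'
#' @param trials list of `mm_trial` objects.
#' @param spec a `midcnn_spec`.
#' @return list of arrays `(L_i, C_i, N)`, one per branch.
#' @export
trial_tensors <- function(trials, spec) {
  lapply(spec$branches, function(br) {
    chans <- if (br$input_name == "stacked") c("ecg", "eda", "rsp")
             else br$input_name
    out <- array(0, c(br$input_length, length(chans), length(trials)))
    for (t_ in seq_along(trials)) {
      for (c_ in seq_along(chans)) {
        out[, c_, t_] <- resample_linear(trials[[t_]][[chans[c_]]]$waveform,
                                         br$input_length)
      }
    }
    out
  })
}

#' Evaluate a DCNN scheme under the balanced-subset protocol
#'
#' Mirrors [run_ml()] for the deep models: per balanced subset, stratified
#' cross-validation with an 80/20 train/test division (`n_folds = 1` uses a
#' single stratified 80/20 split), training a fresh network on each
#' training split and scoring the held-out part.
#'
#' @param x list of branch input tensors (see [trial_tensors()]).
#' @param labels two-level factor.
#' @param spec a `midcnn_spec`.
#' @param n_subsets balanced subsets (default 5).
#' @param n_folds folds per subset; 1 = single 80/20 split.
#' @param epochs,batch_size,lr,patience passed to [fit_midcnn()].
#' @param seed RNG seed.
#' @return object of class `dcnn_eval` (same fields as `ml_eval`).
#' @export
run_dcnn <- function(x, labels, spec, n_subsets = 5L, n_folds = 1L,
                     epochs = 20L, batch_size = 32L, lr = 1e-3,
                     patience = Inf, seed = 1L) {
  labels <- as.factor(labels)
  subsets <- make_balanced_subsets(labels, n_subsets,
                                   seed = derive_seed(seed, 11L))
  kf <- max(1L, as.integer(n_folds))
  eff_folds <- if (kf == 1L) 5L else kf   # 80/20 geometry for single split
  subset_acc <- numeric(n_subsets)
  subset_f1 <- numeric(n_subsets)
  fold_acc <- matrix(NA_real_, n_subsets, kf)
  fold_f1 <- matrix(NA_real_, n_subsets, kf)
  conf <- matrix(0L, 2, 2, dimnames = list(actual = levels(labels),
                                           predicted = levels(labels)))
  for (si in seq_len(n_subsets)) {
    idx <- subsets[[si]]$indices
    y <- labels[idx]
    folds <- with_seed(derive_seed(seed, 20L, si), {
      f <- integer(length(y))
      for (cl in levels(y)) {
        ii <- which(y == cl)
        f[ii] <- sample(rep_len(seq_len(eff_folds), length(ii)))
      }
      f
    })
    for (fi in seq_len(kf)) {
      te <- folds == fi
      xtr <- lapply(x, function(a) a[, , idx[!te], drop = FALSE])
      xte <- lapply(x, function(a) a[, , idx[te], drop = FALSE])
      fit <- fit_midcnn(xtr, y[!te], spec = spec, epochs = epochs,
                        batch_size = batch_size, lr = lr,
                        patience = patience,
                        seed = derive_seed(seed, 40L, si, fi))
      pred <- predict(fit, xte)
      m <- eval_metrics(y[te], pred)
      fold_acc[si, fi] <- m$accuracy
      fold_f1[si, fi] <- m$macro_f1
      conf <- conf + m$confusion
    }
    subset_acc[si] <- mean(fold_acc[si, ], na.rm = TRUE)
    subset_f1[si] <- mean(fold_f1[si, ], na.rm = TRUE)
  }
  structure(list(
    classifier = "dcnn",
    modality = paste(vapply(spec$branches, `[[`, character(1), "input_name"),
                     collapse = "+"),
    accuracy_mean = mean(subset_acc), accuracy_sd = stats::sd(subset_acc),
    f1_mean = mean(subset_f1), f1_sd = stats::sd(subset_f1),
    subset_accuracy = subset_acc, subset_f1 = subset_f1,
    fold_accuracy = fold_acc, fold_f1 = fold_f1,
    confusion = conf, seed = seed
  ), class = c("dcnn_eval", "ml_eval"))
}
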