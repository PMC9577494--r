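test_that("conv1d matches hand cases and the identity kernel", {
  out <- conv1d_forward(array(c(1, 2, 3, 4), c(4, 1, 1)),
                        array(c(1, 1, 1), c(3, 1, 1)), 0, 1)
  expect_equal(as.vector(out), c(3, 6, 9, 7))
  x <- array(rnorm(20), c(20, 1, 1))
  ident <- array(c(0, 1, 0), c(3, 1, 1))
  expect_equal(as.vector(conv1d_forward(x, ident, 0, 1)), as.vector(x))
  expect_error(conv1d_forward(array(0, c(8, 2, 1)),
                              array(0, c(3, 1, 4))), "channel mismatch")
})

test_that("relu clips negatives and is idempotent", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_equal(relu(c(-3, -1)), c(0, 0))
  x <- rnorm(100)
  expect_equal(relu(relu(x)), relu(x))
})

test_that("batch normalization enforces the zero-mean unit-variance contract", {
  set.seed(2)
  x <- matrix(rnorm(10 * 64, 5, 3), 10, 64)   # (features, batch)
  st <- emofuse:::bn_state(10)
  out <- batch_norm(x, st, training = TRUE)$out
  expect_lt(max(abs(rowMeans(out))), 1e-5)
  expect_lt(max(abs(apply(out, 1, function(r) mean(r^2) - mean(r)^2) - 1)),
            1e-4)
  # learned affine map
  st2 <- emofuse:::bn_state(10)
  st2$gamma <- rep(2, 10); st2$beta <- rep(3, 10)
  out2 <- batch_norm(x, st2, training = TRUE)$out
  expect_equal(rowMeans(out2), rep(3, 10), tolerance = 1e-6)
  expect_equal(apply(out2, 1, sd), rep(2, 10), tolerance = 0.05)
  # constant feature collapses to beta (0), guarded by epsilon
  xc <- rbind(rep(4, 64), rnorm(64))
  outc <- batch_norm(xc, emofuse:::bn_state(2), training = TRUE)$out
  expect_equal(outc[1, ], rep(0, 64))
  expect_error(batch_norm(matrix(1, 3, 1), emofuse:::bn_state(3),
                          training = TRUE), ">= 2")
})

test_that("max pooling and GAP follow their definitions", {
  expect_equal(as.vector(max_pool(c(1, 3, 2, 5), 2)), c(3, 5))
  expect_equal(as.vector(max_pool(rep(7, 10), 2)), rep(7, 5))
  x <- array(rnorm(16 * 3 * 2), c(16, 3, 2))
  expect_equal(dim(max_pool(x, 2)), c(8, 3, 2))
  ones <- array(1, c(5, 128, 1))
  expect_equal(as.vector(global_avg_pool(ones)), rep(1, 128))
  expect_equal(global_avg_pool(x), naive_gap(x))
})

test_that("random small tensors match the brute-force layer oracles", {
  set.seed(31)
  for (i in 1:20) {
    L <- sample(4:16, 1); C <- sample(1:3, 1); B <- sample(1:3, 1)
    K <- sample(1:5, 1); F_ <- sample(1:4, 1); s <- sample(1:3, 1)
    x <- array(rnorm(L * C * B), c(L, C, B))
    W <- array(rnorm(K * C * F_), c(K, C, F_)); b <- rnorm(F_)
    expect_equal(conv1d_forward(x, W, b, s), naive_conv1d(x, W, b, s),
                 tolerance = 1e-12)
    p <- sample(1:min(3, L), 1)
    expect_equal(max_pool(x, p), naive_max_pool(x, p), tolerance = 1e-12)
    expect_equal(global_avg_pool(x), naive_gap(x), tolerance = 1e-12)
  }
})

test_that("the default architecture audits to GAP widths 128/32/64 and concat 224", {
  sp <- midcnn_spec()
  gw <- vapply(sp$branches, `[[`, integer(1), "gap_width")
  expect_equal(gw, c(128L, 32L, 64L))
  expect_equal(sp$concat_width, 224L)
  single <- single_dcnn_spec("ecg")
  expect_equal(single$concat_width, single$branches[[1]]$gap_width)
  # input below the stride/pool minimum is rejected with the minimum named
  expect_error(branch_config("ecg", 8, midcnn_spec()$branches[[1]]$blocks),
               "minimum")
})

test_that("model building is deterministic and the stacked trunk shares filters over channels", {
  sp <- midcnn_spec_desk()
  m1 <- build_midcnn(sp, seed = 4)
  m2 <- build_midcnn(sp, seed = 4)
  expect_identical(m1$params, m2$params)
  st <- single_dcnn_spec("stacked", 128, filters = c(8, 8, 8),
                         kernels = c(8, 8, 4))
  ms <- build_midcnn(st, seed = 1)
  expect_equal(dim(ms$params[["br1.b1.c1.W"]])[2], 3L)   # kernels span 3 channels
  mi <- build_midcnn(sp, seed = 1)
  expect_equal(dim(mi$params[["br1.b1.c1.W"]])[2], 1L)   # per-modality filters
})

test_that("analytic gradients agree with numerical differentiation", {
  sp <- midcnn_spec(list(
    branch_config("ecg", 16, list(conv_block_spec(2, 3, c(1, 1)),
                                  conv_block_spec(2, 3, c(1, 1)),
                                  conv_block_spec(3, 2, c(1, 1)))),
    branch_config("eda", 12, list(conv_block_spec(2, 3, c(1, 1)),
                                  conv_block_spec(2, 2, c(1, 1)),
                                  conv_block_spec(2, 2, c(1, 1))))),
    fc_hidden = 4)
  m <- build_midcnn(sp, seed = 3)
  set.seed(5)
  xs <- list(array(rnorm(16 * 6), c(16, 1, 6)),
             array(rnorm(12 * 6), c(12, 1, 6)))
  y <- c(1L, 2L, 1L, 2L, 1L, 2L)
  lossfun <- function(mm) {
    fw <- emofuse:::midcnn_forward(mm, xs, training = TRUE)
    emofuse:::softmax_xent(fw$logits, y)$loss
  }
  fw <- emofuse:::midcnn_forward(m, xs, training = TRUE)
  g <- emofuse:::midcnn_backward(m, fw$caches,
                                 emofuse:::softmax_xent(fw$logits, y)$dlogits)
  for (nm in c("br1.b1.c1.W", "br2.b2.c1.b", "br1.b3.c2.gamma", "fc1.W",
               "fc2.b")) {
    p <- m$params[[nm]]
    for (ii in seq_len(min(3, length(p)))) {
      eps <- 1e-5
      mp <- m; mp$params[[nm]][ii] <- p[ii] + eps
      mm_ <- m; mm_$params[[nm]][ii] <- p[ii] - eps
      num <- (lossfun(mp) - lossfun(mm_)) / (2 * eps)
      expect_equal(g[[nm]][ii], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and separates an easy two-class problem", {
  set.seed(8)
  n <- 80
  y <- factor(rep(c("low", "high"), n / 2), levels = c("low", "high"))
  freq <- ifelse(y == "high", 6, 2)
  x1 <- sapply(seq_len(n), function(i) sin(2 * pi * freq[i] * seq(0, 1, length.out = 64)) +
                 rnorm(64, 0, 0.2))
  xs <- list(array(x1, c(64, 1, n)))
  sp <- midcnn_spec(list(branch_config("ecg", 64,
                                       list(conv_block_spec(8, 8, c(1, 1)),
                                            conv_block_spec(8, 8, c(1, 1)),
                                            conv_block_spec(8, 4, c(1, 1))))),
                    fc_hidden = 16)
  fit <- fit_midcnn(xs, y, spec = sp, epochs = 15, batch_size = 16, seed = 2)
  h <- fit$history
  expect_lt(mean(tail(h$loss, 3)), mean(head(h$loss, 3)))
  expect_gt(tail(h$accuracy, 1), 0.9)
  pred <- predict(fit, xs)
  expect_gt(mean(pred == y), 0.9)
  pr <- predict(fit, xs, type = "prob")
  expect_equal(rowSums(pr), rep(1, n), tolerance = 1e-9)
  # non-finite loss aborts with diagnostics
  xs_bad <- xs
  xs_bad[[1]][1, 1, 1] <- NaN
  expect_error(fit_midcnn(xs_bad, y, spec = sp, epochs = 2, seed = 2),
               "non-finite")
})
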