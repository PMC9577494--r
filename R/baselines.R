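#' Binarize 1-9 self-report scores at a mid-scale threshold
#'
#' @param scores integer scores in 1-9.
#' @param threshold mid-scale cut; scores `<= threshold` map to `"low"`,
#'   the rest to `"high"` (the `<=` convention is a documented choice).
#' @return factor with levels `c("low", "high")`.
#' @export
binarize_scores <- function(scores, threshold = 5) {
  if (any(scores < 1 | scores > 9)) stop("scores must lie in 1-9")
  factor(ifelse(scores <= threshold, "low", "high"),
         levels = c("low", "high"))
}

#' Construct fully balanced subsets by majority undersampling
#'
#' Each subset keeps every minority-class row and an independent random
#' equal-size sample (without replacement) of majority rows, so all subsets
#' have an exact 1:1 class ratio and differ only in the majority sample.
#'
#' @param labels two-level factor.
#' @param n_subsets number of balanced subsets (default 5).
#' @param seed RNG seed.
#' @return list of length `n_subsets`; each element has `indices` (row
#'   indices into `labels`) and `class_counts`.
#' @export
make_balanced_subsets <- function(labels, n_subsets = 5L, seed = 1L) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) != 2L || any(tab == 0)) {
    stop("balanced subsets need both classes present")
  }
  if (min(tab) < 2L) stop("minority class has fewer than 2 rows")
  if (min(tab) < 10L) warning("minority class has fewer than 10 rows")
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  min_idx <- which(labels == minority)
  maj_idx <- which(labels == majority)
  with_seed(seed, {
    lapply(seq_len(n_subsets), function(k) {
      samp <- sample(maj_idx, length(min_idx), replace = FALSE)
      idx <- sort(c(min_idx, samp))
      list(subset_id = k, indices = idx,
           class_counts = table(labels[idx]))
    })
  })
}

# Fixed hyperparameter grids (documented defaults; the method itself gives
# none).
ml_grids <- list(
  svm = expand.grid(cost = c(0.1, 1, 10), gamma_scale = c(0.25, 1, 4)),
  rfc = expand.grid(ntree = 200, mtry_frac = c(0.25, 0.5, 1)),
  knn = expand.grid(k = c(3, 5, 7, 11))
)

# Train on standardized features and predict the test split for one
# hyperparameter setting.
fit_predict <- function(classifier, tr_x, tr_y, te_x, par) {
  switch(classifier,
    svm = {
      g <- par$gamma_scale / ncol(tr_x)
      fit <- e1071::svm(tr_x, tr_y, kernel = "radial", cost = par$cost,
                        gamma = g, scale = FALSE)
      stats::predict(fit, te_x)
    },
    rfc = {
      mtry <- max(1L, round(par$mtry_frac * sqrt(ncol(tr_x))))
      fit <- randomForest::randomForest(tr_x, tr_y, ntree = par$ntree,
                                        mtry = mtry)
      stats::predict(fit, te_x)
    },
    knn = class::knn(tr_x, te_x, tr_y, k = par$k)
  )
}

# Leakage-free grid search: inner 3-fold CV on the training split only.
select_hyperpars <- function(classifier, x, y, seed) {
  grid <- ml_grids[[classifier]]
  if (nrow(grid) == 1L) return(grid[1L, , drop = FALSE])
  folds <- with_seed(seed, sample(rep_len(1:3, length(y))))
  acc <- vapply(seq_len(nrow(grid)), function(gi) {
    mean(vapply(1:3, function(f) {
      tr <- folds != f
      p <- with_seed(derive_seed(seed, gi, f),
                     fit_predict(classifier, x[tr, , drop = FALSE], y[tr],
                                 x[!tr, , drop = FALSE],
                                 grid[gi, , drop = FALSE]))
      mean(p == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(acc), , drop = FALSE]
}

#' Evaluate a classical classifier under the balanced-subset protocol
#'
#' For each of `n_subsets` fully balanced subsets: stratified 5-fold
#' cross-validation with an 80/20 train/test division per fold; feature
#' standardization and hyperparameter grid search (inner 3-fold CV) are fit
#' on the 80% training split only; the held-out 20% gives the fold result.
#' A subset's result is its fold mean, and the reported value is the mean
#' and SD over the subsets.
#'
#' @param features data.frame containing the registry feature columns
#'   (e.g. from [extract_features_dataset()]).
#' @param labels two-level factor aligned with `features` rows.
#' @param classifier `"svm"`, `"rfc"` or `"knn"`.
#' @param modality `"ecg"` (47 features), `"eda"` (4), `"rsp"` (7) or
#'   `"fusion"` (58).
#' @param n_subsets,n_folds protocol sizes.
#' @param seed RNG seed; the full pipeline is reproducible given it.
#' @return object of class `ml_eval`: accuracy/F1 mean and sd over subsets,
#'   per-subset values, fold-level values, the confusion matrix summed over
#'   folds, and metadata.
#' @export
run_ml <- function(features, labels, classifier = c("svm", "rfc", "knn"),
                   modality = c("fusion", "ecg", "eda", "rsp"),
                   n_subsets = 5L, n_folds = 5L, seed = 1L) {
  classifier <- match.arg(classifier)
  modality <- match.arg(modality)
  cols <- feature_names_for(modality)
  x_all <- as.matrix(features[, cols, drop = FALSE])
  labels <- as.factor(labels)
  ok <- stats::complete.cases(x_all) & apply(is.finite(x_all), 1, all)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " rows with non-finite features dropped")
  }
  x_all <- x_all[ok, , drop = FALSE]
  labels <- droplevels(labels[ok])
  subsets <- make_balanced_subsets(labels, n_subsets, seed = derive_seed(seed, 11L))
  subset_acc <- numeric(n_subsets)
  subset_f1 <- numeric(n_subsets)
  fold_acc <- matrix(NA_real_, n_subsets, n_folds)
  fold_f1 <- matrix(NA_real_, n_subsets, n_folds)
  conf <- matrix(0L, 2, 2, dimnames = list(actual = levels(labels),
                                           predicted = levels(labels)))
  for (si in seq_len(n_subsets)) {
    idx <- subsets[[si]]$indices
    x <- x_all[idx, , drop = FALSE]
    y <- labels[idx]
    folds <- with_seed(derive_seed(seed, 20L, si), {
      f <- integer(length(y))
      for (cl in levels(y)) {
        ii <- which(y == cl)
        f[ii] <- sample(rep_len(seq_len(n_folds), length(ii)))
      }
      f
    })
    for (fi in seq_len(n_folds)) {
      tr <- folds != fi
      mu <- colMeans(x[tr, , drop = FALSE])
      sd_ <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ < 1e-12] <- 1
      xs <- sweep(sweep(x, 2, mu), 2, sd_, "/")
      par <- select_hyperpars(classifier, xs[tr, , drop = FALSE], y[tr],
                              derive_seed(seed, 30L, si, fi))
      pred <- with_seed(derive_seed(seed, 40L, si, fi),
                        fit_predict(classifier, xs[tr, , drop = FALSE], y[tr],
                                    xs[!tr, , drop = FALSE], par))
      m <- eval_metrics(y[!tr], pred)
      fold_acc[si, fi] <- m$accuracy
      fold_f1[si, fi] <- m$macro_f1
      conf <- conf + m$confusion
    }
    subset_acc[si] <- mean(fold_acc[si, ])
    subset_f1[si] <- mean(fold_f1[si, ])
  }
  structure(list(
    classifier = classifier, modality = modality,
    accuracy_mean = mean(subset_acc), accuracy_sd = stats::sd(subset_acc),
    f1_mean = mean(subset_f1), f1_sd = stats::sd(subset_f1),
    subset_accuracy = subset_acc, subset_f1 = subset_f1,
    fold_accuracy = fold_acc, fold_f1 = fold_f1,
    confusion = conf, n_dropped = n_dropped, seed = seed
  ), class = "ml_eval")
}

#' @export
print.ml_eval <- function(x, ...) {
  cat(sprintf("%s (%s): accuracy %.1f +/- %.1f%%, macro F1 %.3f +/- %.3f\n",
              toupper(x$classifier), x$modality,
              100 * x$accuracy_mean, 100 * x$accuracy_sd,
              x$f1_mean, x$f1_sd))
  invisible(x)
}

#' Random and majority reference classifiers
#'
#' The random classifier predicts uniformly at random; the majority
#' classifier constantly predicts the most frequent training class. On any
#' balanced binary test set the majority classifier scores exactly 50%
#' accuracy and macro F1 1/3.
#'
#' @param labels_train,labels_test two-level factors.
#' @param seed RNG seed for the random classifier.
#' @return list with `random` and `majority`, each holding `accuracy`,
#'   `macro_f1` and the confusion matrix.
#' @export
dummy_classifiers <- function(labels_train, labels_test, seed = 1L) {
  labels_train <- as.factor(labels_train)
  labels_test <- factor(labels_test, levels = levels(labels_train))
  rnd <- with_seed(seed, factor(sample(levels(labels_train),
                                       length(labels_test), replace = TRUE),
                                levels = levels(labels_train)))
  maj_class <- names(which.max(table(labels_train)))
  maj <- factor(rep(maj_class, length(labels_test)),
                levels = levels(labels_train))
  mr <- eval_metrics(labels_test, rnd)
  mm <- eval_metrics(labels_test, maj)
  list(random = list(accuracy = mr$accuracy, macro_f1 = mr$macro_f1,
                     confusion = mr$confusion),
       majority = list(accuracy = mm$accuracy, macro_f1 = mm$macro_f1,
                       confusion = mm$confusion))
}

#' Two-sided paired t-test on fold- or subset-level results
#'
#' Thin wrapper around [stats::t.test()] with degenerate-input guards: all
#' differences exactly zero gives `p = 1`; a non-zero constant difference
#' (zero variance) gives `p = 0` with `t = Inf` of the matching sign.
#'
#' @param a,b equal-length numeric vectors of paired results.
#' @return list with `t` and `p`.
#' @export
paired_fold_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  if (all(d == 0)) return(list(t = 0, p = 1))
  if (length(d) < 2L) return(list(t = NA_real_, p = NA_real_))
  if (stats::sd(d) < 1e-12) {
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}
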