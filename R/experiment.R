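#' Binary classification metrics
#'
#' Accuracy, macro F1 (unweighted mean of per-class F1), per-class
#' precision/recall, and the confusion matrix (rows = actual, columns =
#' predicted). Zero-division cases (a class never predicted or absent)
#' contribute 0 to the affected precision/recall/F1 and are flagged.
#'
#' @param y_true,y_pred equal-length factors (or vectors coercible to a
#'   common factor).
#' @return list: `accuracy`, `macro_f1`, `precision`, `recall`, `f1` (named
#'   per class), `confusion`, `zero_division` flag.
#' @export
eval_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  lev <- levels(as.factor(y_true))
  if (is.factor(y_pred)) lev <- union(lev, levels(y_pred))
  y_true <- factor(y_true, levels = lev)
  y_pred <- factor(y_pred, levels = lev)
  cm <- table(actual = y_true, predicted = y_pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / sum(cm),
       macro_f1 = mean(f1),
       precision = prec, recall = rec, f1 = f1,
       confusion = unclass(cm),
       zero_division = any(colSums(cm) == 0 | rowSums(cm) == 0))
}

#' Run the full simulation study at desk scale
#'
#' Orchestrates the complete pipeline from one dataset seed: simulate the
#' dataset, extract features, evaluate the classical classifiers
#' (SVM/RFC/KNN x modality) plus the random/majority references, train the
#' five deep schemes (three single-modality DCNNs, the stacked single-input
#' DCNN, and the multi-input DCNN), and run paired comparisons of the
#' multi-input model against the best classical baseline and the stacked
#' model.
#'
#' @param config a [sim_config()].
#' @param task `"arousal"` or `"valence"`.
#' @param out_dir optional directory for the report CSV/JSON files.
#' @param spec `midcnn_spec` for the multi-input model (desk preset by
#'   default); single-input schemes reuse its first-branch shape.
#' @param classifiers,modalities classical grid to evaluate.
#' @param schemes deep schemes to run, a subset of
#'   `c("single-ecg", "single-eda", "single-rsp", "single-stacked", "mi")`.
#' @param n_subsets,n_folds,epochs,batch_size,lr protocol sizes.
#' @param seed master seed stamped on every artifact.
#' @return list of class `emostudy`: `ml_table`, `dcnn_table`,
#'   `dummy`, `tests`, `confusions`, plus the config/seed stamp.
#' @export
run_study <- function(config, task = c("arousal", "valence"),
                      out_dir = NULL, spec = midcnn_spec_desk(),
                      classifiers = c("svm", "rfc", "knn"),
                      modalities = c("ecg", "eda", "rsp", "fusion"),
                      schemes = c("single-ecg", "single-eda", "single-rsp",
                                  "single-stacked", "mi"),
                      n_subsets = 2L, n_folds = 5L, epochs = 10L,
                      batch_size = 32L, lr = 1e-3, seed = 1L) {
  task <- match.arg(task)
  dataset <- simulate_dataset(config)
  feats <- extract_features_dataset(dataset)
  labels <- binarize_scores(feats[[task]])

  ml <- list()
  for (cl in classifiers) {
    for (mo in modalities) {
      ml[[paste(cl, mo, sep = ".")]] <-
        run_ml(feats, labels, cl, mo, n_subsets = n_subsets,
               n_folds = n_folds, seed = derive_seed(seed, 1L))
    }
  }
  ml_table <- do.call(rbind, lapply(ml, function(r) {
    data.frame(classifier = r$classifier, modality = r$modality,
               accuracy = r$accuracy_mean, accuracy_sd = r$accuracy_sd,
               f1 = r$f1_mean, f1_sd = r$f1_sd)
  }))
  rownames(ml_table) <- NULL

  # analytic references on a balanced split of the data
  bal <- make_balanced_subsets(labels, 1L, seed = derive_seed(seed, 2L))[[1]]
  yb <- labels[bal$indices]
  # stratified 80/20 so the reference test set is exactly balanced
  te <- unlist(lapply(levels(yb), function(cl) {
    ii <- which(yb == cl)
    utils::tail(ii, floor(0.2 * length(ii)))
  }))
  dum <- dummy_classifiers(yb[-te], yb[te], seed = derive_seed(seed, 3L))

  sb <- spec$branches
  spec_for <- function(sch) {
    switch(sch,
      "single-ecg" = midcnn_spec(sb[1], fc_hidden = spec$fc_hidden),
      "single-eda" = midcnn_spec(sb[2], fc_hidden = spec$fc_hidden),
      "single-rsp" = midcnn_spec(sb[3], fc_hidden = spec$fc_hidden),
      "single-stacked" = {
        br1 <- sb[[1]]
        midcnn_spec(list(branch_config("stacked", br1$input_length,
                                       br1$blocks, in_channels = 3L)),
                    fc_hidden = spec$fc_hidden)
      },
      "mi" = spec)
  }
  dl <- list()
  confusions <- list()
  for (sch in schemes) {
    sp <- spec_for(sch)
    xt <- trial_tensors(dataset$trials, sp)
    dl[[sch]] <- run_dcnn(xt, labels, sp, n_subsets = n_subsets,
                          n_folds = 1L, epochs = epochs,
                          batch_size = batch_size, lr = lr,
                          seed = derive_seed(seed, 4L))
    confusions[[sch]] <- dl[[sch]]$confusion
  }
  dcnn_table <- do.call(rbind, lapply(names(dl), function(nm) {
    r <- dl[[nm]]
    data.frame(scheme = nm, accuracy = r$accuracy_mean,
               accuracy_sd = r$accuracy_sd, f1 = r$f1_mean, f1_sd = r$f1_sd)
  }))

  tests <- list()
  if ("mi" %in% schemes) {
    best_ml <- ml[[which.max(vapply(ml, `[[`, numeric(1), "accuracy_mean"))]]
    k <- min(length(dl$mi$subset_accuracy), length(best_ml$subset_accuracy))
    tests$mi_vs_best_ml <- c(
      list(comparator = paste(best_ml$classifier, best_ml$modality)),
      paired_fold_test(dl$mi$subset_accuracy[seq_len(k)],
                       best_ml$subset_accuracy[seq_len(k)]))
    if ("single-stacked" %in% schemes) {
      tests$mi_vs_stacked <- paired_fold_test(dl$mi$subset_accuracy,
                                              dl$`single-stacked`$subset_accuracy)
    }
  }

  out <- structure(list(task = task, ml_table = ml_table,
                        dcnn_table = dcnn_table,
                        dummy = dum, tests = tests, confusions = confusions,
                        ml = ml, dcnn = dl,
                        config = config, seed = seed),
                   class = "emostudy")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ml_table, file.path(out_dir, "ml_baselines.csv"),
                     row.names = FALSE)
    utils::write.csv(dcnn_table, file.path(out_dir, "dcnn_schemes.csv"),
                     row.names = FALSE)
    for (nm in names(confusions)) {
      utils::write.csv(confusions[[nm]],
                       file.path(out_dir, paste0("confusion_", nm, ".csv")))
    }
    jsonlite::write_json(
      list(task = task, seed = seed,
           dummy = lapply(dum, function(d) d[c("accuracy", "macro_f1")]),
           tests = tests),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.emostudy <- function(x, ...) {
  cat("Simulation study (", x$task, "), seed ", x$seed, "\n\n", sep = "")
  cat("Classical baselines (balanced subsets):\n")
  print(x$ml_table, digits = 3)
  cat("\nDeep schemes:\n")
  print(x$dcnn_table, digits = 3)
  cat(sprintf("\nMajority reference: accuracy %.3f, macro F1 %.3f\n",
              x$dummy$majority$accuracy, x$dummy$majority$macro_f1))
  invisible(x)
}
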