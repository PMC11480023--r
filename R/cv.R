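#' Patient-grouped k-fold splits
#'
#' Assigns whole patients to folds so no patient ever appears on both
#' sides of a split: patients are taken in order of decreasing row count
#' (ties by first appearance) and each goes to the currently smallest test
#' fold — the same greedy balancing GroupKFold uses. Deterministic given
#' the input order.
#'
#' @param patient_ids per-row patient identifiers
#' @param k number of folds (default 10); requires at least `k` distinct
#'   patients
#' @return list of `k` fold objects, each with `fold`, `train_patients`,
#'   `test_patients`, `train_idx`, `test_idx`
#' @export
group_kfold_splits <- function(patient_ids, k = 10) {
  patient_ids <- as.character(patient_ids)
  patients <- unique(patient_ids)
  if (length(patients) < k) {
    stop(sprintf("need at least %d distinct patients for %d folds (have %d)",
                 k, k, length(patients)), call. = FALSE)
  }
  counts <- table(factor(patient_ids, levels = patients))
  ord <- order(-as.integer(counts), seq_along(patients))
  fold_of <- integer(length(patients))
  fold_sizes <- numeric(k)
  for (p in ord) {
    f <- which.min(fold_sizes)
    fold_of[p] <- f
    fold_sizes[f] <- fold_sizes[f] + counts[p]
  }
  lapply(seq_len(k), function(f) {
    test_p <- patients[fold_of == f]
    test_idx <- which(patient_ids %in% test_p)
    list(fold = f, train_patients = setdiff(patients, test_p),
         test_patients = test_p,
         train_idx = setdiff(seq_along(patient_ids), test_idx),
         test_idx = test_idx)
  })
}

#' Run a full augmentation-and-classification experiment
#'
#' Patient-grouped k-fold cross-validation of one augmentation plan and
#' one classifier. Inside every fold the plan is fitted on the training
#' split only — the GAN sees only training-fold rows, SMOTE/ADASYN only
#' interpolate training rows, and no synthetic row can reach a test fold.
#' Metrics are computed per fold and averaged.
#'
#' @param table feature table data.frame (real rows only)
#' @param plan an [augmentation_plan()]
#' @param config a [classifier_config()]
#' @param k number of folds (default 10)
#' @param fidelity if TRUE and the plan is generative, record the energy
#'   distance between the fold's synthetic rows and its real minority rows
#'   (on standardized features)
#' @return an `experiment_report`: `per_fold` data.frame, `average` row,
#'   `folds` (patient composition for leakage audits), `fidelity`,
#'   configuration provenance and seeds
#' @export
run_experiment <- function(table, plan, config, k = 10, fidelity = TRUE) {
  assert_feature_table(table)
  if (any(table$is_synthetic %||% FALSE)) {
    stop("`table` must contain only real rows", call. = FALSE)
  }
  splits <- group_kfold_splits(table$patient_id, k)
  per_fold <- NULL
  fid <- NULL
  fold_log <- lapply(splits, function(s)
    list(fold = s$fold, test_patients = s$test_patients))
  for (s in splits) {
    train <- table[s$train_idx, , drop = FALSE]
    test <- table[s$test_idx, , drop = FALSE]
    fold_plan <- plan
    fold_plan$seed <- derive_seed(plan$seed, s$fold)
    if (plan$method == "gan") fold_plan$gan$seed <- derive_seed(plan$gan$seed, s$fold)
    bal <- balance_dataset(train, fold_plan)
    fold_config <- config
    fold_config$seed <- derive_seed(config$seed, s$fold)
    model <- train_classifier(bal$table, fold_config, weights = bal$weights)
    prob <- predict_classifier(model, test)
    m <- compute_metrics(test$label, prob)
    m$fold <- s$fold
    per_fold <- rbind(per_fold, m)
    if (fidelity && plan$method %in% c("gan", "smote", "adasyn")) {
      synth <- bal$table[bal$table$is_synthetic, , drop = FALSE]
      realm <- train[train$label == 1, , drop = FALSE]
      if (nrow(synth) > 1 && nrow(realm) > 1) {
        sc <- fit_scaler(feature_matrix(realm))
        fid <- rbind(fid, data.frame(
          fold = s$fold,
          energy_distance = energy_distance_mat(
            apply_scaler(feature_matrix(realm), sc),
            apply_scaler(feature_matrix(synth), sc))))
      }
    }
  }
  metric_cols <- c("loss", "accuracy", "recall", "specificity", "precision", "f1")
  avg <- as.data.frame(t(colMeans(per_fold[, metric_cols])))
  structure(list(per_fold = per_fold[, c("fold", metric_cols,
                                         "tp", "fp", "tn", "fn")],
                 average = avg, folds = fold_log, fidelity = fid,
                 plan = plan, classifier = config, k = k),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> plan=%s, classifier=%s, %d folds\n",
              x$plan$method, x$classifier$kind, x$k))
  print(round(x$average, 4))
  invisible(x)
}

#' Write an experiment report to JSON and per-fold CSV
#'
#' @param report an `experiment_report`
#' @param path JSON output path; a sibling `<path>_folds.csv` is written too
#' @param seed the experiment's global seed, recorded for provenance
#' @return `path`, invisibly
#' @export
write_experiment_report <- function(report, path, seed = NULL) {
  payload <- list(
    plan = report$plan[setdiff(names(report$plan), "gan")],
    gan = if (report$plan$method == "gan")
      unclass(report$plan$gan) else NULL,
    classifier = unclass(report$classifier),
    k = report$k, seed = seed,
    config_hash = config_hash(jsonlite::toJSON(
      list(unclass(report$plan["method"]), unclass(report$classifier)),
      auto_unbox = TRUE)),
    average = report$average, per_fold = report$per_fold,
    fidelity = report$fidelity,
    folds = report$folds,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  utils::write.csv(report$per_fold,
                   sub("\\.json$", "_folds.csv", path), row.names = FALSE)
  invisible(path)
}
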