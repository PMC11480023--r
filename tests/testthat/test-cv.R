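test_that("grouped folds partition patients and rows", {
  pids <- rep(sprintf("P%02d", 1:20), each = 5)
  sp <- group_kfold_splits(pids, 10)
  expect_length(sp, 10)
  for (s in sp) {
    expect_length(s$test_patients, 2)
    expect_length(intersect(s$train_patients, s$test_patients), 0)
  }
  all_test <- sort(unlist(lapply(sp, `[[`, "test_idx")))
  expect_identical(all_test, seq_along(pids))
  expect_error(group_kfold_splits(rep(c("a", "b", "c", "d", "e"), 4), 10),
               "at least 10")
})

test_that("unbalanced patient sizes still give disjoint, exhaustive folds", {
  set.seed(95)
  pids <- rep(sprintf("P%02d", 1:13), times = sample(1:20, 13, replace = TRUE))
  sp <- group_kfold_splits(pids, 10)
  test_sets <- lapply(sp, `[[`, "test_idx")
  expect_identical(sort(unlist(test_sets)), seq_along(pids))
  expect_equal(sum(lengths(test_sets)), length(pids))  # pairwise disjoint
  for (s in sp) {
    expect_length(intersect(pids[s$train_idx], pids[s$test_idx]), 0)
  }
})

test_that("run_experiment reports per-fold rows, averages and clean folds", {
  tab <- simulate_feature_dataset(feature_sim_config(
    n_majority = 150, n_minority = 15, n_features = 3,
    minority_mean = rep(2, 3), n_patients = 12, seed = 97))
  rep_ <- suppressWarnings(run_experiment(
    tab, augmentation_plan("smote", seed = 1),
    classifier_config("rf", n_trees = 100, seed = 1), k = 10))
  expect_equal(nrow(rep_$per_fold), 10)
  expect_equal(rep_$average$accuracy, mean(rep_$per_fold$accuracy))
  expect_length(rep_$folds, 10)
  # every patient appears in exactly one test fold
  tp <- unlist(lapply(rep_$folds, `[[`, "test_patients"))
  expect_identical(sort(tp), sort(unique(tab$patient_id)))
  # fidelity summary present for a sampling plan
  expect_true(!is.null(rep_$fidelity))
})

test_that("experiments refuse synthetic input rows and class_weight passes weights", {
  tab <- simulate_feature_dataset(feature_sim_config(
    n_majority = 60, n_minority = 12, n_features = 2, n_patients = 10,
    seed = 99))
  aug <- smote_oversample(tab, k = 3, n_target = 5, seed = 1)
  expect_error(suppressWarnings(run_experiment(
    aug, augmentation_plan("none"), classifier_config("rf", seed = 1))),
    "real rows")
  rep_ <- suppressWarnings(run_experiment(
    tab, augmentation_plan("class_weight"),
    classifier_config("rf", n_trees = 50, seed = 1), k = 10))
  expect_equal(nrow(rep_$per_fold), 10)
})

test_that("report serialization round-trips the key quantities", {
  tab <- simulate_feature_dataset(feature_sim_config(
    n_majority = 60, n_minority = 12, n_features = 2, n_patients = 10,
    seed = 103))
  rep_ <- suppressWarnings(run_experiment(
    tab, augmentation_plan("none"), classifier_config("rf", n_trees = 50,
                                                      seed = 1), k = 10))
  path <- withr::local_tempfile(fileext = ".json")
  write_experiment_report(rep_, path, seed = 1)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$average$accuracy, rep_$average$accuracy)
  expect_equal(nrow(back$per_fold), 10)
  expect_true(nzchar(back$config_hash))
  expect_true(file.exists(sub("\\.json$", "_folds.csv", path)))
})
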