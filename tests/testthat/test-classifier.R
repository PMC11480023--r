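test_that("LSTM backpropagation matches finite differences", {
  set.seed(105)
  n <- 5; T_ <- 3; d <- 4; hid <- 3
  for (bidir in c(FALSE, TRUE)) {
    net <- eegaug:::lstm_net_init(d, hid, 2, bidir)
    X <- lapply(1:T_, function(t) matrix(rnorm(n * d), n, d))
    y <- rbinom(n, 1, 0.5)
    loss_of <- function(net) {
      p <- eegaug:::lstm_net_forward(net, X)$prob
      p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
    fwd <- eegaug:::lstm_net_forward(net, X)
    dlogit <- (fwd$prob - y) / n
    gr <- eegaug:::lstm_net_backward(net, fwd, dlogit)
    eps <- 1e-6
    base <- loss_of(net)
    for (ci in seq_along(net$cells)) {
      for (fld in c("Wx", "Wh")) {
        pick <- sample(length(net$cells[[ci]][[fld]]), 3)
        for (i in pick) {
          n2 <- net
          n2$cells[[ci]][[fld]][i] <- n2$cells[[ci]][[fld]][i] + eps
          expect_equal(gr$cells[[ci]][[fld]][i], (loss_of(n2) - base) / eps,
                       tolerance = 1e-3)
        }
      }
      i <- sample(length(net$cells[[ci]]$b), 1)
      n2 <- net
      n2$cells[[ci]]$b[i] <- n2$cells[[ci]]$b[i] + eps
      expect_equal(gr$cells[[ci]]$b[i], (loss_of(n2) - base) / eps,
                   tolerance = 1e-3)
    }
    n2 <- net; n2$dense_b <- n2$dense_b + eps
    expect_equal(gr$dense_b, (loss_of(n2) - base) / eps, tolerance = 1e-3)
  }
})

test_that("both classifiers separate well-separated Gaussians", {
  sp <- group_kfold_splits(separable_table$patient_id, 5)
  tr <- separable_table[sp[[1]]$train_idx, ]
  te <- separable_table[sp[[1]]$test_idx, ]
  rf <- train_classifier(tr, classifier_config("rf", seed = 1))
  acc_rf <- mean((predict_classifier(rf, te) >= 0.5) == (te$label == 1))
  expect_gt(acc_rf, 0.95)
  lstm <- train_classifier(tr, classifier_config(
    "lstm", seed = 1, timesteps = 2, max_epochs = 60))
  acc_lstm <- mean((predict_classifier(lstm, te) >= 0.5) == (te$label == 1))
  expect_gt(acc_lstm, 0.95)
  # the recorded training-accuracy trace improves over training
  hist <- lstm$fit$history
  expect_gte(tail(hist$train_acc, 1), hist$train_acc[1])
})

test_that("Random Forest predictions are deterministic at a fixed seed", {
  sp <- group_kfold_splits(separable_table$patient_id, 5)
  tr <- separable_table[sp[[2]]$train_idx, ]
  te <- separable_table[sp[[2]]$test_idx, ]
  m1 <- train_classifier(tr, classifier_config("rf", seed = 4))
  m2 <- train_classifier(tr, classifier_config("rf", seed = 4))
  expect_identical(predict_classifier(m1, te), predict_classifier(m2, te))
})

test_that("LSTM infers channel-count timesteps from feature names", {
  tab <- extract_features(tiny_eeg)
  expect_equal(eegaug:::infer_timesteps(tab, classifier_config("lstm")), 3L)
  expect_equal(eegaug:::infer_timesteps(toy_table, classifier_config("lstm")),
               1L)
})

test_that("training contracts are enforced", {
  bad <- separable_table
  bad$label <- 0
  expect_error(train_classifier(bad, classifier_config("rf", seed = 1)),
               "both classes")
})

test_that("class weights shift the LSTM toward minority recall", {
  tab <- simulate_feature_dataset(feature_sim_config(
    n_majority = 270, n_minority = 30, n_features = 4,
    minority_mean = rep(1.2, 4), n_patients = 15, seed = 107))
  sp <- group_kfold_splits(tab$patient_id, 5)
  tr <- tab[sp[[1]]$train_idx, ]
  te <- tab[sp[[1]]$test_idx, ]
  cfg <- classifier_config("lstm", seed = 2, timesteps = 1, max_epochs = 40)
  plain <- train_classifier(tr, cfg)
  weighted <- train_classifier(tr, cfg,
                               weights = compute_class_weights(tr$label))
  rec <- function(m) {
    suppressWarnings(
      compute_metrics(te$label, predict_classifier(m, te))$recall)
  }
  expect_gte(rec(weighted), rec(plain))
})
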