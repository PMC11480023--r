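test_that("seizure labels are realized as exact counts at the requested fraction", {
  cfg <- sim_config(n_patients = 20, epochs_per_patient = 50, n_channels = 2,
                    seizure_fraction = 0.06, seed = 3)
  ds <- simulate_eeg_dataset(cfg)
  labs <- dataset_labels(ds)
  expect_length(labs, 1000)
  expect_equal(sum(labs), round(0.06 * 1000))
  # within the binomial 99% interval around 0.06 by construction
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.06) / 1000
  expect_gte(mean(labs), bounds[1])
  expect_lte(mean(labs), bounds[2])
})

test_that("degenerate fractions and determinism behave as promised", {
  cfg0 <- sim_config(n_patients = 3, epochs_per_patient = 4, n_channels = 2,
                     seizure_fraction = 0, seed = 5)
  expect_true(all(dataset_labels(simulate_eeg_dataset(cfg0)) == 0))
  cfg <- sim_config(n_patients = 2, epochs_per_patient = 3, n_channels = 2,
                    seizure_fraction = 0.5, seed = 9)
  d1 <- simulate_eeg_dataset(cfg)
  d2 <- simulate_eeg_dataset(cfg)
  expect_identical(d1$epochs, d2$epochs)
})

test_that("invalid simulator configs are rejected", {
  expect_error(sim_config(n_patients = 0), "positive integer")
  expect_error(sim_config(seizure_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(fs = 100), "250")
})

test_that("seizure epochs carry more power in the injected band than background", {
  cfg <- sim_config(n_patients = 3, epochs_per_patient = 12, n_channels = 6,
                    seizure_fraction = 0.25, seed = 21)
  ds <- simulate_eeg_dataset(cfg)
  labs <- dataset_labels(ds)
  pids <- dataset_patients(ds)
  band_power <- function(epoch) {
    # mean 2.5-9.5 Hz power over channels (covers the 3 Hz burst + harmonics)
    mean(apply(epoch, 1, function(x) {
      p <- welch_psd(x, ds$fs)
      sum(p$psd[p$freq >= 2.5 & p$freq <= 9.5])
    }))
  }
  for (pid in unique(pids)) {
    sz <- which(pids == pid & labs == 1)
    bg <- which(pids == pid & labs == 0)
    if (!length(sz) || !length(bg)) next
    expect_gt(min(vapply(ds$epochs[sz], function(e) band_power(e$data), 1)),
              max(vapply(ds$epochs[bg], function(e) band_power(e$data), 1)) * 0.99)
  }
})

test_that("per-patient amplitude scaling is constant within a patient", {
  cfg <- sim_config(n_patients = 6, epochs_per_patient = 8, n_channels = 2,
                    seizure_fraction = 0, patient_effect_sd = 0.6, seed = 13)
  ds <- simulate_eeg_dataset(cfg)
  pids <- dataset_patients(ds)
  sds <- vapply(ds$epochs, function(e) sd(as.vector(e$data)), numeric(1))
  within_cv <- vapply(unique(pids), function(p) {
    s <- sds[pids == p]; sd(s) / mean(s)
  }, numeric(1))
  between_cv <- sd(tapply(sds, pids, mean)) / mean(sds)
  expect_lt(max(within_cv), between_cv)
})

test_that("feature-table simulator delivers exact counts and known means", {
  cfg <- feature_sim_config(n_majority = 100, n_minority = 10, n_features = 2,
                            minority_mean = c(2, 2), seed = 17)
  tab <- simulate_feature_dataset(cfg)
  expect_equal(as.integer(table(tab$label)), c(100L, 10L))
  cfg2 <- feature_sim_config(n_majority = 200, n_minority = 50, n_features = 2,
                             minority_mean = c(2, 2), seed = 23)
  tab2 <- simulate_feature_dataset(cfg2)
  mins <- colMeans(feature_matrix(tab2[tab2$label == 1, ]))
  expect_true(all(abs(mins - 2) < 3 / sqrt(50)))
  expect_identical(simulate_feature_dataset(cfg2), tab2)
})

test_that("feature simulator rejects invalid covariances and counts", {
  expect_error(feature_sim_config(10, 20), "exceed")
  bad <- matrix(c(1, 2, 0, 1), 2)
  expect_error(feature_sim_config(10, 5, 2, majority_cov = bad), "symmetric")
})
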