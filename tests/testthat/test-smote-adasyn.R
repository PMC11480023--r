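test_that("the SMOTE interpolation primitive is exact", {
  expect_equal(smote_sample(c(1, 2), c(3, 4), 0), c(1, 2))
  expect_equal(smote_sample(c(1, 2), c(3, 4), 1), c(3, 4))
  expect_equal(smote_sample(c(0, 0), c(2, 4), 0.5), c(1, 2))
  expect_error(smote_sample(c(1, 2), c(1, 2, 3), 0.5), "dimensionality")
  expect_error(smote_sample(c(1), c(2), 1.5), "\\[0, 1\\]")
})

test_that("SMOTE matches the brute-force reference exactly on a toy set", {
  tab <- simulate_feature_dataset(feature_sim_config(
    n_majority = 20, n_minority = 6, n_features = 2,
    minority_mean = c(2, 2), seed = 61))
  out <- smote_oversample(tab, k = 3, n_target = 9, seed = 99)
  synth <- feature_matrix(out[out$is_synthetic, ])
  ref <- brute_smote(tab, k = 3, n_target = 9, seed = 99)
  expect_equal(unname(synth), unname(ref))
})

test_that("SMOTE preserves originals and stays in the minority convex hull", {
  out <- smote_oversample(toy_table, k = 5, n_target = 30, seed = 7)
  expect_identical(out[!out$is_synthetic, colnames(toy_table)], toy_table)
  synth <- feature_matrix(out[out$is_synthetic, ])
  mino <- feature_matrix(toy_table[toy_table$label == 1, ])
  # interpolation keeps every coordinate within the minority range
  for (j in 1:2) {
    expect_gte(min(synth[, j]), min(mino[, j]) - 1e-12)
    expect_lte(max(synth[, j]), max(mino[, j]) + 1e-12)
  }
  expect_identical(smote_oversample(toy_table, k = 5, n_target = 0, seed = 1),
                   toy_table)
  expect_error(smote_oversample(toy_table, k = 12, n_target = 5, seed = 1),
               "exceed")
})

test_that("ADASYN density ratios follow the defining arithmetic", {
  # minority point at the origin with 2 majority / 3 minority among its
  # K = 5 nearest neighbors
  tab <- data.frame(
    patient_id = "P1", label = c(1, 1, 1, 1, 0, 0, 0),
    f1 = c(0, 0.1, -0.1, 0.05, 0.12, -0.12, 3),
    f2 = c(0, 0.1, -0.1, -0.05, 0.02, -0.02, 3))
  r <- adasyn_ratios(tab, K = 5, G = 10)
  expect_equal(r$r[1], 2 / 5)
  expect_equal(sum(r$r_hat), 1, tolerance = 1e-12)
  expect_equal(sum(r$g), 10)
})

test_that("largest-remainder allocation is exact on the worked example", {
  expect_equal(eegaug:::largest_remainder(10 * c(0.2, 0.8), 10), c(2L, 8L))
  expect_equal(sum(eegaug:::largest_remainder(7 * c(1, 1, 1) / 3, 7)), 7)
})

test_that("ADASYN matches the brute-force implementation of its equations", {
  tab <- simulate_feature_dataset(feature_sim_config(
    n_majority = 20, n_minority = 8, n_features = 2,
    minority_mean = c(1.5, 1.5), seed = 67))
  ref <- brute_adasyn(tab, K = 5, G = 12, seed = 101)
  rat <- adasyn_ratios(tab, K = 5, G = 12)
  expect_equal(rat$r_hat, ref$r_hat)
  expect_equal(rat$g, as.integer(ref$g))
  out <- adasyn_oversample(tab, K = 5, G = 12, seed = 101)
  expect_equal(unname(feature_matrix(out[out$is_synthetic, ])),
               unname(ref$synth))
  expect_equal(sum(out$is_synthetic), 12)
})

test_that("ADASYN allocates more synthetics where ratios are larger", {
  rat <- adasyn_ratios(toy_table, K = 5, G = 40)
  ord <- order(rat$r_hat)
  expect_true(all(diff(rat$g[ord]) >= -1))  # monotone up to integer rounding
  expect_identical(adasyn_oversample(toy_table, K = 5, G = 0, seed = 1),
                   toy_table)
})

test_that("class weights are inverse-frequency and symmetric", {
  expect_equal(compute_class_weights(rep(c(0, 1), each = 50)),
               c("0" = 1, "1" = 1))
  w <- compute_class_weights(rep(c(0, 1), c(90, 10)))
  expect_equal(unname(w["1"] / w["0"]), 9)
  expect_error(compute_class_weights(rep(1, 5)), "both classes")
})
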