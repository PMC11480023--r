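test_that("feature vectors have the documented dimensionality and names", {
  ep1 <- tiny_eeg$epochs[[1]]$data[1, , drop = FALSE]
  fv1 <- extract_feature_vector(ep1, tiny_eeg$fs)
  expect_length(fv1, 44)
  expect_identical(names(fv1), paste0("ch01_", channel_feature_names()))
  fv3 <- extract_feature_vector(tiny_eeg$epochs[[1]]$data, tiny_eeg$fs)
  expect_length(fv3, 44 * 3)
})

test_that("permuting channels permutes the 44-blocks accordingly", {
  ep <- tiny_eeg$epochs[[2]]$data
  fv <- extract_feature_vector(ep, tiny_eeg$fs)
  perm <- c(3, 1, 2)
  fvp <- extract_feature_vector(ep[perm, ], tiny_eeg$fs)
  block <- function(v, ch) unname(v[(ch - 1) * 44 + 1:44])
  for (new_pos in 1:3) {
    expect_identical(block(fvp, new_pos), block(fv, perm[new_pos]))
  }
})

test_that("extraction is bitwise deterministic", {
  ep <- tiny_eeg$epochs[[3]]$data
  expect_identical(extract_feature_vector(ep, tiny_eeg$fs),
                   extract_feature_vector(ep, tiny_eeg$fs))
})

test_that("every simulated epoch yields a finite feature vector", {
  ds <- simulate_eeg_dataset(sim_config(
    n_patients = 25, epochs_per_patient = 40, n_channels = 1,
    seizure_fraction = 0.06, seed = 51))
  tab <- extract_features(ds)
  expect_equal(nrow(tab), 1000)
  expect_true(all(is.finite(feature_matrix(tab))))
})

test_that("scale-invariant features ignore amplitude; energies scale quadratically", {
  ep <- tiny_eeg$epochs[[4]]$data
  a <- extract_feature_vector(ep, tiny_eeg$fs)
  b <- extract_feature_vector(ep * 3.1, tiny_eeg$fs)
  inv <- grep("psd_rel_|perment_|hjorth_mobility|hjorth_complexity", names(a))
  expect_equal(a[inv], b[inv], tolerance = 1e-8)
  quad <- grep("variance|mean_energy|cum_energy", names(a))
  expect_equal(unname(b[quad] / a[quad]), rep(3.1^2, length(quad)),
               tolerance = 1e-8)
})

test_that("the feature dictionary names every column of an extracted table", {
  tab <- extract_features(tiny_eeg)
  dict <- feature_dictionary(3)
  expect_identical(dict$name, feature_columns(tab))
  expect_setequal(unique(dict$family),
                  c("band_power", "moments", "emd", "entropy", "hjorth",
                    "spectral_entropy", "wavelet", "sdi_energy"))
})
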