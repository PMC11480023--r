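test_that("EMD recovers a pure sine as its first IMF", {
  x <- sine_wave(8, seconds = 2)
  dec <- emd_decompose(x)
  expect_gte(nrow(dec$imfs), 1)
  imf1 <- dec$imfs[1, ]
  core <- 50:450                      # away from boundary effects
  expect_gt(cor(imf1[core], x[core]), 0.99)
  expect_equal(sum(imf1[core]^2) / sum(x[core]^2), 1, tolerance = 0.05)
})

test_that("EMD features are deterministic and handle degenerate input", {
  set.seed(41)
  x <- rnorm(500)
  f1 <- extract_emd_features(x, 250)
  f2 <- extract_emd_features(x, 250)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
  expect_warning(f0 <- extract_emd_features(rep(1, 500), 250), "degenerate")
  expect_true(all(f0 == 0))
})

test_that("first-IMF mean is near zero for an oscillatory signal", {
  x <- sine_wave(12, seconds = 2) + 0.1 * rnorm(500)
  f <- extract_emd_features(x, 250)
  expect_lt(abs(f[["emd_mean"]]), 0.05)
  # population second central moment vs n-1 sample variance
  expect_equal(f[["emd_moment"]], f[["emd_sd"]]^2 * 499 / 500,
               tolerance = 1e-9)
})

test_that("wavelet subband energies conserve signal energy (Parseval)", {
  set.seed(43)
  for (n in c(1000, 1024)) {
    x <- rnorm(n)
    dec <- dwt_db4(x, 5)
    sub_e <- sum(unlist(dec$details)^2) + sum(dec$approx^2)
    expect_equal(sub_e, sum(x^2), tolerance = 1e-6 * sum(x^2))
  }
})

test_that("wavelet energy percentages are bounded and frequency-ordered", {
  set.seed(45)
  w <- extract_wavelet_features(rnorm(1000))
  pct <- w[grep("wav_energy_pct", names(w))]
  expect_true(all(pct >= 0 & pct <= 100))
  expect_lte(sum(pct), 100)
  # a 1 Hz sine sits below every detail band: the deepest approximation
  # holds most of the energy
  slow <- extract_wavelet_features(sine_wave(1))
  pct_slow <- slow[grep("wav_energy_pct", names(slow))]
  expect_lt(sum(pct_slow), 50)
  # a fast oscillation loads the finest detail levels instead
  fast <- extract_wavelet_features(sine_wave(100))
  pct_fast <- fast[grep("wav_energy_pct", names(fast))]
  expect_gt(sum(pct_fast), 50)
  expect_gt(which.max(pct_slow[1:5]) , which.max(pct_fast[1:5]))
})

test_that("wavelet packet energies also conserve energy", {
  set.seed(47)
  x <- rnorm(512)
  nodes <- eegaug:::wpd_db4(x, 3)
  expect_length(nodes, 8)
  expect_equal(sum(vapply(nodes, function(z) sum(z^2), 1)), sum(x^2),
               tolerance = 1e-8 * sum(x^2))
})

test_that("constant signals yield zero wavelet features with a warning", {
  expect_warning(w <- extract_wavelet_features(rep(2, 256)), "degenerate")
  expect_true(all(w == 0))
  expect_error(extract_wavelet_features(rnorm(16)), "too short")
})
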