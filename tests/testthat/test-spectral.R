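test_that("a pure 10 Hz sine concentrates relative power in alpha", {
  x <- sine_wave(10)
  bp <- extract_band_powers(x, 250)
  expect_gt(bp[["psd_rel_alpha"]], 0.95)
  # periodogram oracle on the same sine agrees on the dominant band
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  f <- sp$freq * 250
  oracle_alpha <- sum(sp$spec[f >= 8 & f <= 13]) /
    sum(sp$spec[f >= 0.5 & f <= 45])
  expect_gt(oracle_alpha, 0.95)
})

test_that("relative band powers always sum to one", {
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(1000) + sine_wave(sample(2:40, 1))
    bp <- extract_band_powers(x, 250)
    expect_equal(sum(bp[sprintf("psd_rel_%s", c("delta", "theta", "alpha",
                                                "beta", "gamma"))]),
                 1, tolerance = 1e-9)
  }
})

test_that("white noise spreads relative power like bandwidth fractions", {
  set.seed(8)
  x <- rnorm(250 * 60)                 # long epoch for a stable estimate
  bp <- extract_band_powers(x, 250)
  widths <- c(3.5, 4, 5, 17, 15)       # band widths within the 0.5-45 range
  expect_equal(unname(bp[11:15]), widths / sum(widths), tolerance = 0.05)
})

test_that("constant signals take the degenerate zero rule with a warning", {
  expect_warning(bp <- extract_band_powers(rep(2, 1000), 250), "degenerate")
  expect_true(all(bp == 0))
  expect_warning(se <- extract_spectral_entropy(rep(0, 1000), 250), "degenerate")
  expect_equal(unname(se), 0)
})

test_that("relative powers are amplitude-invariant, absolute powers quadratic", {
  set.seed(15)
  x <- rnorm(1000) + sine_wave(6)
  a <- extract_band_powers(x, 250)
  b <- extract_band_powers(2.7 * x, 250)
  expect_equal(a[11:15], b[11:15], tolerance = 1e-9)
  expect_equal(unname(b[6:10] / a[6:10]), rep(2.7^2, 5), tolerance = 1e-9)
})

test_that("spectral entropy separates narrowband from broadband signals", {
  set.seed(16)
  tone <- extract_spectral_entropy(sine_wave(10), 250)
  noise <- extract_spectral_entropy(rnorm(1000), 250)
  expect_lt(tone, noise)
  expect_gt(noise, 0.8)
})
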