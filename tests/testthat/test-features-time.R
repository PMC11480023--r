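test_that("moment features match direct arithmetic and conventions", {
  expect_equal(extract_moments(rep(3, 10)),
               c(skewness = 0, variance = 0, kurtosis = 0))
  expect_equal(extract_moments(rep(c(-1, 1), 50))[["skewness"]], 0)
  x <- c(1, 2, 3, 4, 5)
  m <- extract_moments(x)
  expect_equal(m[["variance"]], sum((x - 3)^2) / 4)   # n-1 estimator
  expect_equal(m[["kurtosis"]], mean((x - 3)^4) / mean((x - 3)^2)^2 - 3)
})

test_that("Hjorth parameters follow their definitions", {
  set.seed(2)
  x <- rnorm(500)
  h <- extract_hjorth(x)
  expect_equal(h[["hjorth_activity"]], extract_moments(x)[["variance"]])
  expect_equal(h[["hjorth_mobility"]], sqrt(var(diff(x)) / var(x)))
  expect_equal(extract_hjorth(rep(1, 100)),
               c(hjorth_mobility = 0, hjorth_activity = 0,
                 hjorth_complexity = 0))
  # a sinusoid's derivative is a sinusoid at the same frequency
  expect_equal(extract_hjorth(sine_wave(10))[["hjorth_complexity"]], 1,
               tolerance = 0.05)
  expect_lt(extract_hjorth(sine_wave(5))[["hjorth_mobility"]],
            extract_hjorth(sine_wave(40))[["hjorth_mobility"]])
})

test_that("sample entropy matches the independent template-counting oracle", {
  brute_sampen <- function(x, m, r) {
    n <- length(x)
    count <- function(mm) {
      c_ <- 0
      for (i in 1:(n - m)) for (j in 1:(n - m)) {
        if (i == j) next
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) c_ <- c_ + 1
      }
      c_
    }
    -log(count(m + 1) / count(m))
  }
  set.seed(31)
  for (i in 1:3) {
    x <- rnorm(80)
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, 2, r), brute_sampen(x, 2, r))
  }
  skip_if_not_installed("pracma")
  x <- rnorm(300)
  expect_equal(sample_entropy(x, 2, 0.2 * sd(x)),
               pracma::sample_entropy(x, edim = 2, r = 0.2 * sd(x)))
})

test_that("periodic signals are more regular than noise under sample entropy", {
  set.seed(33)
  periodic <- rep(c(0, 1, 2, 1), 50)
  noise <- rnorm(200)
  expect_lt(sample_entropy(periodic, 2, 0.2 * sd(periodic)),
            sample_entropy(noise, 2, 0.2 * sd(noise)))
})

test_that("permutation entropy hits its analytic endpoints", {
  ramp <- seq_len(200)
  for (m in 3:6) expect_equal(permutation_entropy(ramp, m), 0)
  set.seed(35)
  u <- runif(20000)
  expect_gt(permutation_entropy(u, 3), 0.999)
  expect_gt(permutation_entropy(u, 4), 0.99)
})

test_that("permutation entropy matches a naive rank-pattern counter", {
  naive <- function(x, m) {
    pats <- vapply(seq_len(length(x) - m + 1), function(i)
      paste(rank(x[i:(i + m - 1)], ties.method = "first"), collapse = "."),
      character(1))
    p <- table(pats) / length(pats)
    -sum(p * log(p)) / log(factorial(m))
  }
  set.seed(37)
  for (m in c(3, 5)) {
    x <- rnorm(150)
    expect_equal(permutation_entropy(x, m), naive(x, m))
  }
})

test_that("SDI and energy features satisfy their identities", {
  expect_equal(extract_sdi_energy(rep(0, 64)),
               c(sdi = 0, mean_energy = 0, cum_energy = 0))
  v <- extract_sdi_energy(rep(1, 16))
  expect_equal(v[["mean_energy"]], 1)
  expect_equal(v[["cum_energy"]], 16)
  set.seed(39)
  x <- rnorm(500)
  v2 <- extract_sdi_energy(x)
  expect_equal(v2[["cum_energy"]], length(x) * v2[["mean_energy"]])
  # SDI grows with amplitude
  expect_gt(extract_sdi_energy(10 * x)[["sdi"]], v2[["sdi"]])
})
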