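test_that("QQ deviations obey identity and translation equivariance", {
  set.seed(81)
  x <- rnorm(400)
  q0 <- qq_compare(x, x)
  expect_equal(q0$max_abs_deviation, 0)
  expect_true(all(diff(q0$table$q_real) >= 0))
  for (c_ in c(-2.5, 0.7)) {
    expect_equal(qq_compare(x, x + c_)$max_abs_deviation, abs(c_))
  }
  expect_error(qq_compare(numeric(0), x), "non-empty")
})

test_that("per-feature QQ summary pools deviations", {
  set.seed(82)
  a <- matrix(rnorm(600), ncol = 3)
  b <- a + 1
  qt <- qq_compare_table(a, b)
  expect_equal(nrow(qt), 3)
  expect_equal(qt$max_abs_deviation, rep(1, 3))
  expect_equal(attr(qt, "pooled_mean"), 1)
})

test_that("energy distance is a symmetric divergence that tracks separation", {
  set.seed(83)
  x <- matrix(rnorm(200), ncol = 2)
  expect_equal(distribution_distance(x, x), 0)
  y <- matrix(rnorm(160), ncol = 2)
  expect_equal(distribution_distance(x, y), distribution_distance(y, x))
  expect_error(distribution_distance(x, matrix(0, 4, 3)), "dimensionality")
  d <- vapply(c(0, 1, 2, 4), function(delta) {
    set.seed(90)
    a <- matrix(rnorm(300), ncol = 2)
    b <- matrix(rnorm(300), ncol = 2) + delta
    distribution_distance(a, b)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("true-distribution samples beat shifted samples in >= 95% of trials", {
  wins <- 0L
  for (i in 1:100) {
    set.seed(1000 + i)
    real <- matrix(rnorm(120), ncol = 2)
    good <- matrix(rnorm(120), ncol = 2)
    bad <- matrix(rnorm(120), ncol = 2) + 2   # 2-SD shift
    if (distribution_distance(real, good) < distribution_distance(real, bad)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 95L)
})

test_that("2-D projections keep row counts, labels and determinism", {
  set.seed(85)
  real <- matrix(rnorm(120), ncol = 4)
  synth <- matrix(rnorm(80), ncol = 4)
  for (m in c("tsvd", "kpca", "fastica", "tsne")) {
    pr <- project_2d(real, synth, method = m, seed = 9)
    expect_equal(nrow(pr), 50)
    expect_equal(sum(pr$origin == "real"), 30)
    expect_true(all(is.finite(pr$dim1)))
    pr2 <- project_2d(real, synth, method = m, seed = 9)
    expect_equal(pr, pr2)
  }
})

test_that("identical rows labeled synthetic collapse onto the real centroid", {
  set.seed(86)
  real <- matrix(rnorm(100), ncol = 2)
  pr <- project_2d(real, real, method = "tsvd", seed = 1)
  cr <- colMeans(pr[pr$origin == "real", 1:2])
  cs <- colMeans(pr[pr$origin == "synthetic", 1:2])
  expect_equal(cr, cs, tolerance = 1e-10)
})

test_that("embedding separates shifted synthetic data but not same-distribution data", {
  set.seed(87)
  real <- matrix(rnorm(300), ncol = 2)
  same <- matrix(rnorm(300), ncol = 2)
  shifted <- matrix(rnorm(300), ncol = 2) + 5
  centroid_gap <- function(synth) {
    pr <- project_2d(real, synth, method = "tsvd", seed = 2)
    sqrt(sum((colMeans(pr[pr$origin == "real", 1:2]) -
                colMeans(pr[pr$origin == "synthetic", 1:2]))^2))
  }
  expect_lt(centroid_gap(same), centroid_gap(shifted))
})
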