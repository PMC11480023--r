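test_that("gradient penalty vanishes for a unit-slope linear critic in 1-D", {
  net <- list(W = list(matrix(1, 1, 1)), b = list(0), out_act = "linear",
              sizes = c(1, 1))
  gp <- eegaug:::gradient_penalty(net, matrix(rnorm(20), 20, 1), gp_lambda = 10)
  expect_equal(gp$penalty, 0)
  expect_true(all(abs(unlist(gp$grads$W)) < 1e-12))
})

test_that("gradient-penalty parameter gradients match finite differences", {
  set.seed(71)
  net <- eegaug:::mlp_init(c(2, 6, 5, 1), "linear")
  X <- matrix(rnorm(16), 8, 2)
  gp <- eegaug:::gradient_penalty(net, X, 10)
  eps <- 1e-6
  for (l in seq_along(net$W)) {
    pick <- sample(length(net$W[[l]]), min(4, length(net$W[[l]])))
    for (i in pick) {
      n2 <- net
      n2$W[[l]][i] <- n2$W[[l]][i] + eps
      num <- (eegaug:::gradient_penalty(n2, X, 10)$penalty - gp$penalty) / eps
      expect_equal(gp$grads$W[[l]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("all four GAN variants train and keep bookkeeping contracts", {
  for (variant in c("wgan_gp", "vanilla", "cgan", "cramer")) {
    cfg <- gan_config(variant, noise_dim = 4, generator_widths = c(8, 8),
                      critic_widths = c(8, 8), batch_size = 8, epochs = 5,
                      seed = 3)
    m <- suppressWarnings(train_gan(toy_table, cfg))
    expect_equal(nrow(m$loss_trace), 5)
    expect_true(all(is.finite(m$loss_trace$critic_loss)))
    g <- generate_synthetic(m, 7, seed = 5)
    expect_equal(dim(g), c(7, 2))
    expect_true(all(is.finite(g)))
    expect_equal(generate_synthetic(m, 7, seed = 5), g)
    expect_equal(nrow(generate_synthetic(m, 0, seed = 5)), 0)
  }
})

test_that("GAN training is deterministic under a fixed seed", {
  cfg <- gan_config("wgan_gp", noise_dim = 4, generator_widths = c(8, 8),
                    critic_widths = c(8, 8), batch_size = 8, epochs = 4,
                    seed = 13)
  m1 <- suppressWarnings(train_gan(toy_table, cfg))
  m2 <- suppressWarnings(train_gan(toy_table, cfg))
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$generator$W, m2$generator$W)
})

test_that("generation inverts the internal standardization", {
  set.seed(77)
  x <- cbind(rnorm(200, 50, 5), rnorm(200, -3, 0.1))
  cfg <- gan_config("wgan_gp", noise_dim = 4, generator_widths = c(16, 16),
                    critic_widths = c(16, 16), batch_size = 32, epochs = 40,
                    seed = 5)
  m <- train_gan(x, cfg)
  g <- generate_synthetic(m, 500, seed = 1)
  # generated samples live on the original feature scale, not z-scores
  expect_gt(mean(g[, 1]), 20)
  expect_lt(mean(g[, 2]), 0)
})

test_that("invalid GAN configurations are rejected", {
  expect_error(gan_config("wgan_gp", gp_lambda = -1), "non-negative")
  expect_error(gan_config("nope"), "arg")
  expect_error(gan_config("wgan_gp", critic_steps = 0), ">= 1")
})
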