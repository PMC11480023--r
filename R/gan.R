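#' Configuration of a tabular GAN
#'
#' Four loss variants are implemented: `vanilla` (original adversarial
#' game with a sigmoid discriminator), `cgan` (label-conditioned generator
#' and discriminator, trained on both classes, generation targeting the
#' minority label), `cramer` (the critic objective replaced by its
#' energy-distance surrogate — the generator directly minimizes the sample
#' energy distance to real batches; documented approximation of the Cramer
#' formulation), and `wgan_gp` (Wasserstein critic loss with an exact
#' gradient penalty driving the critic's input-gradient norm to 1).
#'
#' Optimizer defaults are Adam with learning rate 0.001, beta1 = 0.9,
#' beta2 = 0.999 — except for `wgan_gp`, which defaults to the original
#' Wasserstein-GP prescription (learning rate 1e-4, beta1 = 0,
#' beta2 = 0.9): the momentum-heavy setting destabilizes the critic late
#' in training. Both can be overridden. Other WGAN-GP defaults follow
#' standard practice: penalty coefficient 10, 5 critic updates per
#' generator update.
#'
#' @param variant one of `"vanilla"`, `"cgan"`, `"cramer"`, `"wgan_gp"`
#' @param noise_dim latent dimension (default 64)
#' @param generator_widths,critic_widths hidden-layer sizes
#' @param gp_lambda gradient-penalty coefficient (wgan_gp only)
#' @param critic_steps critic updates per generator update (wgan_gp)
#' @param batch_size minibatch size
#' @param epochs training epochs
#' @param learning_rate,beta1,beta2 Adam parameters
#' @param seed integer seed for initialization and batching
#' @param track_every if > 0 and `track_data` is passed to [train_gan()],
#'   record the energy distance between generated samples and the tracking
#'   data every this many epochs
#' @return an object of class `gan_config`
#' @export
gan_config <- function(variant = c("wgan_gp", "vanilla", "cgan", "cramer"),
                       noise_dim = 64, generator_widths = c(128, 128),
                       critic_widths = c(128, 128), gp_lambda = 10,
                       critic_steps = 5, batch_size = 64, epochs = 300,
                       learning_rate = NULL, beta1 = NULL, beta2 = NULL,
                       seed = 1L, track_every = 0) {
  variant <- match.arg(variant)
  if (variant == "wgan_gp") {
    learning_rate <- learning_rate %||% 1e-4
    beta1 <- beta1 %||% 0
    beta2 <- beta2 %||% 0.9
  } else {
    learning_rate <- learning_rate %||% 0.001
    beta1 <- beta1 %||% 0.9
    beta2 <- beta2 %||% 0.999
  }
  if (gp_lambda < 0) stop("`gp_lambda` must be non-negative", call. = FALSE)
  if (critic_steps < 1) stop("`critic_steps` must be >= 1", call. = FALSE)
  structure(list(variant = variant, noise_dim = as.integer(noise_dim),
                 generator_widths = generator_widths,
                 critic_widths = critic_widths, gp_lambda = gp_lambda,
                 critic_steps = as.integer(critic_steps),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), track_every = as.integer(track_every)),
            class = "gan_config")
}

#' Train a GAN on minority-class feature rows
#'
#' Features are standardized to zero mean / unit SD internally (the scaler
#' is stored on the model and inverted on generation) so scale disparities
#' between feature families do not dominate the critic. For `cgan` the
#' full table (both classes) is used with label conditioning; all other
#' variants train on the minority rows only.
#'
#' @param data a feature table data.frame (minority rows are selected for
#'   non-conditional variants) or a plain numeric matrix of minority rows
#' @param config a [gan_config()]
#' @param track_data optional held-out real matrix/table for fidelity
#'   tracking (see `track_every` in [gan_config()])
#' @return a `gan_model`: generator and critic networks, scaler, variant,
#'   per-epoch `loss_trace` (data.frame epoch/critic_loss/gen_loss) and
#'   optional `fidelity_trace`
#' @export
train_gan <- function(data, config, track_data = NULL) {
  stopifnot(inherits(config, "gan_config"))
  if (is.data.frame(data)) {
    assert_feature_table(data)
    labels <- data$label
    x <- feature_matrix(data)
    if (config$variant != "cgan") {
      x <- x[labels == 1, , drop = FALSE]
      labels <- rep(1L, nrow(x))
    }
  } else {
    x <- as.matrix(data)
    labels <- rep(1L, nrow(x))
  }
  if (!all(is.finite(x))) stop("non-finite values in GAN training data", call. = FALSE)
  n <- nrow(x)
  d <- ncol(x)
  batch <- config$batch_size
  if (n < 2 * batch) {
    batch <- max(4L, n %/% 2L)
    warning(sprintf("few training rows (%d): batch size shrunk to %d", n, batch))
  }
  sc <- fit_scaler(x)
  z <- apply_scaler(x, sc)
  if (!is.null(track_data)) {
    tx <- if (is.data.frame(track_data)) feature_matrix(track_data) else
      as.matrix(track_data)
    tz <- apply_scaler(tx, sc)
  }
  cond <- config$variant == "cgan"
  g_in <- config$noise_dim + if (cond) 1L else 0L
  c_in <- d + if (cond) 1L else 0L

  with_seed(config$seed, {
    gen <- mlp_init(c(g_in, config$generator_widths, d), "linear")
    g_opt <- adam_init(gen)
    crit <- NULL
    c_opt <- NULL
    if (config$variant != "cramer") {
      crit <- mlp_init(c(c_in, config$critic_widths, 1),
                       if (config$variant == "wgan_gp") "linear" else "sigmoid")
      c_opt <- adam_init(crit)
    }
    trace <- data.frame(epoch = seq_len(config$epochs), critic_loss = NA_real_,
                        gen_loss = NA_real_)
    fid <- NULL
    since_gen <- 0L

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      c_losses <- g_losses <- numeric(0)
      for (start in seq(1, n - batch + 1, by = batch)) {
        idx <- ord[start:(start + batch - 1)]
        real <- z[idx, , drop = FALSE]
        real_y <- labels[idx]
        noise <- matrix(stats::rnorm(batch * config$noise_dim), batch)
        fake_y <- if (cond) sample(labels, batch, replace = TRUE) else NULL
        g_in_mat <- if (cond) cbind(noise, fake_y) else noise
        fcache <- mlp_forward(gen, g_in_mat)
        fake <- fcache$out

        if (config$variant == "wgan_gp") {
          step <- wgan_critic_step(crit, c_opt, real, fake, config)
          crit <- step$net; c_opt <- step$opt
          c_losses <- c(c_losses, step$loss)
          since_gen <- since_gen + 1L
          if (since_gen >= config$critic_steps) {
            since_gen <- 0L
            gu <- wgan_generator_step(gen, g_opt, crit, config, cond, labels)
            gen <- gu$net; g_opt <- gu$opt
            g_losses <- c(g_losses, gu$loss)
          }
        } else if (config$variant == "cramer") {
          gu <- cramer_generator_step(gen, g_opt, real, g_in_mat, fcache, config)
          gen <- gu$net; g_opt <- gu$opt
          g_losses <- c(g_losses, gu$loss)
          c_losses <- c(c_losses, gu$loss)
        } else {  # vanilla / cgan
          step <- bce_discriminator_step(crit, c_opt, real, real_y, fake,
                                         fake_y, config, cond)
          crit <- step$net; c_opt <- step$opt
          c_losses <- c(c_losses, step$loss)
          gu <- bce_generator_step(gen, g_opt, crit, config, cond, labels)
          gen <- gu$net; g_opt <- gu$opt
          g_losses <- c(g_losses, gu$loss)
        }
      }
      trace$critic_loss[ep] <- mean(c_losses)
      trace$gen_loss[ep] <- if (length(g_losses)) mean(g_losses) else NA_real_
      if (!is.finite(trace$critic_loss[ep])) {
        stop(sprintf("non-finite %s loss at epoch %d: training diverged",
                     config$variant, ep), call. = FALSE)
      }
      if (config$track_every > 0 && !is.null(track_data) &&
          ep %% config$track_every == 0) {
        gi <- matrix(stats::rnorm(nrow(tz) * config$noise_dim), nrow(tz))
        if (cond) gi <- cbind(gi, 1)
        samp <- mlp_forward(gen, gi)$out
        fid <- rbind(fid, data.frame(
          epoch = ep, energy_distance = energy_distance_mat(tz, samp)))
      }
    }
    structure(list(generator = gen, critic = crit, variant = config$variant,
                   scaler = sc, dim = d, config = config, loss_trace = trace,
                   fidelity_trace = fid),
              class = "gan_model")
  })
}

wgan_critic_step <- function(crit, opt, real, fake, config) {
  nb <- nrow(real)
  rc <- mlp_forward(crit, real)
  fc <- mlp_forward(crit, fake)
  eps <- stats::runif(nb)
  xhat <- real * eps + fake * (1 - eps)
  gp <- gradient_penalty(crit, xhat, config$gp_lambda)
  loss <- mean(fc$out) - mean(rc$out) + gp$penalty
  g_real <- mlp_backward(crit, rc, matrix(-1 / nb, nb, 1))
  g_fake <- mlp_backward(crit, fc, matrix(1 / nb, nb, 1))
  grads <- add_grads(add_grads(g_real, g_fake), gp$grads)
  up <- adam_step(crit, grads, opt, config$learning_rate, config$beta1,
                  config$beta2)
  list(net = up$net, opt = up$state, loss = loss)
}

wgan_generator_step <- function(gen, opt, crit, config, cond, labels) {
  nb <- config$batch_size
  noise <- matrix(stats::rnorm(nb * config$noise_dim), nb)
  gin <- if (cond) cbind(noise, sample(labels, nb, replace = TRUE)) else noise
  gc_ <- mlp_forward(gen, gin)
  cc <- mlp_forward(crit, gc_$out)
  loss <- -mean(cc$out)
  dfake <- mlp_backward(crit, cc, matrix(-1 / nb, nb, 1))$dX
  grads <- mlp_backward(gen, gc_, dfake)
  up <- adam_step(gen, grads, opt, config$learning_rate, config$beta1,
                  config$beta2)
  list(net = up$net, opt = up$state, loss = loss)
}

bce_discriminator_step <- function(crit, opt, real, real_y, fake, fake_y,
                                   config, cond) {
  nb <- nrow(real)
  rin <- if (cond) cbind(real, real_y) else real
  fin <- if (cond) cbind(fake, fake_y) else fake
  rc <- mlp_forward(crit, rin)
  fc <- mlp_forward(crit, fin)
  p_r <- pmin(pmax(rc$out, 1e-7), 1 - 1e-7)
  p_f <- pmin(pmax(fc$out, 1e-7), 1 - 1e-7)
  loss <- -mean(log(p_r)) - mean(log(1 - p_f))
  # sigmoid + BCE: d loss / d preact = (p - y) / n
  g_r <- mlp_backward(crit, rc, (rc$out - 1) / nb)
  g_f <- mlp_backward(crit, fc, (fc$out - 0) / nb)
  up <- adam_step(crit, add_grads(g_r, g_f), opt, config$learning_rate,
                  config$beta1, config$beta2)
  list(net = up$net, opt = up$state, loss = loss)
}

bce_generator_step <- function(gen, opt, crit, config, cond, labels) {
  nb <- config$batch_size
  noise <- matrix(stats::rnorm(nb * config$noise_dim), nb)
  y <- if (cond) sample(labels, nb, replace = TRUE) else NULL
  gin <- if (cond) cbind(noise, y) else noise
  gc_ <- mlp_forward(gen, gin)
  cin <- if (cond) cbind(gc_$out, y) else gc_$out
  cc <- mlp_forward(crit, cin)
  p <- pmin(pmax(cc$out, 1e-7), 1 - 1e-7)
  loss <- -mean(log(p))           # non-saturating generator loss
  dfull <- mlp_backward(crit, cc, (cc$out - 1) / nb)$dX
  dfake <- if (cond) dfull[, seq_len(ncol(gc_$out)), drop = FALSE] else dfull
  grads <- mlp_backward(gen, gc_, dfake)
  up <- adam_step(gen, grads, opt, config$learning_rate, config$beta1,
                  config$beta2)
  list(net = up$net, opt = up$state, loss = loss)
}

# Generator step minimizing the sample energy distance between the
# generated batch and the real batch (Cramer-surrogate objective).
cramer_generator_step <- function(gen, opt, real, gin, gcache, config) {
  y <- gcache$out
  m <- nrow(y)
  ed <- energy_distance_mat(real, y)
  # d ED / d y_j = 2/(nm) sum_i (y_j - x_i)/||.|| - 2/m^2 sum_j' (y_j - y_j')/||.||
  dy <- matrix(0, m, ncol(y))
  for (j in seq_len(m)) {
    dx <- sweep(-real, 2, y[j, ], "+")            # y_j - x_i
    nx <- sqrt(rowSums(dx^2)); nx[nx < 1e-12] <- 1
    t1 <- colSums(dx / nx) * 2 / (nrow(real) * m)
    dyy <- sweep(-y, 2, y[j, ], "+")
    ny <- sqrt(rowSums(dyy^2)); ny[ny < 1e-12] <- 1
    t2 <- colSums(dyy / ny) * 2 / m^2
    dy[j, ] <- t1 - t2
  }
  grads <- mlp_backward(gen, gcache, dy)
  up <- adam_step(gen, grads, opt, config$learning_rate, config$beta1,
                  config$beta2)
  list(net = up$net, opt = up$state, loss = ed)
}

#' Generate synthetic minority rows from a trained GAN
#'
#' Draws standard-normal noise, maps it through the generator and inverts
#' the training-time standardization, returning rows on the original
#' feature scale. Conditional models are fed the minority label.
#'
#' @param model a `gan_model` from [train_gan()]
#' @param n number of rows to generate
#' @param seed integer seed
#' @return numeric matrix with `n` rows in the training feature space
#' @export
generate_synthetic <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "gan_model"))
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  if (n == 0) return(matrix(numeric(0), 0, model$dim))
  with_seed(seed, {
    gi <- matrix(stats::rnorm(n * model$config$noise_dim), n)
    if (model$variant == "cgan") gi <- cbind(gi, 1)
    z <- mlp_forward(model$generator, gi)$out
    invert_scaler(z, model$scaler)
  })
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf("<gan_model> variant=%s, dim=%d, epochs=%d, final critic loss %.4g\n",
              x$variant, x$dim, nrow(x$loss_trace),
              utils::tail(x$loss_trace$critic_loss, 1)))
  invisible(x)
}
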