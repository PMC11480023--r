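# Small dense-network toolkit used by the GAN variants: tanh hidden layers,
# linear or sigmoid output, Adam updates. Everything is batched with plain
# matrix algebra; rows are samples.

mlp_init <- function(sizes, out_act = c("linear", "sigmoid")) {
  out_act <- match.arg(out_act)
  L <- length(sizes) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))   # Glorot uniform
    W[[l]] <- matrix(stats::runif(sizes[l + 1] * sizes[l], -lim, lim),
                     sizes[l + 1], sizes[l])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, out_act = out_act, sizes = sizes)
}

# Forward pass; returns activations (H[[1]] = input, H[[l+1]] = hidden l)
# and the output. Hidden activations are tanh.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L)       # H[[l]] = input to layer l
  H[[1]] <- X
  A <- X
  for (l in seq_len(L - 1)) {
    A <- tanh(sweep(A %*% t(net$W[[l]]), 2, net$b[[l]], "+"))
    H[[l + 1]] <- A
  }
  out <- sweep(A %*% t(net$W[[L]]), 2, net$b[[L]], "+")
  if (net$out_act == "sigmoid") out <- 1 / (1 + exp(-out))
  list(H = H, out = out)
}

# Backward pass. `d_preact` is dLoss/d(output preactivation) (n x out_dim):
# for a linear output this is dLoss/d(out); for sigmoid + BCE the caller
# passes (p - y) / n directly. Returns parameter gradients and dLoss/dX.
mlp_backward <- function(net, cache, d_preact) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- d_preact
  for (l in L:1) {
    gW[[l]] <- t(delta) %*% cache$H[[l]]
    gb[[l]] <- colSums(delta)
    dH <- delta %*% net$W[[l]]
    if (l > 1) delta <- dH * (1 - cache$H[[l]]^2)
  }
  list(W = gW, b = gb, dX = dH)
}

# Gradient of a scalar-output critic with respect to its input, per row.
mlp_input_grad <- function(net, cache) {
  L <- length(net$W)
  n <- nrow(cache$H[[1]])
  V <- matrix(net$W[[L]], n, ncol(net$W[[L]]), byrow = TRUE)
  if (L > 1) {
    for (l in (L - 1):1) {
      V <- V * (1 - cache$H[[l + 1]]^2)
      V <- V %*% net$W[[l]]
    }
  }
  V
}

# WGAN-GP penalty and its exact parameter gradients at interpolated points
# Xhat. The penalty is gp_lambda * mean((||grad_x f(xhat)|| - 1)^2). Its
# parameter gradient is obtained by backpropagating through the computation
# of the input gradient itself (forward tangent pass + adjoint pass); tanh
# hidden units keep every second derivative smooth.
gradient_penalty <- function(net, Xhat, gp_lambda) {
  L <- length(net$W)               # layer count incl. scalar output layer
  stopifnot(net$out_act == "linear", nrow(net$W[[L]]) == 1)
  cache <- mlp_forward(net, Xhat)
  n <- nrow(Xhat)
  nh <- L - 1                      # hidden layers
  D <- lapply(seq_len(nh), function(l) 1 - cache$H[[l + 1]]^2)

  # input gradient g_i = grad_x f(xhat_i)
  G <- matrix(net$W[[L]], n, ncol(net$W[[L]]), byrow = TRUE)
  if (nh > 0) for (l in nh:1) G <- (G * D[[l]]) %*% net$W[[l]]
  gn <- sqrt(rowSums(G^2))
  penalty <- gp_lambda * mean((gn - 1)^2)

  # U rows: d penalty / d g_i (treating the direction as the chain rule does)
  coef <- ifelse(gn > 1e-12, 2 * gp_lambda * (gn - 1) / (n * gn), 0)
  U <- G * coef

  if (nh == 0) {
    # linear critic: g is the weight row itself; only W gets a gradient
    gW <- list(matrix(colSums(U), nrow = 1))
    gb <- list(net$b[[1]] * 0)
    return(list(penalty = penalty, grads = list(W = gW, b = gb)))
  }

  # tangent pass: T[[l]] = tangent after hidden layer l
  Tt <- vector("list", nh + 1)     # Tt[[1]] = T_0 = U
  Aa <- vector("list", nh)
  Tt[[1]] <- U
  for (l in seq_len(nh)) {
    Aa[[l]] <- Tt[[l]] %*% t(net$W[[l]])
    Tt[[l + 1]] <- Aa[[l]] * D[[l]]
  }

  gW <- lapply(net$W, function(w) w * 0)
  gb <- lapply(net$b, function(bb) bb * 0)
  gW[[L]] <- matrix(colSums(Tt[[nh + 1]]), nrow = 1)   # w_out adjoint

  Hbar <- vector("list", nh)
  Tbar <- matrix(net$W[[L]], n, ncol(net$W[[L]]), byrow = TRUE)  # adj of T_L
  for (l in nh:1) {
    Abar <- Tbar * D[[l]]
    Dbar <- Tbar * Aa[[l]]
    hb <- -2 * cache$H[[l + 1]] * Dbar
    if (!is.null(Hbar[[l]])) hb <- hb + Hbar[[l]]
    gW[[l]] <- gW[[l]] + t(Abar) %*% Tt[[l]]
    Tbar <- Abar %*% net$W[[l]]
    Zbar <- hb * D[[l]]
    gW[[l]] <- gW[[l]] + t(Zbar) %*% cache$H[[l]]
    gb[[l]] <- gb[[l]] + colSums(Zbar)
    if (l > 1) {
      down <- Zbar %*% net$W[[l]]
      Hbar[[l - 1]] <- if (is.null(Hbar[[l - 1]])) down else Hbar[[l - 1]] + down
    }
  }
  list(penalty = penalty, grads = list(W = gW, b = gb))
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0),
       vb = lapply(net$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
  }
  for (l in seq_along(net$b)) {
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

add_grads <- function(a, b) {
  list(W = mapply(`+`, a$W, b$W, SIMPLIFY = FALSE),
       b = mapply(`+`, a$b, b$b, SIMPLIFY = FALSE))
}
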