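# LSTM classifier implemented with plain matrix algebra: stacked
# (optionally bidirectional) LSTM layers, a dense sigmoid head on the final
# sequence output, binary cross-entropy with optional class weights, Adam,
# and patience-based early stopping. Gates are ordered (input, forget,
# output, cell); the forget-gate bias is initialized to 1.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_cell_init <- function(input_dim, hidden) {
  lim <- sqrt(6 / (input_dim + hidden))
  Wx <- matrix(stats::runif(4 * hidden * input_dim, -lim, lim),
               4 * hidden, input_dim)
  limh <- sqrt(6 / (2 * hidden))
  Wh <- matrix(stats::runif(4 * hidden * hidden, -limh, limh),
               4 * hidden, hidden)
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1       # forget gate
  list(Wx = Wx, Wh = Wh, b = b)
}

# Forward pass of one direction over a sequence (list of T n x d
# matrices). Returns per-timestep hidden states and the caches BPTT needs.
lstm_cell_forward <- function(Xseq, cell, reverse = FALSE) {
  T_ <- length(Xseq)
  n <- nrow(Xseq[[1]])
  hid <- length(cell$b) / 4
  steps <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  h <- matrix(0, n, hid)
  c_ <- matrix(0, n, hid)
  H <- I <- Fg <- O <- G <- Cp <- Cn <- Hp <- vector("list", T_)
  gi <- seq_len(hid)
  for (t in steps) {
    z <- Xseq[[t]] %*% t(cell$Wx) + h %*% t(cell$Wh) +
      matrix(cell$b, n, 4 * hid, byrow = TRUE)
    i <- sigmoid(z[, gi, drop = FALSE])
    f <- sigmoid(z[, gi + hid, drop = FALSE])
    o <- sigmoid(z[, gi + 2 * hid, drop = FALSE])
    g <- tanh(z[, gi + 3 * hid, drop = FALSE])
    Hp[[t]] <- h; Cp[[t]] <- c_
    c_ <- f * c_ + i * g
    h <- o * tanh(c_)
    H[[t]] <- h; I[[t]] <- i; Fg[[t]] <- f; O[[t]] <- o; G[[t]] <- g
    Cn[[t]] <- c_
  }
  list(H = H, cache = list(I = I, Fg = Fg, O = O, G = G, Cp = Cp, Cn = Cn,
                           Hp = Hp, X = Xseq, steps = steps, hid = hid))
}

# BPTT for one direction. `dH` is the per-timestep upstream gradient on the
# hidden states (list of n x hid matrices, zeros where unused). Returns
# parameter gradients and per-timestep input gradients.
lstm_cell_backward <- function(cell, fw, dH) {
  ca <- fw$cache
  hid <- ca$hid
  T_ <- length(ca$X)
  n <- nrow(ca$X[[1]])
  gWx <- cell$Wx * 0; gWh <- cell$Wh * 0; gb <- cell$b * 0
  dX <- vector("list", T_)
  dh_next <- matrix(0, n, hid)
  dc_next <- matrix(0, n, hid)
  for (t in rev(ca$steps)) {
    dh <- dH[[t]] + dh_next
    tc <- tanh(ca$Cn[[t]])
    do_ <- dh * tc
    dc <- dc_next + dh * ca$O[[t]] * (1 - tc^2)
    di <- dc * ca$G[[t]]
    dg <- dc * ca$I[[t]]
    df <- dc * ca$Cp[[t]]
    dc_next <- dc * ca$Fg[[t]]
    dz <- cbind(di * ca$I[[t]] * (1 - ca$I[[t]]),
                df * ca$Fg[[t]] * (1 - ca$Fg[[t]]),
                do_ * ca$O[[t]] * (1 - ca$O[[t]]),
                dg * (1 - ca$G[[t]]^2))
    gWx <- gWx + t(dz) %*% ca$X[[t]]
    gWh <- gWh + t(dz) %*% ca$Hp[[t]]
    gb <- gb + colSums(dz)
    dX[[t]] <- dz %*% cell$Wx
    dh_next <- dz %*% cell$Wh
  }
  list(Wx = gWx, Wh = gWh, b = gb, dX = dX)
}

lstm_net_init <- function(input_dim, hidden, n_layers, bidirectional) {
  ndir <- if (bidirectional) 2 else 1
  cells <- vector("list", n_layers * ndir)
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1) input_dim else hidden * ndir
    for (dr in seq_len(ndir)) {
      cells[[(l - 1) * ndir + dr]] <- lstm_cell_init(d_in, hidden)
    }
  }
  dense_in <- hidden * ndir
  lim <- sqrt(6 / (dense_in + 1))
  list(cells = cells, dense_W = matrix(stats::runif(dense_in, -lim, lim), 1),
       dense_b = 0, n_layers = n_layers, ndir = ndir, hidden = hidden)
}

# Full forward: returns probability vector and caches for backward.
lstm_net_forward <- function(net, Xseq) {
  T_ <- length(Xseq)
  n <- nrow(Xseq[[1]])
  inputs <- Xseq
  fws <- vector("list", net$n_layers * net$ndir)
  for (l in seq_len(net$n_layers)) {
    outs <- vector("list", net$ndir)
    for (dr in seq_len(net$ndir)) {
      ix <- (l - 1) * net$ndir + dr
      fws[[ix]] <- lstm_cell_forward(inputs, net$cells[[ix]], reverse = dr == 2)
      outs[[dr]] <- fws[[ix]]$H
    }
    inputs <- lapply(seq_len(T_), function(t)
      do.call(cbind, lapply(outs, `[[`, t)))
  }
  # sequence summary: forward direction's last state, backward direction's
  # state at t = 1 (its final processing step)
  top <- (net$n_layers - 1) * net$ndir
  feat <- fws[[top + 1]]$H[[T_]]
  if (net$ndir == 2) feat <- cbind(feat, fws[[top + 2]]$H[[1]])
  logits <- feat %*% t(net$dense_W) + net$dense_b
  list(prob = as.vector(sigmoid(logits)), feat = feat, fws = fws, T_ = T_, n = n)
}

# Full backward from d loss / d logits (length-n vector).
lstm_net_backward <- function(net, fwd, dlogit) {
  T_ <- fwd$T_
  n <- fwd$n
  hid <- net$hidden
  gdW <- dlogit %*% fwd$feat            # 1 x dense_in
  gdb <- sum(dlogit)
  dfeat <- outer(dlogit, as.vector(net$dense_W))
  zero <- function() lapply(seq_len(T_), function(t) matrix(0, n, hid))
  grads <- vector("list", length(net$cells))
  # upstream gradients on the top layer's per-direction hidden sequences
  dH_layer <- vector("list", net$ndir)
  for (dr in seq_len(net$ndir)) dH_layer[[dr]] <- zero()
  dH_layer[[1]][[T_]] <- dfeat[, seq_len(hid), drop = FALSE]
  if (net$ndir == 2) dH_layer[[2]][[1]] <- dfeat[, hid + seq_len(hid), drop = FALSE]
  for (l in net$n_layers:1) {
    dX_sum <- NULL
    for (dr in seq_len(net$ndir)) {
      ix <- (l - 1) * net$ndir + dr
      bk <- lstm_cell_backward(net$cells[[ix]], fwd$fws[[ix]], dH_layer[[dr]])
      grads[[ix]] <- bk[c("Wx", "Wh", "b")]
      dX_sum <- if (is.null(dX_sum)) bk$dX else
        lapply(seq_len(T_), function(t) dX_sum[[t]] + bk$dX[[t]])
    }
    if (l > 1) {
      # split the summed input gradient into the lower layer's directions
      dH_layer <- vector("list", net$ndir)
      for (dr in seq_len(net$ndir)) {
        cols <- (dr - 1) * hid + seq_len(hid)
        dH_layer[[dr]] <- lapply(dX_sum, function(m) m[, cols, drop = FALSE])
      }
    }
  }
  list(cells = grads, dense_W = gdW, dense_b = gdb)
}

# Pack network parameters into the flat {W, b} lists the Adam helper
# expects.
lstm_pack <- function(net) {
  W <- list(); b <- list()
  for (cell in net$cells) {
    W <- c(W, list(cell$Wx, cell$Wh))
    b <- c(b, list(cell$b))
  }
  W <- c(W, list(net$dense_W))
  b <- c(b, list(net$dense_b))
  list(W = W, b = b)
}

lstm_unpack <- function(net, packed) {
  k <- 1
  for (i in seq_along(net$cells)) {
    net$cells[[i]]$Wx <- packed$W[[2 * i - 1]]
    net$cells[[i]]$Wh <- packed$W[[2 * i]]
    net$cells[[i]]$b <- packed$b[[i]]
  }
  net$dense_W <- packed$W[[length(packed$W)]]
  net$dense_b <- packed$b[[length(packed$b)]]
  net
}

lstm_pack_grads <- function(net, grads) {
  W <- list(); b <- list()
  for (g in grads$cells) {
    W <- c(W, list(g$Wx, g$Wh))
    b <- c(b, list(g$b))
  }
  W <- c(W, list(grads$dense_W))
  b <- c(b, list(grads$dense_b))
  list(W = W, b = b)
}

# Reshape a feature matrix (n x (T*d)) into a list of T n x d matrices,
# channel-major: columns are assumed ordered ch1 features, ch2 features, ...
matrix_to_seq <- function(x, timesteps) {
  d <- ncol(x) / timesteps
  stopifnot(d == round(d))
  lapply(seq_len(timesteps), function(t)
    x[, (t - 1) * d + seq_len(d), drop = FALSE])
}
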