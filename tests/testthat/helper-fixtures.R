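# Shared fixtures, built in code at load time.

# Small imbalanced two-class Gaussian table: 100 majority at 0, 12 minority
# at (2, 2), 10 patients.
toy_table <- simulate_feature_dataset(feature_sim_config(
  n_majority = 100, n_minority = 12, n_features = 2,
  minority_mean = c(2, 2), n_patients = 10, seed = 42))

# Tiny 3-channel EEG dataset (4 patients x 5 epochs).
tiny_eeg <- simulate_eeg_dataset(sim_config(
  n_patients = 4, epochs_per_patient = 5, n_channels = 3,
  seizure_fraction = 0.2, seed = 7))

# A linearly separable 200-row table: class means 6 SD apart.
separable_table <- simulate_feature_dataset(feature_sim_config(
  n_majority = 100, n_minority = 100, n_features = 8,
  majority_mean = rep(0, 8), minority_mean = rep(6, 8),
  n_patients = 20, seed = 11))

sine_wave <- function(freq, fs = 250, seconds = 4, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq_len(fs * seconds) / fs + phase)
}

# Brute-force confusion-count metrics used as the oracle for
# compute_metrics.
brute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(y_true)) {
    pred <- if (y_prob[i] >= threshold) 1 else 0
    if (pred == 1 && y_true[i] == 1) tp <- tp + 1
    if (pred == 1 && y_true[i] == 0) fp <- fp + 1
    if (pred == 0 && y_true[i] == 0) tn <- tn + 1
    if (pred == 0 && y_true[i] == 1) fn <- fn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(accuracy = (tp + tn) / length(y_true),
    recall = rec,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    precision = prec,
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

# Brute-force SMOTE reference: identical random-stream order (base row,
# neighbor slot, weight), neighbors by an explicit double loop.
brute_smote <- function(table, k, n_target, seed) {
  x <- eegaug::feature_matrix(table)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd); sdv[sdv < .Machine$double.eps] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  min_idx <- which(table$label == 1)
  zm <- z[min_idx, , drop = FALSE]
  xm <- x[min_idx, , drop = FALSE]
  nm <- length(min_idx)
  nn <- matrix(0L, nm, k)
  for (i in seq_len(nm)) {
    d <- numeric(nm)
    for (j in seq_len(nm)) d[j] <- sqrt(sum((zm[i, ] - zm[j, ])^2))
    d[i] <- Inf
    nn[i, ] <- order(d, seq_len(nm))[seq_len(k)]
  }
  set.seed(seed)
  out <- matrix(0, n_target, ncol(x))
  for (s in seq_len(n_target)) {
    i <- sample.int(nm, 1)
    j <- nn[i, sample.int(k, 1)]
    lam <- runif(1)
    out[s, ] <- xm[i, ] + lam * (xm[j, ] - xm[i, ])
  }
  out
}

# Brute-force ADASYN reference implementing the density-ratio allocation
# and interpolation directly.
brute_adasyn <- function(table, K, G, seed) {
  x <- eegaug::feature_matrix(table)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd); sdv[sdv < .Machine$double.eps] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  min_idx <- which(table$label == 1)
  n <- nrow(x)
  r <- numeric(length(min_idx))
  for (ii in seq_along(min_idx)) {
    i <- min_idx[ii]
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((z[i, ] - z[j, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(K)]
    r[ii] <- sum(table$label[nb] == 0) / K
  }
  r_hat <- if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)
  quota <- G * r_hat
  g <- floor(quota)
  rem <- G - sum(g)
  if (rem > 0) {
    ord <- order(quota - g, decreasing = TRUE)
    g[ord[seq_len(rem)]] <- g[ord[seq_len(rem)]] + 1
  }
  zm <- z[min_idx, , drop = FALSE]
  xm <- x[min_idx, , drop = FALSE]
  nm <- length(min_idx)
  k_eff <- min(K, nm - 1)
  nn <- matrix(0L, nm, k_eff)
  for (i in seq_len(nm)) {
    d <- numeric(nm)
    for (j in seq_len(nm)) d[j] <- sqrt(sum((zm[i, ] - zm[j, ])^2))
    d[i] <- Inf
    nn[i, ] <- order(d, seq_len(nm))[seq_len(k_eff)]
  }
  set.seed(seed)
  out <- matrix(0, G, ncol(x))
  s <- 0L
  for (i in seq_len(nm)) {
    for (rep_ in seq_len(g[i])) {
      s <- s + 1L
      j <- nn[i, sample.int(k_eff, 1)]
      lam <- runif(1)
      out[s, ] <- xm[i, ] + lam * (xm[j, ] - xm[i, ])
    }
  }
  list(g = g, r_hat = r_hat, synth = out)
}
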