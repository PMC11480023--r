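#' Quantile-quantile comparison of one feature
#'
#' Pairs the empirical quantiles of the real and synthetic samples at the
#' probability grid `(i - 0.5) / n_quantiles` (quantiles by linear
#' interpolation of order statistics). If the two distributions match, the
#' points fall on the diagonal; the maximum absolute deviation from it is
#' the summary statistic. Shifting the synthetic sample by `c` shifts the
#' deviation to exactly `|c|`.
#'
#' @param real,synthetic numeric vectors (non-empty)
#' @param n_quantiles number of probability points (default 100)
#' @return list of class `qq_result`: `table` (prob, q_real, q_synth) and
#'   `max_abs_deviation`
#' @export
qq_compare <- function(real, synthetic, n_quantiles = 100) {
  if (!length(real) || !length(synthetic)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  p <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  qr <- stats::quantile(real, p, names = FALSE, type = 7)
  qs <- stats::quantile(synthetic, p, names = FALSE, type = 7)
  structure(list(table = data.frame(prob = p, q_real = qr, q_synth = qs),
                 max_abs_deviation = max(abs(qr - qs))),
            class = "qq_result")
}

#' Per-feature QQ deviations between two tables
#'
#' Runs [qq_compare()] on every shared feature column and summarizes.
#'
#' @param real,synthetic feature tables or matrices with matching columns
#' @param n_quantiles probability grid size
#' @return data.frame with columns `feature`, `max_abs_deviation`, plus a
#'   `pooled_mean` attribute (mean deviation over features)
#' @export
qq_compare_table <- function(real, synthetic, n_quantiles = 100) {
  xr <- if (is.data.frame(real)) feature_matrix(real) else as.matrix(real)
  xs <- if (is.data.frame(synthetic)) feature_matrix(synthetic) else
    as.matrix(synthetic)
  dev <- vapply(seq_len(ncol(xr)), function(j)
    qq_compare(xr[, j], xs[, j], n_quantiles)$max_abs_deviation, numeric(1))
  out <- data.frame(feature = colnames(xr) %||% sprintf("f%d", seq_len(ncol(xr))),
                    max_abs_deviation = dev)
  attr(out, "pooled_mean") <- mean(dev)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Energy distance between two sample matrices:
# 2 E||X-Y|| - E||X-X'|| - E||Y-Y'||, all expectations as V-statistics
# (full pair means), so identical samples give exactly zero.
energy_distance_mat <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  2 * mean(pair_dists(x, y)) - mean(pair_dists(x, x)) -
    mean(pair_dists(y, y))
}

pair_dists <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Multivariate energy distance between real and synthetic rows
#'
#' Scalar fidelity measure: symmetric, non-negative, and zero iff the two
#' empirical distributions coincide. Computed on the raw (unstandardized)
#' values; standardize beforehand if features live on different scales.
#'
#' @param real,synthetic feature tables or numeric matrices with equal
#'   column counts
#' @return non-negative scalar
#' @export
distribution_distance <- function(real, synthetic) {
  xr <- if (is.data.frame(real)) feature_matrix(real) else as.matrix(real)
  xs <- if (is.data.frame(synthetic)) feature_matrix(synthetic) else
    as.matrix(synthetic)
  if (!nrow(xr) || !nrow(xs)) stop("both samples must be non-empty", call. = FALSE)
  if (ncol(xr) != ncol(xs)) {
    stop("real and synthetic have different dimensionality", call. = FALSE)
  }
  energy_distance_mat(xr, xs)
}

#' Project real and synthetic rows to 2-D for visual fidelity checks
#'
#' Standardizes the combined rows, fits the chosen embedding on them, and
#' returns one coordinate pair per input row with its origin label.
#' Methods: truncated SVD (`tsvd`), RBF kernel PCA (`kpca`, via kernlab),
#' FastICA (`fastica`, symmetric decorrelation, logcosh contrast), and
#' exact t-SNE (`tsne`, perplexity 30) — quadratic in the row count, meant
#' for diagnostic sample sizes.
#'
#' @param real,synthetic feature tables or matrices with equal columns
#' @param method one of `"tsvd"`, `"kpca"`, `"fastica"`, `"tsne"`
#' @param seed integer seed (stochastic methods; recorded in the result)
#' @param perplexity t-SNE perplexity (default 30)
#' @return data.frame of class `projection_result` with columns `dim1`,
#'   `dim2`, `origin`; attributes `method` and `seed`
#' @export
project_2d <- function(real, synthetic,
                       method = c("tsvd", "kpca", "fastica", "tsne"),
                       seed = 1L, perplexity = 30) {
  method <- match.arg(method)
  xr <- if (is.data.frame(real)) feature_matrix(real) else as.matrix(real)
  xs <- if (is.data.frame(synthetic)) feature_matrix(synthetic) else
    as.matrix(synthetic)
  x <- rbind(xr, xs)
  if (nrow(x) < 3) stop("need at least 3 combined rows", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  z <- apply_scaler(x, fit_scaler(x))
  coords <- with_seed(seed, switch(
    method,
    tsvd = {
      s <- svd(z, nu = 2, nv = 2)
      if (s$d[2] < 1e-12) stop("rank-deficient input for tsvd", call. = FALSE)
      s$u %*% diag(s$d[1:2])
    },
    kpca = {
      kp <- kernlab::kpca(z, kernel = "rbfdot", features = 2)
      kernlab::rotated(kp)
    },
    fastica = fastica_2d(z),
    tsne = tsne_2d(z, perplexity)
  ))
  out <- data.frame(dim1 = coords[, 1], dim2 = coords[, 2],
                    origin = rep(c("real", "synthetic"), c(nrow(xr), nrow(xs))))
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  class(out) <- c("projection_result", "data.frame")
  out
}

# Symmetric FastICA with the logcosh contrast, 2 components.
fastica_2d <- function(z, max_iter = 200, tol = 1e-6) {
  n <- nrow(z)
  zc <- scale(z, scale = FALSE)
  sv <- svd(zc)
  keep <- sv$d > 1e-10 * sv$d[1]
  if (sum(keep) < 2) stop("rank-deficient input for fastica", call. = FALSE)
  K <- sv$v[, keep, drop = FALSE] %*% diag(1 / sv$d[keep]) * sqrt(n)
  Xw <- zc %*% K                      # whitened, n x r
  r <- ncol(Xw)
  W <- matrix(stats::rnorm(2 * r), 2, r)
  sym_decorr <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)                    # (W W^T)^{-1/2} W
  }
  W <- sym_decorr(W)
  for (it in seq_len(max_iter)) {
    WX <- Xw %*% t(W)                 # n x 2
    gwx <- tanh(WX)
    W1 <- t(gwx) %*% Xw / n - diag(colMeans(1 - gwx^2)) %*% W
    W1 <- sym_decorr(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  Xw %*% t(W)
}

# Exact t-SNE (O(n^2)); standard perplexity calibration, early
# exaggeration, momentum gradient descent.
tsne_2d <- function(z, perplexity = 30, n_iter = 400, eta = 100) {
  n <- nrow(z)
  perplexity <- min(perplexity, (n - 1) / 3)
  d2 <- as.matrix(stats::dist(z))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < 1e-300) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  for (it in seq_len(n_iter)) {
    Pn <- if (it <= 100) P * 4 else P      # early exaggeration
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pn - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    inc <- mom * inc - eta * grad
    Y <- Y + inc
    Y <- scale(Y, scale = FALSE)
  }
  Y
}
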