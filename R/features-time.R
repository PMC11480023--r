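#' Sample moments of a signal
#'
#' Skewness and kurtosis are the population-moment estimators
#' (`m3 / m2^(3/2)` and excess `m4 / m2^2 - 3`); variance is the unbiased
#' sample variance (n - 1 denominator). A constant signal returns
#' `(0, 0, 0)` by the degenerate rule.
#'
#' @param signal numeric samples
#' @return named numeric vector `(skewness, variance, kurtosis)`
#' @export
extract_moments <- function(signal) {
  if (length(signal) < 2) stop("need at least 2 samples", call. = FALSE)
  v <- stats::var(signal)
  if (v < .Machine$double.eps) {
    return(c(skewness = 0, variance = 0, kurtosis = 0))
  }
  m <- mean(signal)
  m2 <- mean((signal - m)^2)
  c(skewness = mean((signal - m)^3) / m2^1.5,
    variance = v,
    kurtosis = mean((signal - m)^4) / m2^2 - 3)
}

#' Hjorth parameters
#'
#' Activity is the signal variance; mobility is
#' `sqrt(var(diff(x)) / var(x))`, a dominant-frequency proxy; complexity is
#' `mobility(diff(x)) / mobility(x)`, a bandwidth proxy. Constant signals
#' return `(0, 0, 0)` by the degenerate rule. Returned in the order
#' mobility, activity, complexity.
#'
#' @param signal numeric samples (length >= 3)
#' @return named numeric vector `(hjorth_mobility, hjorth_activity,
#'   hjorth_complexity)`
#' @export
extract_hjorth <- function(signal) {
  if (length(signal) < 3) stop("need at least 3 samples", call. = FALSE)
  v0 <- stats::var(signal)
  if (v0 < .Machine$double.eps) {
    return(c(hjorth_mobility = 0, hjorth_activity = 0, hjorth_complexity = 0))
  }
  d1 <- diff(signal)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 < .Machine$double.eps) 0 else sqrt(v2 / v1) / mob
  c(hjorth_mobility = mob, hjorth_activity = v0, hjorth_complexity = comp)
}

#' Sample entropy and multi-order permutation entropy
#'
#' One sample-entropy value (embedding `sampen_m`, tolerance
#' `sampen_r * sd(signal)`) followed by permutation entropies at the four
#' configured embedding orders (delay 1), each normalized by `log(order!)`
#' so values lie in [0, 1].
#'
#' @param signal numeric samples
#' @param config a [feature_config()]
#' @return named numeric vector of 5 values
#' @export
extract_entropies <- function(signal, config = feature_config()) {
  min_len <- max(config$perment_orders) + 1
  if (length(signal) < min_len) {
    stop(sprintf("signal too short for entropy features: need >= %d samples",
                 min_len), call. = FALSE)
  }
  s <- stats::sd(signal)
  se <- if (s < .Machine$double.eps) 0 else {
    v <- sample_entropy(signal, m = config$sampen_m, r = config$sampen_r * s)
    if (!is.finite(v)) 0 else v
  }
  pe <- vapply(config$perment_orders, function(m)
    permutation_entropy(signal, m), numeric(1))
  stats::setNames(c(se, pe),
                  c("sampen", sprintf("perment_o%d", config$perment_orders)))
}

#' Sample entropy
#'
#' Negative log of the conditional probability that template vectors close
#' (Chebyshev distance <= `r`) at embedding dimension `m` remain close at
#' `m + 1`; self-matches excluded. Vectorized over the full
#' template-distance matrix. Returns `Inf` when no template pair matches at
#' `m + 1`.
#'
#' @param signal numeric samples
#' @param m embedding dimension (default 2)
#' @param r tolerance on the original signal scale
#' @return non-negative scalar (possibly `Inf`)
#' @export
sample_entropy <- function(signal, m = 2, r) {
  n <- length(signal)
  if (n < m + 2) stop("signal too short for sample entropy", call. = FALSE)
  M <- abs(outer(signal, signal, "-")) <= r
  idx <- seq_len(n - m)
  B <- M[idx, idx, drop = FALSE]
  for (k in seq_len(m - 1)) B <- B & M[idx + k, idx + k, drop = FALSE]
  A <- B & M[idx + m, idx + m, drop = FALSE]
  nb <- sum(B) - length(idx)            # drop self-matches on the diagonal
  na <- sum(A) - length(idx)
  if (nb <= 0 || na <= 0) return(Inf)
  -log(na / nb)
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution at embedding order
#' `m` and delay 1, normalized by `log(m!)`. A strictly monotone signal has
#' a single pattern and entropy 0; white noise approaches 1.
#'
#' @param signal numeric samples
#' @param m embedding order
#' @return value in [0, 1]
#' @export
permutation_entropy <- function(signal, m) {
  n <- length(signal) - m + 1
  if (n < 1) stop("signal shorter than embedding order", call. = FALSE)
  # encode each window's ordinal pattern by its inversion table (earlier
  # equal values count as smaller, matching first-occurrence rank ties)
  emb <- lapply(seq_len(m), function(k) signal[(k - 1) + seq_len(n)])
  code <- numeric(n)
  for (k in 2:m) {
    ck <- numeric(n)
    for (j in seq_len(k - 1)) ck <- ck + (emb[[j]] > emb[[k]])
    code <- code + ck * factorial(k - 1)
  }
  pr <- tabulate(code + 1, nbins = factorial(m)) / n
  pr <- pr[pr > 0]
  0 - sum(pr * log(pr)) / log(factorial(m))  # 0 - x avoids IEEE negative zero
}

#' Successive decomposition index, mean energy and cumulative energy
#'
#' The successive decomposition index condenses the signal by repeated
#' pairwise Haar-style averaging of its absolute values (each pass halves
#' the length, scaling by 1/sqrt(2)) until a single coefficient remains;
#' the index is `log1p` of that coefficient — a computationally light
#' amplitude/energy summary that rises sharply during rhythmic
#' high-amplitude activity. Mean energy is the mean squared sample and
#' cumulative energy the final value of the running sum of squared samples
#' (so cumulative = n * mean).
#'
#' @param signal numeric samples (length >= 2)
#' @return named numeric vector `(sdi, mean_energy, cum_energy)`
#' @export
extract_sdi_energy <- function(signal) {
  if (length(signal) < 2) stop("need at least 2 samples", call. = FALSE)
  a <- abs(signal)
  while (length(a) > 1) {
    if (length(a) %% 2 == 1) a <- c(a, a[length(a)])
    a <- (a[seq(1, length(a), 2)] + a[seq(2, length(a), 2)]) / sqrt(2)
  }
  e <- signal^2
  c(sdi = log1p(a), mean_energy = mean(e), cum_energy = sum(e))
}
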