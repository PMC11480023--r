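# Daubechies-4 (8-tap) analysis filters, low-pass h and high-pass g.
DB4_LO <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965)
DB4_HI <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
            -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
            -0.0328830116668852, -0.010597401785069032)

# One level of the periodized orthogonal DWT: circularly convolve with each
# filter and downsample by 2. Requires even length; the transform is
# orthonormal, so energy is conserved exactly across levels.
dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  L <- length(DB4_LO)
  # y[k] = sum_m h[m] * x[(2k + m - 2) mod n + 1], k = 1..n/2
  idx <- outer(seq(0, n - 2, by = 2), seq_len(L) - 1L, "+") %% n + 1L
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = as.vector(xm %*% DB4_LO), detail = as.vector(xm %*% DB4_HI))
}

# Pad with zeros to the next multiple of 2^levels. Zero padding leaves the
# signal energy unchanged, so Parseval holds on the padded vector.
pad_pow2 <- function(x, levels) {
  block <- 2^levels
  rem <- length(x) %% block
  if (rem != 0) x <- c(x, numeric(block - rem))
  x
}

#' Multi-level discrete wavelet transform (db4, periodized)
#'
#' @param x numeric signal; zero-padded to a multiple of `2^levels`
#' @param levels decomposition depth
#' @return list with `details` (list of detail coefficient vectors, level 1
#'   = finest) and `approx` (deepest approximation)
#' @export
dwt_db4 <- function(x, levels = 5) {
  x <- pad_pow2(x, levels)
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    st <- dwt_step(a)
    details[[l]] <- st$detail
    a <- st$approx
  }
  list(details = details, approx = a)
}

# Full wavelet packet decomposition to `depth`; returns the 2^depth terminal
# node coefficient vectors in natural (filter-bank) order.
wpd_db4 <- function(x, depth = 3) {
  nodes <- list(pad_pow2(x, depth))
  for (l in seq_len(depth)) {
    nxt <- vector("list", 2 * length(nodes))
    for (i in seq_along(nodes)) {
      st <- dwt_step(nodes[[i]])
      nxt[[2 * i - 1]] <- st$approx
      nxt[[2 * i]] <- st$detail
    }
    nodes <- nxt
  }
  nodes
}

#' Wavelet-domain features of a channel
#'
#' Eight values from db4 decompositions: the Shannon entropy of the
#' normalized energy distribution over all 5-level DWT coefficients
#' (details + deepest approximation); the log-energy entropy
#' (`sum(log(E_node))`) and Shannon entropy of the 8 terminal-node energies
#' of a depth-3 wavelet packet decomposition; and the percentage of total
#' epoch energy captured by each of the 5 DWT detail levels (the remaining
#' share sits in the deepest approximation band, so the five percentages sum
#' to <= 100). Constant signals return zeros by the degenerate rule.
#'
#' @param signal numeric samples
#' @param config a [feature_config()]
#' @return named numeric vector of 8 values
#' @export
extract_wavelet_features <- function(signal, config = feature_config()) {
  lv <- config$dwt_levels
  nm <- c("dwt_shannon", "wpd_logenergy", "wpd_shannon",
          sprintf("wav_energy_pct_l%d", seq_len(lv)))
  if (length(signal) < 2^lv) {
    stop(sprintf("signal too short for %d-level DWT: need >= %d samples",
                 lv, 2^lv), call. = FALSE)
  }
  if (stats::sd(signal) < .Machine$double.eps) {
    warning("constant signal: wavelet features set to 0 by degenerate rule")
    return(stats::setNames(numeric(3 + lv), nm))
  }
  dec <- dwt_db4(signal, lv)
  all_coef <- c(unlist(dec$details), dec$approx)
  dwt_shannon <- shannon_entropy_norm(all_coef^2)

  nodes <- wpd_db4(signal, config$wpd_depth)
  node_e <- vapply(nodes, function(z) sum(z^2), numeric(1))
  wpd_logenergy <- sum(log(pmax(node_e, .Machine$double.xmin)))
  wpd_shannon <- shannon_entropy_norm(node_e)

  total_e <- sum(all_coef^2)  # equals padded-signal energy (orthonormal)
  pct <- vapply(dec$details, function(d) 100 * sum(d^2) / total_e, numeric(1))
  stats::setNames(c(dwt_shannon, wpd_logenergy, wpd_shannon, pct), nm)
}
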