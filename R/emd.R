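#' Empirical mode decomposition by iterative sifting
#'
#' Classic EMD: at each sifting pass the upper and lower envelopes are cubic
#' splines through the local maxima and minima (endpoints included as
#' extrema), and the envelope mean is subtracted. A candidate is accepted as
#' an intrinsic mode function (IMF) when the normalized squared change
#' between passes drops below `sd_stop` or `max_sift` passes are reached.
#' Extraction stops when the residual has fewer than two maxima or minima,
#' or `max_imfs` IMFs have been extracted.
#'
#' @param signal numeric samples (non-constant)
#' @param max_imfs maximum number of IMFs to extract (default 8)
#' @param sd_stop sifting stop criterion (default 0.3)
#' @param max_sift maximum sifting passes per IMF (default 50)
#' @return list with `imfs` (matrix, one IMF per row; may have 0 rows) and
#'   `residual`
#' @export
emd_decompose <- function(signal, max_imfs = 8, sd_stop = 0.3, max_sift = 50) {
  n <- length(signal)
  imfs <- list()
  resid <- signal
  for (k in seq_len(max_imfs)) {
    ext <- find_extrema(resid)
    if (length(ext$n_max) < 1 || length(ext$n_min) < 1) break
    h <- resid
    for (s in seq_len(max_sift)) {
      ext <- find_extrema(h)
      if (length(ext$n_max) < 1 || length(ext$n_min) < 1) break
      upper <- stats::spline(ext$max, h[ext$max], xout = seq_len(n))$y
      lower <- stats::spline(ext$min, h[ext$min], xout = seq_len(n))$y
      m <- (upper + lower) / 2
      h_new <- h - m
      crit <- sum(m^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (crit < sd_stop^2) break
    }
    imfs[[k]] <- h
    resid <- resid - h
  }
  list(imfs = if (length(imfs)) do.call(rbind, imfs) else
         matrix(numeric(0), 0, n),
       residual = resid)
}

# Indices of interior local maxima and minima; `max`/`min` have the
# endpoints appended so the envelope splines cover the full support, while
# `n_max`/`n_min` count interior extrema only (the sifting stop criterion).
find_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  # collapse flat runs so plateaus count once
  idx <- which(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)]) + 1L
  maxima <- idx[x[idx] > x[idx - 1L]]
  minima <- idx[x[idx] < x[idx - 1L]]
  list(max = unique(c(1L, maxima, n)), min = unique(c(1L, minima, n)),
       n_max = maxima, n_min = minima)
}

#' Statistics of the first intrinsic mode function
#'
#' Decomposes the channel with [emd_decompose()] and returns six statistics
#' of the first IMF: energy (sum of squares), normalized spectral entropy,
#' mean, standard deviation, second central moment, and skewness. If no IMF
#' can be extracted the degenerate rule applies: six zeros with a warning.
#'
#' @param signal numeric samples
#' @param fs sampling rate in Hz
#' @param config a [feature_config()]
#' @return named numeric vector of 6 values
#' @export
extract_emd_features <- function(signal, fs, config = feature_config()) {
  nm <- c("emd_energy", "emd_spec_entropy", "emd_mean", "emd_sd",
          "emd_moment", "emd_skewness")
  dec <- emd_decompose(signal, max_imfs = config$emd_max_imfs)
  if (nrow(dec$imfs) == 0) {
    warning("EMD produced no IMFs: features set to 0 by degenerate rule")
    return(stats::setNames(numeric(6), nm))
  }
  imf <- dec$imfs[1, ]
  m <- mean(imf)
  m2 <- mean((imf - m)^2)
  skew <- if (m2 < .Machine$double.eps) 0 else mean((imf - m)^3) / m2^1.5
  sp <- welch_psd(imf, fs, config$psd_seg_seconds, config$psd_overlap)
  stats::setNames(
    c(sum(imf^2), shannon_entropy_norm(sp$psd), m, stats::sd(imf), m2, skew),
    nm)
}
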