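#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with Hann-windowed segments. One-sided
#' density normalized so that summing `psd * df` recovers the mean-square
#' power of the (windowed) signal.
#'
#' @param x numeric signal
#' @param fs sampling rate in Hz
#' @param seg_seconds segment length in seconds (default 1)
#' @param overlap fractional overlap between segments (default 0.5)
#' @return list with `freq` (Hz) and `psd` (power per Hz)
#' @export
welch_psd <- function(x, fs, seg_seconds = 1, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, round(fs * seg_seconds))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / nseg))  # periodic Hann
  u <- sum(w^2)                                            # window power norm
  nfreq <- floor(nseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:nfreq])^2 / (u * fs)
    # one-sided: double everything but DC (and Nyquist if nseg even)
    if (nseg %% 2 == 0) {
      sp[2:(nfreq - 1)] <- 2 * sp[2:(nfreq - 1)]
    } else {
      sp[2:nfreq] <- 2 * sp[2:nfreq]
    }
    acc <- acc + sp
  }
  list(freq = seq(0, nfreq - 1) * fs / nseg, psd = acc / length(starts))
}

#' Band-power features from a single channel
#'
#' For each of the five configured bands returns the average PSD (mean
#' density over in-band bins), the absolute power (integrated density), and
#' the relative power (absolute / total over the five bands). Relative
#' powers sum to 1. An all-zero or constant signal triggers the degenerate
#' rule: all 15 values are 0 and a warning is logged.
#'
#' @param signal numeric samples of one channel
#' @param fs sampling rate in Hz
#' @param config a [feature_config()]
#' @return named numeric vector of 15 values
#'   (`psd_avg_*`, `psd_abs_*`, `psd_rel_*` per band)
#' @export
extract_band_powers <- function(signal, fs, config = feature_config()) {
  bands <- config$bands
  nm <- c(sprintf("psd_avg_%s", bands$band),
          sprintf("psd_abs_%s", bands$band),
          sprintf("psd_rel_%s", bands$band))
  if (stats::sd(signal) < .Machine$double.eps) {
    warning("constant signal: band powers set to 0 by degenerate rule")
    return(stats::setNames(numeric(15), nm))
  }
  min_len <- 2 * fs / bands$lo[1]
  if (length(signal) < min_len) {
    stop(sprintf("signal too short for band-power estimation: need >= %d samples (two cycles of %.2g Hz)",
                 ceiling(min_len), bands$lo[1]), call. = FALSE)
  }
  p <- welch_psd(signal, fs, config$psd_seg_seconds, config$psd_overlap)
  df <- p$freq[2] - p$freq[1]
  avg <- abs_ <- numeric(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sel <- p$freq >= bands$lo[b] & p$freq <= bands$hi[b]
    avg[b] <- mean(p$psd[sel])
    abs_[b] <- sum(p$psd[sel]) * df
  }
  rel <- abs_ / sum(abs_)
  stats::setNames(c(avg, abs_, rel), nm)
}

#' Normalized Shannon spectral entropy of a PSD
#'
#' Shannon entropy of the PSD normalized to a probability distribution over
#' the analyzed range (lower delta edge to upper gamma edge), divided by
#' log of the number of bins so the value lies in [0, 1].
#'
#' @inheritParams extract_band_powers
#' @return single numeric value in [0, 1]
#' @export
extract_spectral_entropy <- function(signal, fs, config = feature_config()) {
  if (stats::sd(signal) < .Machine$double.eps) {
    warning("constant signal: spectral entropy set to 0 by degenerate rule")
    return(c(spec_entropy_psd = 0))
  }
  p <- welch_psd(signal, fs, config$psd_seg_seconds, config$psd_overlap)
  sel <- p$freq >= min(config$bands$lo) & p$freq <= max(config$bands$hi)
  c(spec_entropy_psd = shannon_entropy_norm(p$psd[sel]))
}

# Normalized Shannon entropy of a non-negative weight vector.
shannon_entropy_norm <- function(w) {
  w <- w[w > 0]
  if (length(w) <= 1) return(0)
  pr <- w / sum(w)
  -sum(pr * log(pr)) / log(length(pr))
}
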