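#' Configuration for the synthetic EEG simulator
#'
#' Describes a patient-structured, class-imbalanced collection of multichannel
#' EEG epochs. Defaults mirror the shape of a clinical seizure corpus: a
#' 19-channel 10/20 montage sampled at 250 Hz with roughly 6% of epochs
#' containing seizure activity.
#'
#' @param n_patients number of simulated patients
#' @param epochs_per_patient epochs recorded per patient
#' @param n_channels number of EEG channels (default 19)
#' @param fs sampling rate in Hz (>= 250)
#' @param epoch_seconds epoch duration in seconds; the default 4 s gives the
#'   0.5 Hz lower delta edge two full cycles per epoch
#' @param seizure_fraction proportion of epochs labeled seizure, in [0, 1]
#' @param patient_effect_sd SD of the per-patient log-amplitude factor
#' @param noise_sd SD of the additive white noise
#' @param seizure_freq fundamental frequency (Hz) of the injected rhythmic
#'   seizure burst (default 3 Hz, spike-wave-like)
#' @param seed integer seed governing all randomness in the simulation
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_patients = 20, epochs_per_patient = 50,
                       n_channels = 19, fs = 250, epoch_seconds = 4,
                       seizure_fraction = 0.06, patient_effect_sd = 0.2,
                       noise_sd = 0.5, seizure_freq = 3, seed = 1L) {
  stopifnot_count(n_patients, "n_patients")
  stopifnot_count(epochs_per_patient, "epochs_per_patient")
  stopifnot_count(n_channels, "n_channels")
  if (fs < 250) stop("`fs` must be at least 250 Hz", call. = FALSE)
  if (epoch_seconds <= 0) stop("`epoch_seconds` must be positive", call. = FALSE)
  if (seizure_fraction < 0 || seizure_fraction > 1) {
    stop("`seizure_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    epochs_per_patient = as.integer(epochs_per_patient),
    n_channels = as.integer(n_channels), fs = fs,
    epoch_seconds = epoch_seconds, seizure_fraction = seizure_fraction,
    patient_effect_sd = patient_effect_sd, noise_sd = noise_sd,
    seizure_freq = seizure_freq, seed = as.integer(seed)
  ), class = "sim_config")
}

# Five canonical EEG rhythms used for the background generator. Amplitudes
# fall off with frequency so the composite spectrum is pink-ish.
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(0.5, 4, 8, 13, 30),
    hi = c(4, 8, 13, 30, 45),
    amp = c(2.0, 1.2, 1.0, 0.5, 0.25)
  )
}

# One channel of background activity: five band-limited oscillators with a
# random in-band frequency, phase and strength per epoch (band power in
# resting EEG fluctuates several-fold with vigilance state), plus white
# noise.
simulate_background_channel <- function(n, fs, noise_sd) {
  t <- seq_len(n) / fs
  bands <- eeg_bands()
  x <- numeric(n)
  for (b in seq_len(nrow(bands))) {
    f <- stats::runif(1, bands$lo[b], bands$hi[b])
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- bands$amp[b] * stats::runif(1, 0.4, 1.6)
    x <- x + amp * sin(2 * pi * f * t + ph)
  }
  x + stats::rnorm(n, sd = noise_sd)
}

#' Simulate a patient-structured imbalanced EEG dataset
#'
#' Background epochs are sums of five band-limited oscillators (delta through
#' gamma) with random phases plus white noise, all scaled by a per-patient
#' amplitude factor. Seizure epochs additionally carry a high-amplitude
#' rhythmic burst (default 3 Hz with 2nd and 3rd harmonics, amplitude 3x the
#' background SD) on a random subset of `ceiling(n_channels / 3)` channels.
#' The number of seizure epochs is realized exactly as
#' `round(seizure_fraction * n_epochs)` (round half up), not by Bernoulli
#' draws, and their positions are drawn without replacement.
#'
#' @param config a [sim_config()]
#' @return an `eeg_dataset`: list with `epochs` (each a list with
#'   `patient_id`, `data` channel-by-sample matrix, `label`), `fs`,
#'   `channel_names`, and the generating `config`
#' @export
simulate_eeg_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_samp <- round(config$fs * config$epoch_seconds)
    n_total <- config$n_patients * config$epochs_per_patient
    n_seiz <- round_half_up(config$seizure_fraction * n_total)
    seiz_idx <- if (n_seiz > 0) sort(sample.int(n_total, n_seiz)) else integer(0)
    labels <- integer(n_total)
    labels[seiz_idx] <- 1L

    patient_scale <- exp(stats::rnorm(config$n_patients, 0,
                                      config$patient_effect_sd))
    n_seiz_ch <- ceiling(config$n_channels / 3)
    channel_names <- sprintf("ch%02d", seq_len(config$n_channels))
    t <- seq_len(n_samp) / config$fs

    epochs <- vector("list", n_total)
    idx <- 0L
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%03d", p)
      for (e in seq_len(config$epochs_per_patient)) {
        idx <- idx + 1L
        mat <- matrix(0, config$n_channels, n_samp,
                      dimnames = list(channel_names, NULL))
        for (ch in seq_len(config$n_channels)) {
          mat[ch, ] <- simulate_background_channel(n_samp, config$fs,
                                                   config$noise_sd)
        }
        mat <- mat * patient_scale[p]
        if (labels[idx] == 1L) {
          bg_sd <- stats::sd(as.vector(mat))
          chans <- sample.int(config$n_channels, n_seiz_ch)
          ph <- stats::runif(1, 0, 2 * pi)
          amp <- 3 * bg_sd
          f0 <- config$seizure_freq
          burst <- amp * (sin(2 * pi * f0 * t + ph) +
                            0.5 * sin(2 * pi * 2 * f0 * t + 2 * ph) +
                            0.3 * sin(2 * pi * 3 * f0 * t + 3 * ph))
          mat[chans, ] <- mat[chans, ] + rep(burst, each = length(chans))
        }
        epochs[[idx]] <- list(patient_id = pid, data = mat,
                              label = labels[idx])
      }
    }
    structure(list(epochs = epochs, fs = config$fs,
                   channel_names = channel_names, config = config),
              class = "eeg_dataset")
  })
}

#' @export
print.eeg_dataset <- function(x, ...) {
  n <- length(x$epochs)
  labs <- vapply(x$epochs, `[[`, numeric(1), "label")
  cat(sprintf(
    "<eeg_dataset> %d epochs (%d seizure, %.1f%%), %d channels @ %g Hz, %d patients\n",
    n, sum(labs), 100 * mean(labs), length(x$channel_names), x$fs,
    length(unique(vapply(x$epochs, `[[`, character(1), "patient_id")))))
  invisible(x)
}

#' Labels of every epoch in an EEG dataset
#' @param dataset an `eeg_dataset`
#' @return integer vector of 0/1 labels
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$epochs, function(e) as.integer(e$label), integer(1))
}

#' Patient ids of every epoch in an EEG dataset
#' @param dataset an `eeg_dataset`
#' @return character vector of patient ids
#' @export
dataset_patients <- function(dataset) {
  vapply(dataset$epochs, function(e) as.character(e$patient_id), character(1))
}
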