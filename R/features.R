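#' Configuration of the per-channel feature extractor
#'
#' Defaults: standard EEG band edges (delta 0.5-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-45 Hz); Welch PSD with 1 s Hann segments at 50%
#' overlap; EMD features on the first IMF with at most 8 IMFs sifted;
#' sample entropy with m = 2, r = 0.2 SD; permutation entropy at embedding
#' orders 3-6 (the four "levels"); db4 wavelets, 5 DWT levels, depth-3
#' wavelet packets.
#'
#' @param bands data.frame with columns `band`, `lo`, `hi` (five rows,
#'   ordered, non-overlapping)
#' @param psd_seg_seconds,psd_overlap Welch segmentation
#' @param emd_max_imfs maximum IMFs sifted
#' @param sampen_m,sampen_r sample-entropy embedding dimension and tolerance
#'   (as a multiple of the signal SD)
#' @param perment_orders exactly four permutation-entropy embedding orders
#' @param wavelet_family wavelet name (db4 is the implemented family)
#' @param dwt_levels DWT decomposition depth (default 5)
#' @param wpd_depth wavelet-packet depth (default 3)
#' @return an object of class `feature_config`
#' @export
feature_config <- function(bands = eeg_bands()[, c("band", "lo", "hi")],
                           psd_seg_seconds = 1, psd_overlap = 0.5,
                           emd_max_imfs = 8, sampen_m = 2, sampen_r = 0.2,
                           perment_orders = c(3, 4, 5, 6),
                           wavelet_family = "db4", dwt_levels = 5,
                           wpd_depth = 3) {
  if (nrow(bands) != 5) stop("exactly five bands are required", call. = FALSE)
  if (any(diff(bands$lo) <= 0) || any(bands$hi <= bands$lo) ||
      any(bands$lo[-1] < bands$hi[-5])) {
    stop("bands must be ordered and non-overlapping", call. = FALSE)
  }
  if (length(perment_orders) != 4) {
    stop("`perment_orders` must have exactly 4 entries", call. = FALSE)
  }
  if (wavelet_family != "db4") {
    stop("only the db4 wavelet family is implemented", call. = FALSE)
  }
  structure(list(bands = bands, psd_seg_seconds = psd_seg_seconds,
                 psd_overlap = psd_overlap, emd_max_imfs = emd_max_imfs,
                 sampen_m = sampen_m, sampen_r = sampen_r,
                 perment_orders = perment_orders,
                 wavelet_family = wavelet_family, dwt_levels = dwt_levels,
                 wpd_depth = wpd_depth),
            class = "feature_config")
}

#' Canonical names of the 44 per-channel features
#'
#' The fixed within-channel order: 15 band-power values (average, absolute,
#' relative PSD per band), 3 moments, 6 first-IMF statistics, 5 entropies
#' (sample + four permutation orders), 3 Hjorth parameters, the spectral
#' entropy of the PSD, 8 wavelet values and the SDI/energy triple — 44 in
#' all.
#'
#' @param config a [feature_config()]
#' @return character vector of length 44
#' @export
channel_feature_names <- function(config = feature_config()) {
  b <- config$bands$band
  c(sprintf("psd_avg_%s", b), sprintf("psd_abs_%s", b), sprintf("psd_rel_%s", b),
    "skewness", "variance", "kurtosis",
    "emd_energy", "emd_spec_entropy", "emd_mean", "emd_sd", "emd_moment",
    "emd_skewness",
    "sampen", sprintf("perment_o%d", config$perment_orders),
    "hjorth_mobility", "hjorth_activity", "hjorth_complexity",
    "spec_entropy_psd",
    "dwt_shannon", "wpd_logenergy", "wpd_shannon",
    "sdi", "mean_energy", "cum_energy",
    sprintf("wav_energy_pct_l%d", seq_len(config$dwt_levels)))
}

# The 44 features of one channel, reordered to the canonical layout (the
# wavelet energy percentages close the block, after the SDI/energy triple).
extract_channel_features <- function(signal, fs, config) {
  v <- c(extract_band_powers(signal, fs, config),
         extract_moments(signal),
         extract_emd_features(signal, fs, config),
         extract_entropies(signal, config),
         extract_hjorth(signal),
         extract_spectral_entropy(signal, fs, config),
         extract_wavelet_features(signal, config),
         extract_sdi_energy(signal))
  v[channel_feature_names(config)]
}

#' Extract the full per-epoch feature vector
#'
#' Concatenates the 44 per-channel features channel-major (all 44 features
#' of channel 1, then channel 2, ...), yielding `44 * n_channels` values —
#' 836 for a 19-channel montage. Names are `chXX_<feature>`.
#'
#' @param epoch channel-by-sample numeric matrix
#' @param fs sampling rate in Hz
#' @param config a [feature_config()]
#' @return named numeric vector of length `44 * nrow(epoch)`
#' @export
extract_feature_vector <- function(epoch, fs, config = feature_config()) {
  epoch <- as.matrix(epoch)
  if (nrow(epoch) < 1) stop("epoch must have at least one channel", call. = FALSE)
  per_ch <- channel_feature_names(config)
  out <- vector("list", nrow(epoch))
  for (ch in seq_len(nrow(epoch))) {
    v <- tryCatch(
      extract_channel_features(epoch[ch, ], fs, config),
      error = function(e) stop(sprintf("channel %d: %s", ch, conditionMessage(e)),
                               call. = FALSE))
    names(v) <- sprintf("ch%02d_%s", ch, per_ch)
    out[[ch]] <- v
  }
  unlist(out)
}

#' Extract a feature table from an EEG dataset
#'
#' Runs [extract_feature_vector()] over every epoch and assembles the
#' feature table (one row per epoch) with `patient_id`, `label` and
#' `is_synthetic` metadata columns.
#'
#' @param dataset an `eeg_dataset` from [simulate_eeg_dataset()] or
#'   [read_eeg_dataset()]
#' @param config a [feature_config()]
#' @param progress print a progress marker every 100 epochs
#' @return feature table data.frame
#' @export
extract_features <- function(dataset, config = feature_config(),
                             progress = FALSE) {
  rows <- vector("list", length(dataset$epochs))
  for (i in seq_along(dataset$epochs)) {
    rows[[i]] <- extract_feature_vector(dataset$epochs[[i]]$data, dataset$fs,
                                        config)
    if (progress && i %% 100 == 0) message("extracted ", i, " epochs")
  }
  feats <- do.call(rbind, rows)
  out <- data.frame(patient_id = dataset_patients(dataset),
                    label = dataset_labels(dataset),
                    is_synthetic = FALSE)
  cbind(out, as.data.frame(feats))
}

#' Feature dictionary
#'
#' One row per feature column: canonical name, channel, feature family and
#' measurement scale, for downstream tooling and provenance.
#'
#' @param n_channels number of channels in the table
#' @param config a [feature_config()]
#' @return data.frame with columns `name`, `channel`, `feature`, `family`
#' @export
feature_dictionary <- function(n_channels, config = feature_config()) {
  per_ch <- channel_feature_names(config)
  fam <- c(rep("band_power", 15), rep("moments", 3), rep("emd", 6),
           rep("entropy", 5), rep("hjorth", 3), "spectral_entropy",
           rep("wavelet", 3), rep("sdi_energy", 3),
           rep("wavelet", config$dwt_levels))
  do.call(rbind, lapply(seq_len(n_channels), function(ch) {
    data.frame(name = sprintf("ch%02d_%s", ch, per_ch),
               channel = ch, feature = per_ch, family = fam)
  }))
}

#' Write a feature table and its dictionary to disk
#'
#' @param table feature table data.frame
#' @param path CSV path for the table
#' @param dict_path optional JSON path for the feature dictionary
#' @param config a [feature_config()]
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path, dict_path = NULL,
                                config = feature_config()) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(dict_path)) {
    nch <- length(feature_columns(table)) / length(channel_feature_names(config))
    jsonlite::write_json(feature_dictionary(as.integer(nch), config),
                         dict_path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path
#' @return feature table data.frame
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_feature_table(tab)
  tab
}
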