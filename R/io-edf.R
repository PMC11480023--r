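# Minimal EDF (European Data Format) support: 16-bit integer samples, one
# data record per epoch, one file per patient. Epoch labels go to a sidecar
# CSV (epoch_index, label) since EDF carries no per-record annotations in
# the base format.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  sprintf(sprintf("%%-%ds", width), s)
}

# Format numbers to fit the 8-character ASCII header fields.
edf_num8 <- function(v) {
  vapply(v, function(x) {
    for (d in 7:1) {
      s <- sprintf(paste0("%.", d, "g"), x)
      if (nchar(s) <= 8) return(s)
    }
    stop("value does not fit an 8-character EDF field: ", x, call. = FALSE)
  }, character(1))
}

write_edf_file <- function(path, data_by_epoch, fs, channel_names,
                           patient_id, epoch_seconds) {
  n_sig <- length(channel_names)
  n_rec <- length(data_by_epoch)
  spr <- ncol(data_by_epoch[[1]])
  all_mat <- do.call(cbind, data_by_epoch)     # channels x (epochs*samples)
  pmin_ <- apply(all_mat, 1, min)
  pmax_ <- apply(all_mat, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  # widen by 1%, then round-trip through the 8-char ASCII header fields so
  # the scaling actually used matches what the header stores
  rng <- pmax_ - pmin_
  pmin_ <- as.numeric(edf_num8(pmin_ - 0.01 * rng))
  pmax_ <- as.numeric(edf_num8(pmax_ + 0.01 * rng))
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient_id, 80), edf_pad("eegaug simulation", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * n_sig, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(epoch_seconds), 8), edf_pad(n_sig, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(channel_names, 16)
  field(rep("AgAgCl electrode", n_sig), 80)
  field(rep("uV", n_sig), 8)
  field(edf_num8(pmin_), 8)
  field(edf_num8(pmax_), 8)
  field(rep(dmin, n_sig), 8)
  field(rep(dmax, n_sig), 8)
  field(rep("", n_sig), 80)
  field(rep(spr, n_sig), 8)
  field(rep("", n_sig), 32)

  for (rec in seq_len(n_rec)) {
    m <- data_by_epoch[[rec]]
    dig <- matrix(0L, n_sig, spr)
    for (s in seq_len(n_sig)) {
      g <- (dmax - dmin) / (pmax_[s] - pmin_[s])
      dig[s, ] <- as.integer(round((m[s, ] - pmin_[s]) * g + dmin))
    }
    writeBin(as.integer(as.vector(t(dig))), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                      # version
  patient_id <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))
  fields <- function(width) vapply(seq_len(n_sig), function(i) rd(width), character(1))
  labels <- fields(16)
  fields(80); fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  stopifnot(length(unique(spr)) == 1)
  spr <- spr[1]
  epochs <- vector("list", n_rec)
  for (rec in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = spr * n_sig, size = 2, signed = TRUE,
                   endian = "little")
    dig <- t(matrix(raw, nrow = spr))
    m <- matrix(0, n_sig, spr, dimnames = list(labels, NULL))
    for (s in seq_len(n_sig)) {
      m[s, ] <- (dig[s, ] - dmin[s]) * (pmax_[s] - pmin_[s]) /
        (dmax[s] - dmin[s]) + pmin_[s]
    }
    epochs[[rec]] <- m
  }
  list(patient_id = patient_id, epochs = epochs, channel_names = labels,
       fs = spr / rec_dur, epoch_seconds = rec_dur)
}

#' Write an EEG dataset to EDF files with a label sidecar
#'
#' One EDF file per patient (`<patient_id>.edf`), each epoch stored as one
#' data record, plus `labels.csv` with columns `patient_id`, `epoch_index`,
#' `label`. Sample values are quantized to the EDF 16-bit integer range.
#'
#' @param dataset an `eeg_dataset`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_eeg_dataset_edf <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pids <- dataset_patients(dataset)
  labs <- dataset_labels(dataset)
  epoch_seconds <- ncol(dataset$epochs[[1]]$data) / dataset$fs
  rows <- list()
  for (pid in unique(pids)) {
    sel <- which(pids == pid)
    write_edf_file(file.path(dir, paste0(pid, ".edf")),
                   lapply(dataset$epochs[sel], `[[`, "data"),
                   dataset$fs, dataset$channel_names, pid, epoch_seconds)
    rows[[pid]] <- data.frame(patient_id = pid,
                              epoch_index = seq_along(sel),
                              label = labs[sel])
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an EEG dataset from a directory of EDF files
#'
#' Symmetric to [write_eeg_dataset_edf()]; expects `labels.csv` alongside
#' the per-patient EDF files.
#'
#' @param dir dataset directory
#' @return an `eeg_dataset`
#' @export
read_eeg_dataset_edf <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stop("missing labels.csv in ", dir, call. = FALSE)
  labels <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  epochs <- list()
  fs <- NULL; channel_names <- NULL
  for (pid in unique(labels$patient_id)) {
    f <- file.path(dir, paste0(pid, ".edf"))
    if (!file.exists(f)) stop("missing EDF file for patient ", pid, call. = FALSE)
    edf <- read_edf_file(f)
    fs <- edf$fs; channel_names <- edf$channel_names
    lab <- labels[labels$patient_id == pid, ]
    lab <- lab[order(lab$epoch_index), ]
    for (i in seq_along(edf$epochs)) {
      epochs[[length(epochs) + 1]] <- list(patient_id = pid,
                                           data = edf$epochs[[i]],
                                           label = lab$label[i])
    }
  }
  structure(list(epochs = epochs, fs = fs, channel_names = channel_names,
                 config = NULL), class = "eeg_dataset")
}

#' Write an EEG dataset to a flat CSV container
#'
#' Lossless text alternative to EDF: one row per (epoch, channel) with the
#' samples in wide columns. Round-trips exactly.
#'
#' @param dataset an `eeg_dataset`
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_eeg_dataset_csv <- function(dataset, path) {
  mats <- lapply(dataset$epochs, `[[`, "data")
  n_ch <- nrow(mats[[1]])
  flat <- do.call(rbind, mats)
  meta <- data.frame(
    patient_id = rep(dataset_patients(dataset), each = n_ch),
    epoch = rep(seq_along(mats), each = n_ch),
    label = rep(dataset_labels(dataset), each = n_ch),
    channel = rep(dataset$channel_names, length(mats)),
    fs = dataset$fs)
  utils::write.csv(cbind(meta, as.data.frame(flat)), path, row.names = FALSE)
  invisible(path)
}

#' Read an EEG dataset from the flat CSV container
#' @param path CSV path written by [write_eeg_dataset_csv()]
#' @return an `eeg_dataset`
#' @export
read_eeg_dataset_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- c("patient_id", "epoch", "label", "channel", "fs")
  samp <- as.matrix(tab[, setdiff(colnames(tab), meta_cols)])
  channel_names <- unique(tab$channel)
  key <- paste(tab$patient_id, tab$epoch)
  epochs <- lapply(unique(key), function(k) {
    sel <- key == k
    m <- samp[sel, , drop = FALSE]
    rownames(m) <- tab$channel[sel]
    list(patient_id = tab$patient_id[sel][1], data = unname(m),
         label = tab$label[sel][1])
  })
  for (i in seq_along(epochs)) {
    rownames(epochs[[i]]$data) <- channel_names
  }
  structure(list(epochs = epochs, fs = tab$fs[1],
                 channel_names = channel_names, config = NULL),
            class = "eeg_dataset")
}
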