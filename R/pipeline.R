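#' Read and validate a declarative pipeline configuration
#'
#' A single YAML file with nested sections `sim`, `features`,
#' `augmentation`, `classifier`, `evaluation`, `output` plus a global
#' `seed`. Each present section is validated against its module's
#' constructor; unknown keys are rejected by name. Missing sections fall
#' back to module defaults.
#'
#' @param path YAML file path
#' @return a `pipeline_config` list with constructed module configs
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("sim", "features", "augmentation", "classifier", "evaluation",
             "output", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  seed <- as.integer(raw$seed %||% 1L)
  build <- function(section, fn, fn_name) {
    args <- raw[[section]] %||% list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in section `%s`: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    do.call(fn, args)
  }
  plans <- raw$augmentation %||% list(list(method = "none"))
  if (!is.null(names(plans)) && any(names(plans) != "")) plans <- list(plans)
  plan_objs <- lapply(plans, function(p) {
    bad <- setdiff(names(p), names(formals(augmentation_plan)))
    bad <- setdiff(bad, "gan")
    if (length(bad)) {
      stop("unknown key(s) in augmentation plan: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!is.null(p$gan)) p$gan <- do.call(gan_config, p$gan)
    p$seed <- p$seed %||% seed
    do.call(augmentation_plan, p)
  })
  structure(list(
    sim = build("sim", sim_config, "sim_config"),
    features = build("features", feature_config, "feature_config"),
    plans = plan_objs,
    classifier = build("classifier", classifier_config, "classifier_config"),
    k = (raw$evaluation %||% list())$k %||% 10,
    output_dir = (raw$output %||% list())$dir %||% "results",
    seed = seed, raw = raw
  ), class = "pipeline_config")
}

#' Simulate a dataset and write it to disk
#'
#' Writes per-patient EDF files with the label sidecar (or the flat CSV
#' container) plus a manifest JSON recording the seed, counts and config
#' hash.
#'
#' @param config a `pipeline_config` or [sim_config()]
#' @param dir output directory
#' @param format `"edf"` or `"csv"`
#' @return the manifest list, invisibly
#' @export
run_simulate <- function(config, dir, format = c("edf", "csv")) {
  format <- match.arg(format)
  sim <- if (inherits(config, "pipeline_config")) config$sim else config
  ds <- simulate_eeg_dataset(sim)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "edf") {
    write_eeg_dataset_edf(ds, dir)
  } else {
    write_eeg_dataset_csv(ds, file.path(dir, "dataset.csv"))
  }
  manifest <- list(
    seed = sim$seed, n_patients = sim$n_patients,
    n_epochs = length(ds$epochs), n_seizure = sum(dataset_labels(ds)),
    n_channels = sim$n_channels, fs = sim$fs,
    epoch_seconds = sim$epoch_seconds, format = format,
    config_hash = config_hash(jsonlite::toJSON(unclass(sim), auto_unbox = TRUE)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Extract features from a dataset directory and write the feature table
#'
#' @param input dataset directory (EDF + labels.csv) or flat CSV path
#' @param out_csv feature-table CSV path; the feature dictionary JSON is
#'   written alongside as `<out_csv>_dictionary.json`
#' @param config a [feature_config()]
#' @return the feature table, invisibly
#' @export
run_extract <- function(input, out_csv, config = feature_config()) {
  ds <- if (dir.exists(input)) read_eeg_dataset_edf(input) else
    read_eeg_dataset_csv(input)
  tab <- extract_features(ds, config)
  write_feature_table(tab, out_csv,
                      dict_path = paste0(out_csv, "_dictionary.json"),
                      config = config)
  invisible(tab)
}

#' Run every configured augmentation plan through cross-validated
#' evaluation
#'
#' For each plan in the pipeline config, runs [run_experiment()] and
#' writes `report_<method>.json` (plus a per-fold CSV) under the output
#' directory.
#'
#' @param table feature table data.frame
#' @param config a `pipeline_config`
#' @param dir output directory (defaults to the config's)
#' @return named list of `experiment_report`s, invisibly
#' @export
run_full_experiment <- function(table, config, dir = config$output_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  for (plan in config$plans) {
    rep_ <- run_experiment(table, plan, config$classifier, k = config$k)
    nm <- if (plan$method == "gan") paste0("gan_", plan$gan$variant) else
      plan$method
    write_experiment_report(rep_, file.path(dir, sprintf("report_%s.json", nm)),
                            seed = config$seed)
    reports[[nm]] <- rep_
  }
  invisible(reports)
}
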