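#' Configuration for a known-distribution feature-table simulator
#'
#' Draws a two-class feature table from per-class multivariate Gaussians (or
#' equal-weight Gaussian mixtures) with known parameters, so augmentation
#' methods can be tested for distribution recovery against ground truth.
#'
#' @param n_majority,n_minority class sample counts (minority <= majority)
#' @param n_features feature dimensionality
#' @param majority_mean,minority_mean mean vectors (length `n_features`), or
#'   a matrix with one mixture-component mean per row
#' @param majority_cov,minority_cov covariance matrices (shared across
#'   mixture components), symmetric positive semi-definite
#' @param n_patients number of patients; rows are assigned round-robin
#' @param seed integer seed
#' @return an object of class `feature_sim_config`
#' @export
feature_sim_config <- function(n_majority, n_minority, n_features = 2,
                               majority_mean = rep(0, n_features),
                               minority_mean = rep(2, n_features),
                               majority_cov = diag(n_features),
                               minority_cov = diag(n_features),
                               n_patients = 10, seed = 1L) {
  stopifnot_count(n_majority, "n_majority")
  if (n_minority < 0 || n_minority != round(n_minority)) {
    stop("`n_minority` must be a non-negative integer", call. = FALSE)
  }
  if (n_minority > n_majority) {
    stop("`n_minority` must not exceed `n_majority`", call. = FALSE)
  }
  check_cov <- function(S, name) {
    S <- as.matrix(S)
    if (nrow(S) != n_features || ncol(S) != n_features ||
        max(abs(S - t(S))) > 1e-8 || min(eigen(S, symmetric = TRUE,
                                               only.values = TRUE)$values) < -1e-8) {
      stop(sprintf("`%s` must be a symmetric PSD %dx%d matrix",
                   name, n_features, n_features), call. = FALSE)
    }
    S
  }
  structure(list(
    n_majority = as.integer(n_majority), n_minority = as.integer(n_minority),
    n_features = as.integer(n_features),
    majority_mean = rbind(majority_mean), minority_mean = rbind(minority_mean),
    majority_cov = check_cov(majority_cov, "majority_cov"),
    minority_cov = check_cov(minority_cov, "minority_cov"),
    n_patients = as.integer(n_patients), seed = as.integer(seed)
  ), class = "feature_sim_config")
}

draw_class <- function(n, means, cov) {
  if (n == 0) return(matrix(numeric(0), 0, ncol(cov)))
  comp <- sample.int(nrow(means), n, replace = TRUE)
  MASS::mvrnorm(n, mu = rep(0, ncol(cov)), Sigma = cov) + means[comp, , drop = FALSE]
}

#' Simulate a labeled feature table from known class distributions
#'
#' Majority rows (label 0) come first, then minority rows (label 1); class
#' counts are exact. Patient ids are assigned round-robin over all rows.
#'
#' @param config a [feature_sim_config()]
#' @return a feature table data.frame with columns `patient_id`, `label`,
#'   `is_synthetic` (all FALSE) and `f1..fD`
#' @export
simulate_feature_dataset <- function(config) {
  stopifnot(inherits(config, "feature_sim_config"))
  with_seed(config$seed, {
    maj <- draw_class(config$n_majority, config$majority_mean, config$majority_cov)
    mino <- draw_class(config$n_minority, config$minority_mean, config$minority_cov)
    x <- rbind(maj, mino)
    colnames(x) <- sprintf("f%d", seq_len(config$n_features))
    n <- nrow(x)
    out <- data.frame(
      patient_id = sprintf("P%03d", ((seq_len(n) - 1L) %% config$n_patients) + 1L),
      label = rep(c(0L, 1L), c(config$n_majority, config$n_minority)),
      is_synthetic = FALSE
    )
    cbind(out, as.data.frame(x))
  })
}
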