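#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All randomness in the package flows through this
# so a single integer seed reproduces any pipeline stage.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * stream) %% 2147483647L)
}

stopifnot_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer, got %s",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Round-half-up used wherever a fraction is converted to a count, so label
# frequencies are exact and deterministic rather than Bernoulli draws.
round_half_up <- function(x) floor(x + 0.5)

# --- feature-table helpers ---------------------------------------------------

#' Column names of the feature block of a feature table
#'
#' A feature table is a plain data.frame with metadata columns
#' `patient_id`, `label` and (optionally) `is_synthetic`; every other column
#' is a numeric feature.
#'
#' @param table a feature table data.frame
#' @return character vector of feature column names
#' @export
feature_columns <- function(table) {
  setdiff(colnames(table), c("patient_id", "label", "is_synthetic"))
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param table a feature table data.frame
#' @return numeric matrix, rows = epochs, columns = features
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_columns(table), drop = FALSE])
}

assert_feature_table <- function(table) {
  if (!is.data.frame(table)) stop("feature table must be a data.frame", call. = FALSE)
  miss <- setdiff(c("patient_id", "label"), colnames(table))
  if (length(miss)) {
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(table$label %in% c(0, 1))) {
    stop("feature table labels must be binary 0/1", call. = FALSE)
  }
  invisible(table)
}

# --- standardization ---------------------------------------------------------

#' Column-wise standardization helpers
#'
#' `fit_scaler()` learns per-column means and SDs (constant columns get SD
#' 1 so the transform stays invertible); `apply_scaler()` maps data to
#' z-scores and `invert_scaler()` maps back. Fit scalers on training rows
#' only when used inside cross-validation.
#'
#' @param x,z numeric matrix (rows = samples)
#' @param scaler a fitted scaler from `fit_scaler()`
#' @return `fit_scaler()`: list with `center` and `scale`; the others: a
#'   transformed matrix
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < .Machine$double.eps] <- 1
  list(center = mu, scale = sd)
}

#' @rdname fit_scaler
#' @export
apply_scaler <- function(x, scaler) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(z, scaler) {
  z <- as.matrix(z)
  sweep(sweep(z, 2, scaler$scale, "*"), 2, scaler$center, "+")
}

# Polynomial rolling hash of a string, hex-encoded; used to stamp artifacts
# with their configuration so reruns can be matched to their config.
config_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
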