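# k nearest neighbors of each row of `query` among rows of `ref` by
# Euclidean distance, excluding exact self-matches by index when
# `self_index` is given. Ties broken deterministically by row index.
knn_indices <- function(query, ref, k, self_index = NULL) {
  q2 <- rowSums(query^2)
  r2 <- rowSums(ref^2)
  d2 <- outer(q2, r2, "+") - 2 * query %*% t(ref)
  out <- matrix(0L, nrow(query), k)
  for (i in seq_len(nrow(query))) {
    d <- d2[i, ]
    if (!is.null(self_index)) d[self_index[i]] <- Inf
    ord <- order(d, seq_along(d))          # index tie-break
    out[i, ] <- ord[seq_len(k)]
  }
  out
}

#' SMOTE interpolation primitive
#'
#' The synthetic point `x_i + lam * (x_j - x_i)`, a point on the segment
#' between a minority sample and one of its minority neighbors.
#'
#' @param x_i,x_j numeric feature vectors of equal length
#' @param lam interpolation weight in [0, 1]
#' @return numeric vector
#' @export
smote_sample <- function(x_i, x_j, lam) {
  if (length(x_i) != length(x_j)) {
    stop("`x_i` and `x_j` must have the same dimensionality", call. = FALSE)
  }
  if (lam < 0 || lam > 1) stop("`lam` must lie in [0, 1]", call. = FALSE)
  x_i + lam * (x_j - x_i)
}

#' SMOTE oversampling of the minority class
#'
#' Appends `n_target` synthetic minority rows. Each synthetic row
#' interpolates between a uniformly drawn minority row and one of its `k`
#' nearest minority neighbors (Euclidean distance on features standardized
#' over the whole table; interpolation happens in the original feature
#' space), with interpolation weight Uniform(0, 1). The random stream is
#' consumed in a fixed order — base index, neighbor choice, weight — per
#' synthetic sample, so the procedure is reproducible and externally
#' replayable. Synthetic rows carry `is_synthetic = TRUE`.
#'
#' @param table feature table data.frame
#' @param k neighbor count (default 5; must be < minority count)
#' @param n_target number of synthetic rows to create
#' @param seed integer seed
#' @return augmented feature table
#' @export
smote_oversample <- function(table, k = 5, n_target, seed = 1L) {
  assert_feature_table(table)
  if (n_target < 0) stop("`n_target` must be non-negative", call. = FALSE)
  if (n_target == 0) return(table)
  min_idx <- which(table$label == 1)
  if (length(min_idx) <= k) {
    stop(sprintf("minority count (%d) must exceed k (%d)",
                 length(min_idx), k), call. = FALSE)
  }
  x <- feature_matrix(table)
  sc <- fit_scaler(x)
  z <- apply_scaler(x, sc)
  nn <- knn_indices(z[min_idx, , drop = FALSE], z[min_idx, , drop = FALSE],
                    k, self_index = seq_along(min_idx))
  xm <- x[min_idx, , drop = FALSE]
  synth <- with_seed(seed, {
    out <- matrix(0, n_target, ncol(x))
    for (s in seq_len(n_target)) {
      i <- sample.int(length(min_idx), 1)
      j <- nn[i, sample.int(k, 1)]
      lam <- stats::runif(1)
      out[s, ] <- smote_sample(xm[i, ], xm[j, ], lam)
    }
    out
  })
  append_synthetic_rows(table, synth)
}

append_synthetic_rows <- function(table, synth) {
  colnames(synth) <- feature_columns(table)
  add <- data.frame(patient_id = "synthetic", label = 1L, is_synthetic = TRUE)
  add <- cbind(add, as.data.frame(synth))
  if (!"is_synthetic" %in% colnames(table)) table$is_synthetic <- FALSE
  rbind(table[, colnames(add)], add)
}

#' ADASYN density ratios and per-sample allocations
#'
#' For each minority sample, `r_i = Delta_i / K` where `Delta_i` counts the
#' majority samples among its `K` nearest neighbors taken over the whole
#' table; the `r_i` are normalized to `r_hat` summing to 1, and `G` total
#' synthetic samples are allocated as `g_i = G * r_hat_i`, integerized by
#' largest-remainder so that `sum(g) == G` exactly. If no minority sample
#' has a majority neighbor (`sum(r) == 0`), allocation falls back to
#' uniform with a warning.
#'
#' @param table feature table data.frame
#' @param K neighbor count (default 5)
#' @param G total synthetic samples to allocate
#' @return list with `r`, `r_hat`, `g` (one entry per minority row, in
#'   table order) and `minority_index`
#' @export
adasyn_ratios <- function(table, K = 5, G) {
  assert_feature_table(table)
  min_idx <- which(table$label == 1)
  x <- feature_matrix(table)
  sc <- fit_scaler(x)
  z <- apply_scaler(x, sc)
  nn <- knn_indices(z[min_idx, , drop = FALSE], z, K, self_index = min_idx)
  r <- vapply(seq_along(min_idx), function(i)
    sum(table$label[nn[i, ]] == 0) / K, numeric(1))
  if (sum(r) == 0) {
    warning("no minority sample has majority neighbors; uniform allocation")
    r_hat <- rep(1 / length(r), length(r))
  } else {
    r_hat <- r / sum(r)
  }
  g <- largest_remainder(G * r_hat, G)
  list(r = r, r_hat = r_hat, g = g, minority_index = min_idx)
}

# Integerize non-negative quotas to a fixed total: floor, then distribute
# the remainder to the largest fractional parts (ties by index).
largest_remainder <- function(quota, total) {
  g <- floor(quota)
  rem <- total - sum(g)
  if (rem > 0) {
    ord <- order(quota - g, decreasing = TRUE)
    g[ord[seq_len(rem)]] <- g[ord[seq_len(rem)]] + 1
  }
  as.integer(g)
}

#' ADASYN oversampling of the minority class
#'
#' Allocates synthetic samples per [adasyn_ratios()] — more where minority
#' samples are surrounded by majority samples — then generates each by
#' linear interpolation toward a randomly chosen one of the sample's `K`
#' nearest minority neighbors with weight Uniform(0, 1). Appends exactly
#' `G` rows flagged `is_synthetic = TRUE`. Minority rows are processed in
#' table order; per sample the stream order is neighbor choice then weight.
#'
#' @param table feature table data.frame
#' @param K neighbor count (default 5)
#' @param G total synthetic samples
#' @param seed integer seed
#' @return augmented feature table
#' @export
adasyn_oversample <- function(table, K = 5, G, seed = 1L) {
  assert_feature_table(table)
  if (G < 0) stop("`G` must be non-negative", call. = FALSE)
  if (G == 0) return(table)
  min_idx <- which(table$label == 1)
  if (length(min_idx) < 2) {
    stop("ADASYN needs at least 2 minority samples", call. = FALSE)
  }
  rat <- adasyn_ratios(table, K, G)
  x <- feature_matrix(table)
  sc <- fit_scaler(x)
  z <- apply_scaler(x, sc)
  k_eff <- min(K, length(min_idx) - 1)
  nn_min <- knn_indices(z[min_idx, , drop = FALSE], z[min_idx, , drop = FALSE],
                        k_eff, self_index = seq_along(min_idx))
  xm <- x[min_idx, , drop = FALSE]
  synth <- with_seed(seed, {
    out <- matrix(0, G, ncol(x))
    s <- 0L
    for (i in seq_along(min_idx)) {
      for (rep_ in seq_len(rat$g[i])) {
        s <- s + 1L
        j <- nn_min[i, sample.int(k_eff, 1)]
        lam <- stats::runif(1)
        out[s, ] <- xm[i, ] + lam * (xm[j, ] - xm[i, ])
      }
    }
    out
  })
  append_synthetic_rows(table, synth)
}

#' Inverse-frequency class weights
#'
#' `w_c = n_total / (2 * n_c)`: balanced classes get weight 1 each; a 90/10
#' split gives the minority 9x the majority weight. Both classes must be
#' present.
#'
#' @param labels binary 0/1 label vector
#' @return named numeric vector with weights for classes `"0"` and `"1"`
#' @export
compute_class_weights <- function(labels) {
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0) {
    stop("both classes must be present to compute class weights", call. = FALSE)
  }
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}
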