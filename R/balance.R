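#' Augmentation plan
#'
#' Bundles one balancing method and its parameters. `target_ratio` is the
#' minority:majority ratio to reach by appending synthetic minority rows
#' (1 = exact balance); `class_weight` produces weights instead of rows,
#' and `none` is the identity.
#'
#' @param method one of `"none"`, `"smote"`, `"adasyn"`, `"class_weight"`,
#'   `"gan"`
#' @param target_ratio minority:majority ratio after augmentation
#' @param k SMOTE neighbor count
#' @param K ADASYN neighbor count
#' @param gan a [gan_config()] (gan method only)
#' @param seed integer seed for the sampling methods
#' @return an object of class `augmentation_plan`
#' @export
augmentation_plan <- function(method = c("none", "smote", "adasyn",
                                         "class_weight", "gan"),
                              target_ratio = 1, k = 5, K = 5,
                              gan = gan_config(), seed = 1L) {
  method <- match.arg(method)
  if (target_ratio <= 0 || target_ratio > 1) {
    stop("`target_ratio` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(method = method, target_ratio = target_ratio, k = k, K = K,
                 gan = gan, seed = as.integer(seed)),
            class = "augmentation_plan")
}

# Synthetic rows needed to reach the plan's minority:majority ratio.
synthetic_rows_needed <- function(labels, target_ratio) {
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  max(0L, as.integer(round_half_up(target_ratio * n0) - n1))
}

#' Balance a feature table according to a plan
#'
#' Sampling methods append synthetic minority rows (flagged
#' `is_synthetic = TRUE`) until the target class ratio is met; the GAN
#' plan trains on the minority rows of `table` only (`cgan` conditions on
#' both classes) and generates the shortfall; `class_weight` returns the
#' table untouched together with inverse-frequency weights; `none` is the
#' identity. Original rows are never modified or dropped.
#'
#' @param table feature table data.frame (a training split — never pass
#'   test rows)
#' @param plan an [augmentation_plan()]
#' @return list with `table` (possibly augmented), `weights` (named class
#'   weights or NULL) and `gan_model` (for gan plans)
#' @export
balance_dataset <- function(table, plan) {
  stopifnot(inherits(plan, "augmentation_plan"))
  assert_feature_table(table)
  if (!"is_synthetic" %in% colnames(table)) table$is_synthetic <- FALSE
  need <- synthetic_rows_needed(table$label, plan$target_ratio)
  out <- switch(
    plan$method,
    none = list(table = table, weights = NULL),
    class_weight = list(table = table,
                        weights = compute_class_weights(table$label)),
    smote = list(table = smote_oversample(table, k = plan$k, n_target = need,
                                          seed = plan$seed), weights = NULL),
    adasyn = list(table = adasyn_oversample(table, K = plan$K, G = need,
                                            seed = plan$seed), weights = NULL),
    gan = {
      model <- train_gan(table, plan$gan)
      synth <- generate_synthetic(model, need,
                                  seed = derive_seed(plan$gan$seed, 1L))
      tab <- if (need > 0) append_synthetic_rows(table, synth) else table
      list(table = tab, weights = NULL, gan_model = model)
    })
  out$gan_model <- out$gan_model %||% NULL
  out
}
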