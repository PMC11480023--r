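#' Classifier configuration
#'
#' `rf` is a Random Forest (500 trees by default). `lstm` is the recurrent
#' classifier: two LSTM layers of 10 units, a dense sigmoid output,
#' binary cross-entropy (optionally class-weighted), Adam with learning
#' rate 0.001, beta1 = 0.9, beta2 = 0.999, up to 100 epochs with early
#' stopping once the validation loss has not improved for 20 epochs. The
#' feature vector is reshaped channel-major into a sequence of
#' `timesteps` steps (one per channel for extracted EEG features);
#' `timesteps = NULL` infers the channel count from `chXX_` column-name
#' prefixes and falls back to a single timestep. Direction is unidirectional
#' by default with a bidirectional switch.
#'
#' @param kind `"rf"` or `"lstm"`
#' @param n_trees Random Forest tree count
#' @param units LSTM units per layer (default 10)
#' @param n_layers LSTM layer count (default 2)
#' @param bidirectional process the sequence in both directions
#' @param timesteps sequence length for reshaping, or NULL to infer
#' @param learning_rate,beta1,beta2 Adam parameters
#' @param max_epochs training-epoch cap (default 100)
#' @param patience early-stopping patience in epochs (default 20)
#' @param batch_size minibatch size
#' @param validation_fraction fraction of training patients held out for
#'   early stopping (grouped; default 0.1)
#' @param seed integer seed
#' @return an object of class `classifier_config`
#' @export
classifier_config <- function(kind = c("rf", "lstm"), n_trees = 500,
                              units = 10, n_layers = 2, bidirectional = FALSE,
                              timesteps = NULL, learning_rate = 0.001,
                              beta1 = 0.9, beta2 = 0.999, max_epochs = 100,
                              patience = 20, batch_size = 32,
                              validation_fraction = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 units = as.integer(units), n_layers = as.integer(n_layers),
                 bidirectional = bidirectional, timesteps = timesteps,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

infer_timesteps <- function(table, config) {
  if (!is.null(config$timesteps)) return(as.integer(config$timesteps))
  cols <- feature_columns(table)
  ch <- unique(sub("^(ch[0-9]+)_.*$", "\\1", cols[grepl("^ch[0-9]+_", cols)]))
  if (length(ch) >= 1 && length(cols) %% length(ch) == 0 && length(ch) > 0) {
    return(length(ch))
  }
  1L
}

#' Train a classifier on a (possibly augmented) feature table
#'
#' Both classes must be present. For the LSTM, features are standardized
#' (scaler stored on the model), reshaped into sequences, and a
#' patient-grouped validation slice (synthetic rows excluded) drives early
#' stopping; sample weights from `weights` (per-class) enter the
#' cross-entropy.
#'
#' @param table feature table data.frame
#' @param config a [classifier_config()]
#' @param weights optional named per-class weights (`"0"`, `"1"`) as from
#'   [compute_class_weights()]
#' @return a `classifier_model`
#' @export
train_classifier <- function(table, config, weights = NULL) {
  assert_feature_table(table)
  x <- feature_matrix(table)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  y <- table$label
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  model <- if (config$kind == "rf") {
    with_seed(config$seed, {
      yf <- factor(y, levels = c(0, 1))
      if (is.null(weights)) {
        randomForest::randomForest(x = x, y = yf, ntree = config$n_trees)
      } else {
        # class weights as a weighted stratified per-tree bootstrap: in-bag
        # class counts proportional to n_c * w_c, scaled so no stratum is
        # oversampled (randomForest's classwt argument is ineffective)
        n_c <- table(yf)
        quota <- as.numeric(n_c) * unname(weights[c("0", "1")])
        s <- min(as.numeric(n_c) / quota)
        sampsize <- pmax(1L, floor(quota * s))
        randomForest::randomForest(x = x, y = yf, ntree = config$n_trees,
                                   strata = yf, sampsize = sampsize)
      }
    })
  } else {
    train_lstm(table, config, weights)
  }
  structure(list(kind = config$kind, fit = model, config = config,
                 features = feature_columns(table)),
            class = "classifier_model")
}

#' Predict seizure probabilities
#'
#' @param model a `classifier_model`
#' @param table feature table with the training feature columns
#' @return numeric vector of probabilities
#' @export
predict_classifier <- function(model, table) {
  x <- as.matrix(table[, model$features, drop = FALSE])
  if (model$kind == "rf") {
    unname(stats::predict(model$fit, x, type = "prob")[, "1"])
  } else {
    z <- apply_scaler(x, model$fit$scaler)
    seq_ <- matrix_to_seq(z, model$fit$timesteps)
    lstm_net_forward(model$fit$net, seq_)$prob
  }
}

train_lstm <- function(table, config, weights = NULL) {
  timesteps <- infer_timesteps(table, config)
  x <- feature_matrix(table)
  y <- table$label
  sc <- fit_scaler(x)
  z <- apply_scaler(x, sc)
  sample_w <- if (is.null(weights)) rep(1, nrow(z)) else
    unname(weights[as.character(y)])

  # patient-grouped validation slice from the real rows (last fraction of
  # the patient list); synthetic rows always stay in the training part
  pids <- unique(table$patient_id[!(table$is_synthetic %||% FALSE)])
  n_val_p <- max(1L, floor(length(pids) * config$validation_fraction))
  val_p <- utils::tail(pids, n_val_p)
  is_val <- table$patient_id %in% val_p & !(table$is_synthetic %||% FALSE)
  if (sum(is_val) < 2 || length(unique(y[!is_val])) < 2) {
    is_val <- rep(FALSE, nrow(z))        # too small to hold out; train on all
  }
  tr_idx <- which(!is_val)
  va_idx <- which(is_val)

  with_seed(config$seed, {
    net <- lstm_net_init(ncol(z) / timesteps, config$units, config$n_layers,
                         config$bidirectional)
    packed <- lstm_pack(net)
    opt <- adam_init(packed)
    best <- list(loss = Inf, packed = packed, epoch = 0L)
    wait <- 0L
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          train_acc = numeric(0), val_loss = numeric(0))
    nb <- min(config$batch_size, length(tr_idx))
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      for (start in seq(1, length(ord), by = nb)) {
        idx <- ord[start:min(start + nb - 1, length(ord))]
        Xb <- matrix_to_seq(z[idx, , drop = FALSE], timesteps)
        fwd <- lstm_net_forward(net, Xb)
        p <- pmin(pmax(fwd$prob, 1e-7), 1 - 1e-7)
        w <- sample_w[idx]
        loss <- -mean(w * (y[idx] * log(p) + (1 - y[idx]) * log(1 - p)))
        if (!is.finite(loss)) {
          stop("non-finite LSTM training loss: diverged", call. = FALSE)
        }
        dlogit <- w * (p - y[idx]) / length(idx)
        grads <- lstm_pack_grads(net, lstm_net_backward(net, fwd, dlogit))
        up <- adam_step(packed, grads, opt, config$learning_rate,
                        config$beta1, config$beta2)
        packed <- up$net; opt <- up$state
        net <- lstm_unpack(net, packed)
        ep_loss <- ep_loss + loss * length(idx)
        ep_n <- ep_n + length(idx)
        ep_correct <- ep_correct + sum((p >= 0.5) == (y[idx] == 1))
      }
      val_loss <- if (length(va_idx)) {
        pv <- lstm_net_forward(net,
          matrix_to_seq(z[va_idx, , drop = FALSE], timesteps))$prob
        pv <- pmin(pmax(pv, 1e-7), 1 - 1e-7)
        -mean(y[va_idx] * log(pv) + (1 - y[va_idx]) * log(1 - pv))
      } else ep_loss / ep_n
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / ep_n,
        train_acc = ep_correct / ep_n, val_loss = val_loss))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, packed = packed, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    net <- lstm_unpack(net, best$packed)
    list(net = net, scaler = sc, timesteps = timesteps, history = history,
         best_epoch = best$epoch)
  })
}
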