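#' MAP-threshold baseline classifier
#'
#' The baseline predictor compares the mean MAP of the 20-second segment to
#' a threshold: a mean MAP at or below the threshold is classified as an
#' impending hypotension event. Left without a fixed threshold the model
#' operates in score mode, where the (negated) mean MAP serves as a
#' continuous risk score and a ROC curve sweeps all thresholds.
#'
#' @param threshold_mmHg fixed decision threshold in mmHg, or `NULL` for
#'   score mode.
#' @param sweep_range threshold range covered by the classical sweep, mmHg.
#' @return an object of class `mapthr_model`.
#' @export
mapthr_model <- function(threshold_mmHg = NULL, sweep_range = c(55, 85)) {
  if (!is.null(threshold_mmHg)) {
    stopifnot(threshold_mmHg >= sweep_range[1], threshold_mmHg <= sweep_range[2])
  }
  structure(list(threshold_mmHg = threshold_mmHg, sweep_range = sweep_range),
            class = "mapthr_model")
}

#' Risk score of the MAP-threshold model
#'
#' Higher score means higher hypotension risk, so the score is the negated
#' segment mean MAP (monotone decreasing in MAP).
#'
#' @param segment_mean_map numeric vector of segment mean MAPs, mmHg.
#' @return numeric risk scores.
#' @export
mapthr_score <- function(segment_mean_map) {
  stopifnot(all(is.finite(segment_mean_map)))
  -segment_mean_map
}

#' Hard classification by the MAP-threshold rule
#'
#' Mean MAP above the threshold is classified as non-hypotension
#' (`negative`); at or below the threshold as `positive` (ties alarm, the
#' conservative choice).
#'
#' @param segment_mean_map numeric vector of segment mean MAPs, mmHg.
#' @param threshold_mmHg decision threshold, mmHg.
#' @return character vector of `"positive"` / `"negative"`.
#' @export
mapthr_classify <- function(segment_mean_map, threshold_mmHg) {
  ifelse(segment_mean_map <= threshold_mmHg, "positive", "negative")
}

#' Specification of the 7-layer 1-D CNN
#'
#' The architecture classifies a 20-s (2500-sample) ABP segment: seven
#' valid-padding convolution layers (kernel size 10) each followed by batch
#' normalization, ReLU, stride-2 max pooling and dropout, then a
#' global-average-pooling head with one hidden dense layer and a sigmoid
#' output. Inputs are scaled by the fixed affine map
#' `(x - scale_center) / scale_scale` — deliberately not per-segment
#' normalization, which would erase the absolute MAP level the task depends
#' on.
#'
#' @param n_conv_layers number of convolution blocks.
#' @param kernel_size convolution kernel width, samples.
#' @param channels integer vector of output channels per block.
#' @param dropout_rate dropout probability after each block.
#' @param hidden_units width of the dense hidden layer.
#' @param input_length segment length in samples (20 s x 125 Hz).
#' @param scale_center,scale_scale fixed affine input scaling, mmHg.
#' @return an object of class `cnn_spec`.
#' @export
cnn_spec <- function(n_conv_layers = 7, kernel_size = 10,
                     channels = c(32, 32, 64, 64, 128, 128, 128),
                     dropout_rate = 0.01, hidden_units = 64,
                     input_length = 2500, scale_center = 80, scale_scale = 40) {
  stopifnot(length(channels) == n_conv_layers, kernel_size >= 1,
            dropout_rate >= 0, dropout_rate < 1, input_length >= kernel_size)
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 kernel_size = as.integer(kernel_size),
                 channels = as.integer(channels),
                 dropout_rate = dropout_rate,
                 hidden_units = as.integer(hidden_units),
                 input_length = as.integer(input_length),
                 scale_center = scale_center, scale_scale = scale_scale),
            class = "cnn_spec")
}

#' Training configuration for the CNN
#'
#' Weighted binary cross-entropy (class-balanced weights
#' `w_c = n_total / (2 n_c)` computed on the training split), Adam with
#' learning rate 0.001, batch size 20, up to 150 epochs with early stopping
#' on validation AUC-ROC.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs (must be smaller than
#'   `max_epochs`).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 20,
                         max_epochs = 150, patience = 10, seed = 1L) {
  stopifnot(patience < max_epochs, learning_rate > 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

# Class-balanced weights w_c = n_total / (2 n_c); a constant-output model
# then incurs equal total loss from each class.
.balanced_weights <- function(y) {
  n <- length(y)
  c(neg = n / (2 * sum(y == 0)), pos = n / (2 * sum(y == 1)))
}

.weighted_bce <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  wi <- ifelse(y == 1, w["pos"], w["neg"])
  mean(-wi * (y * log(p) + (1 - y) * log(1 - p)))
}

.dataset_xy <- function(dataset, spec) {
  X <- (dataset$segments - spec$scale_center) / spec$scale_scale
  y <- as.integer(dataset$meta$label == "positive")
  list(X = X, y = y)
}

# Per-layer pooled output geometry for a given input length.
.cnn_layer_dims <- function(spec) {
  L <- spec$input_length
  dims <- list()
  for (i in seq_len(spec$n_conv_layers)) {
    L <- (L - spec$kernel_size + 1L) %/% 2L
    dims[[i]] <- L
  }
  dims
}

#' Train the CNN predictor
#'
#' Minibatch training with Adam on weighted binary cross-entropy; after each
#' epoch the validation AUC-ROC is evaluated (in inference mode) and the
#' weights of the best-validation epoch are retained. Training stops early
#' when the validation AUC has not improved for `patience` epochs. With a
#' fixed seed and single-threaded BLAS the run is deterministic.
#'
#' @param train,val `ioh_dataset` splits; both must contain both classes and
#'   must not share patients.
#' @param spec a [cnn_spec()].
#' @param config a [train_config()].
#' @return an object of class `ioh_cnn` with elements `params` (best
#'   weights), `spec`, `log` (per-epoch data.frame: epoch, train_loss,
#'   val_auc), `best_epoch`, `best_val_auc`.
#' @export
train_cnn <- function(train, val, spec = cnn_spec(), config = train_config()) {
  tr <- .dataset_xy(train, spec)
  va <- .dataset_xy(val, spec)
  if (length(unique(tr$y)) < 2 || length(unique(va$y)) < 2) {
    stop("both classes must be present in train and validation splits")
  }
  if (length(intersect(train$meta$patient_id, val$meta$patient_id)) > 0) {
    stop("patient overlap between train and validation splits")
  }
  if (ncol(tr$X) != spec$input_length) {
    stop("segment length ", ncol(tr$X), " does not match spec input_length ",
         spec$input_length)
  }
  w <- .balanced_weights(tr$y)
  dims <- .cnn_layer_dims(spec)
  n <- nrow(tr$X)

  with_seed(config$seed, {
    params <- .cnn_init_params(spec)
    flat <- .cnn_flatten(params, spec)
    adam <- .adam_state(flat)
    best <- list(auc = -Inf, params = params, epoch = 0L)
    log_rows <- list()
    since_best <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        B <- length(idx)
        Xb <- tr$X[idx, , drop = FALSE]
        yb <- tr$y[idx]
        masks <- if (spec$dropout_rate > 0) {
          lapply(seq_len(spec$n_conv_layers), function(i) {
            matrix(stats::runif(dims[[i]] * B * spec$channels[i]) >=
                     spec$dropout_rate, dims[[i]] * B, spec$channels[i])
          })
        } else NULL
        fwd <- .cnn_forward(params, spec, Xb, training = TRUE,
                            drop_masks = masks)
        params <- fwd$params            # running BN stats updated
        losses <- c(losses, .weighted_bce(fwd$p, yb, w))
        wi <- ifelse(yb == 1, w["pos"], w["neg"])
        dz <- wi * (fwd$p - yb) / B
        grads <- .cnn_backward(params, spec, fwd, dz)
        upd <- .adam_step(.cnn_flatten(params, spec),
                          .cnn_flatten_grads(grads, spec), adam,
                          config$learning_rate)
        adam <- upd$state
        params <- .cnn_unflatten(upd$flat, params, spec)
      }
      val_p <- .cnn_predict_mat(params, spec, va$X)
      val_auc <- roc_pr_auc(val_p, va$y)$auc_roc
      log_rows[[epoch]] <- data.frame(epoch = epoch,
                                      train_loss = mean(losses),
                                      val_auc = val_auc)
      if (val_auc > best$auc) {
        best <- list(auc = val_auc, params = params, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
    structure(list(params = best$params, spec = spec,
                   log = do.call(rbind, log_rows),
                   best_epoch = best$epoch, best_val_auc = best$auc,
                   class_weights = w, config = config),
              class = "ioh_cnn")
  })
}

# Inference-mode forward in memory-bounded chunks (batch-size independent
# because inference batch normalization uses running statistics).
.cnn_predict_mat <- function(params, spec, X, chunk = 32L) {
  n <- nrow(X)
  p <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    p[idx] <- .cnn_forward(params, spec, X[idx, , drop = FALSE],
                           training = FALSE)$p
  }
  p
}

#' Predict hypotension risk scores
#'
#' Generic over the two predictor families. For the CNN, `segments` is a
#' matrix of raw ABP segments (one row per data point, `input_length`
#' samples); outputs are probabilities in (0, 1), order-preserving and
#' independent of batching. For the MAP-threshold model, `segments` is the
#' numeric vector of segment mean MAPs and the output is the negated-MAP
#' risk score.
#'
#' @param model an `ioh_cnn` or `mapthr_model`.
#' @param segments matrix of segments (CNN) or numeric vector of mean MAPs
#'   (MAP-threshold).
#' @return numeric vector of scores.
#' @export
predict_proba <- function(model, segments) UseMethod("predict_proba")

#' @export
predict_proba.ioh_cnn <- function(model, segments) {
  if (is.vector(segments)) segments <- matrix(segments, nrow = 1)
  if (ncol(segments) != model$spec$input_length) {
    stop("segment length ", ncol(segments), " does not match model input_length ",
         model$spec$input_length)
  }
  X <- (segments - model$spec$scale_center) / model$spec$scale_scale
  .cnn_predict_mat(model$params, model$spec, X)
}

#' @export
predict_proba.mapthr_model <- function(model, segments) {
  mapthr_score(as.numeric(segments))
}

#' Score a labeled dataset with either predictor
#'
#' Convenience wrapper routing the right representation to the model: raw
#' segments to the CNN, segment mean MAPs to the MAP-threshold baseline.
#'
#' @param model an `ioh_cnn` or `mapthr_model`.
#' @param dataset an `ioh_dataset`.
#' @return numeric vector of scores, one per data point.
#' @export
predict_dataset <- function(model, dataset) {
  if (inherits(model, "ioh_cnn")) {
    predict_proba(model, dataset$segments)
  } else {
    predict_proba(model, dataset$meta$segment_mean_map)
  }
}

#' Trainer factories for the evaluation framework
#'
#' A trainer is a function `(train, val, seed) -> model` used by
#' [cross_dataset_matrix()] and related experiment drivers.
#' `trainer_mapthr()` needs no fitting; `trainer_cnn()` wraps [train_cnn()]
#' with the given spec and training configuration.
#'
#' @param spec a [cnn_spec()].
#' @param config a [train_config()] whose seed is overridden per call.
#' @return a trainer function.
#' @export
trainer_mapthr <- function() {
  function(train, val, seed = 1L) mapthr_model()
}

#' @rdname trainer_mapthr
#' @export
trainer_cnn <- function(spec = cnn_spec(), config = train_config()) {
  function(train, val, seed = 1L) {
    config$seed <- as.integer(seed)
    train_cnn(train, val, spec, config)
  }
}
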