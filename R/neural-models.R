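#' Training protocol configuration
#'
#' Defaults follow the shared protocol of the five architectures: batch size
#' 32, learning rate 0.001, Adam, binary cross-entropy loss, at most 100
#' epochs with early stopping after 10 epochs without validation-loss
#' improvement (best weights restored).
#'
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param max_epochs Epoch cap (default 100).
#' @param patience Early-stopping patience in epochs (default 10; must be
#'   below `max_epochs`).
#' @param seed Integer seed controlling weight initialization, shuffling and
#'   dropout.
#' @return A list of class `training_config`.
#' @export
training_config <- function(batch_size = 32L, learning_rate = 0.001,
                            max_epochs = 100L, patience = 10L, seed = 1L) {
  if (batch_size < 1L || learning_rate <= 0 || max_epochs < 1L || patience < 1L) {
    stop("all training parameters must be positive", call. = FALSE)
  }
  if (patience >= max_epochs) stop("patience must be smaller than max_epochs", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = "adam",
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 loss = "binary_cross_entropy",
                 seed = as.integer(seed)),
            class = "training_config")
}

ARCHITECTURE_NAMES <- c("cnn", "lstm", "blstm", "cnn_lstm", "cnn_blstm")

#' Build one of the five sequence architectures
#'
#' * `cnn`: three blocks of conv1d(32 filters, width 5, stride 1) + max
#'   pooling(4), then dense 1,024 / 512 / 128 (each followed by 20%
#'   dropout), then a single sigmoid unit.
#' * `lstm`: LSTM(128) -> dense(64) -> 50% dropout -> sigmoid unit.
#' * `blstm`: same with a bidirectional LSTM (128 units per direction,
#'   outputs concatenated).
#' * `cnn_lstm`: conv1d(64 filters, width 3) -> max pooling(3) -> 25%
#'   dropout -> LSTM(64) -> 80% dropout -> sigmoid unit.
#' * `cnn_blstm`: same with a bidirectional LSTM (64 per direction).
#'
#' Convolutions use no padding ("valid") and stride 1; pooling stride equals
#' pool size; hidden activations are rectified linear; recurrent layers
#' return only their final state.
#'
#' @param name One of `"cnn"`, `"lstm"`, `"blstm"`, `"cnn_lstm"`,
#'   `"cnn_blstm"`.
#' @param input_length Window length in bases (default 1003).
#' @param seed Seed for the initial weights (re-initialized by
#'   [train_network()] from its own config).
#' @return An object of class `nn_model` with `name`, `input_length`,
#'   `layers` (initialized), and the structural spec via
#'   [architecture_spec()].
#' @export
build_architecture <- function(name, input_length = 1003L, seed = 1L) {
  if (!name %in% ARCHITECTURE_NAMES) {
    stop("unknown architecture '", name, "'; expected one of ",
         paste(ARCHITECTURE_NAMES, collapse = ", "), call. = FALSE)
  }
  layers <- switch(name,
    cnn = c(
      unlist(lapply(1:3, function(i) list(
        new_layer("conv1d", filters = 32L, width = 5L, stride = 1L,
                  activation = "relu"),
        new_layer("maxpool", size = 4L)
      )), recursive = FALSE),
      list(new_layer("flatten"),
           new_layer("dense", units = 1024L, activation = "relu"),
           new_layer("dropout", rate = 0.2),
           new_layer("dense", units = 512L, activation = "relu"),
           new_layer("dropout", rate = 0.2),
           new_layer("dense", units = 128L, activation = "relu"),
           new_layer("dropout", rate = 0.2),
           new_layer("dense", units = 1L, activation = "sigmoid"))
    ),
    lstm = list(
      new_layer("lstm", units = 128L, bidirectional = FALSE),
      new_layer("dense", units = 64L, activation = "relu"),
      new_layer("dropout", rate = 0.5),
      new_layer("dense", units = 1L, activation = "sigmoid")
    ),
    blstm = list(
      new_layer("lstm", units = 128L, bidirectional = TRUE),
      new_layer("dense", units = 64L, activation = "relu"),
      new_layer("dropout", rate = 0.5),
      new_layer("dense", units = 1L, activation = "sigmoid")
    ),
    cnn_lstm = list(
      new_layer("conv1d", filters = 64L, width = 3L, stride = 1L,
                activation = "relu"),
      new_layer("maxpool", size = 3L),
      new_layer("dropout", rate = 0.25),
      new_layer("lstm", units = 64L, bidirectional = FALSE),
      new_layer("dropout", rate = 0.8),
      new_layer("dense", units = 1L, activation = "sigmoid")
    ),
    cnn_blstm = list(
      new_layer("conv1d", filters = 64L, width = 3L, stride = 1L,
                activation = "relu"),
      new_layer("maxpool", size = 3L),
      new_layer("dropout", rate = 0.25),
      new_layer("lstm", units = 64L, bidirectional = TRUE),
      new_layer("dropout", rate = 0.8),
      new_layer("dense", units = 1L, activation = "sigmoid")
    )
  )
  model <- structure(list(name = name, input_length = as.integer(input_length),
                          layers = layers, initialized = FALSE),
                     class = "nn_model")
  init_model_params(model, seed)
}

#' Structural description of an architecture
#'
#' One row per layer with its kind and size hyper-parameters, for
#' layer-by-layer structural assertions.
#'
#' @param model An `nn_model`.
#' @return Data frame with columns `kind`, `units`, `filters`, `width`,
#'   `pool`, `rate`, `activation`, `bidirectional`.
#' @export
architecture_spec <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  rows <- lapply(model$layers, function(ly) {
    data.frame(kind = ly$type,
               units = if (!is.null(ly$units)) ly$units else NA_integer_,
               filters = if (!is.null(ly$filters)) ly$filters else NA_integer_,
               width = if (!is.null(ly$width)) ly$width else NA_integer_,
               pool = if (ly$type == "maxpool") ly$size else NA_integer_,
               rate = if (!is.null(ly$rate)) ly$rate else NA_real_,
               activation = if (!is.null(ly$activation)) ly$activation else NA_character_,
               bidirectional = if (ly$type == "lstm") isTRUE(ly$bidirectional) else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("nn_model '%s': input %d x 4, %d layers, %d parameters\n",
              x$name, x$input_length, length(x$layers), n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `nn_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(ly) {
    if (is.null(ly$params)) return(0L)
    sum(vapply(ly$params, length, integer(1)))
  }, integer(1)))
}

#' Early-stopping bookkeeping on a validation-loss trace
#'
#' Strict-improvement rule: epoch e improves when its loss is below the best
#' loss seen so far; training stops after `patience` consecutive epochs
#' without improvement.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Number of non-improving epochs tolerated.
#' @return List with `stopped_epoch` and `best_epoch`.
#' @export
early_stop_trace <- function(val_losses, patience) {
  best <- Inf
  best_epoch <- 0L
  since <- 0L
  stopped <- length(val_losses)
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) {
        stopped <- e
        break
      }
    }
  }
  list(stopped_epoch = stopped, best_epoch = best_epoch)
}

#' Train a sequence model on a chromosome split
#'
#' Optimizes binary cross-entropy with Adam on the train partition,
#' monitoring validation loss each epoch; stops early after
#' `config$patience` epochs without improvement and restores the weights of
#' the best validation epoch. Weights are re-initialized from
#' `config$seed`, so two trainings with the same seed and data coincide.
#'
#' @param model An `nn_model` from [build_architecture()].
#' @param split A `tss_split` (train and validation must be non-empty), or a
#'   list with `x_train`, `y_train`, `x_val`, `y_val` (arrays/labels) for
#'   pre-encoded data.
#' @param config A [training_config()].
#' @return List with `model` (trained) and `history` (class
#'   `training_history`: per-epoch `train_loss`, `val_loss`, `stopped_epoch`,
#'   `best_epoch`).
#' @export
train_network <- function(model, split, config = training_config()) {
  stopifnot(inherits(model, "nn_model"), inherits(config, "training_config"))
  if (inherits(split, "tss_split")) {
    if (nrow(split$train$instances) == 0L || nrow(split$validation$instances) == 0L) {
      stop("train and validation partitions must be non-empty", call. = FALSE)
    }
    x_train <- one_hot_array(split$train$instances$sequence)
    y_train <- dataset_labels(split$train)
    x_val <- one_hot_array(split$validation$instances$sequence)
    y_val <- dataset_labels(split$validation)
  } else {
    x_train <- split$x_train; y_train <- as_binary_labels(split$y_train)
    x_val <- split$x_val; y_val <- as_binary_labels(split$y_val)
    if (is.null(x_train) || is.null(x_val) || dim(x_train)[1L] == 0L ||
        dim(x_val)[1L] == 0L) {
      stop("train and validation partitions must be non-empty", call. = FALSE)
    }
  }
  if (dim(x_train)[2L] != model$input_length) {
    stop(sprintf("window length %d does not match model input length %d",
                 dim(x_train)[2L], model$input_length), call. = FALSE)
  }
  model <- init_model_params(model, config$seed)
  state <- adam_init(model)
  n <- dim(x_train)[1L]
  step <- 0L
  train_loss <- numeric(0)
  val_loss <- numeric(0)
  best <- Inf
  best_epoch <- 0L
  best_params <- NULL
  since <- 0L
  stopped <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(n)
    starts <- seq(1L, n, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      Xb <- x_train[idx, , , drop = FALSE]
      yb <- y_train[idx]
      fwd <- nn_forward(model, Xb, train = TRUE)
      p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
      batch_losses[bi] <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
      dZ <- matrix((fwd$p - yb) / length(yb), ncol = 1L)
      grads <- nn_backward(model, fwd$caches, dZ)
      step <- step + 1L
      upd <- adam_step(model, state, grads, config$learning_rate, step)
      model <- upd$model
      state <- upd$state
    }
    train_loss[epoch] <- mean(batch_losses)
    pv <- nn_predict(model, x_val)
    val_loss[epoch] <- binary_cross_entropy(y_val, pv, clip_eps = 1e-12)
    if (val_loss[epoch] < best) {
      best <- val_loss[epoch]
      best_epoch <- epoch
      best_params <- lapply(model$layers, `[[`, "params")
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= config$patience) {
        stopped <- epoch
        break
      }
    }
    stopped <- epoch
  }
  if (!is.null(best_params)) {
    for (i in seq_along(model$layers)) {
      if (!is.null(best_params[[i]])) model$layers[[i]]$params <- best_params[[i]]
    }
  }
  history <- structure(list(train_loss = train_loss, val_loss = val_loss,
                            stopped_epoch = stopped, best_epoch = best_epoch),
                       class = "training_history")
  list(model = model, history = history)
}

#' Predicted probabilities from a trained network
#'
#' @param model A trained `nn_model`.
#' @param instances A `tss_dataset`, a character vector of sequences, or a
#'   pre-encoded `(n, L, 4)` array.
#' @return Probabilities of the positive class, order preserved; empty input
#'   yields an empty vector.
#' @export
predict_proba <- function(model, instances) {
  stopifnot(inherits(model, "nn_model"))
  if (inherits(instances, "tss_dataset")) instances <- instances$instances$sequence
  if (is.character(instances)) {
    if (length(instances) == 0L) return(numeric(0))
    instances <- one_hot_array(instances)
  }
  if (length(dim(instances)) != 3L || dim(instances)[2L] != model$input_length ||
      dim(instances)[3L] != 4L) {
    if (dim(instances)[1L] == 0L) return(numeric(0))
    stop(sprintf("input shape (%s) does not match model input %d x 4",
                 paste(dim(instances), collapse = ", "), model$input_length),
         call. = FALSE)
  }
  nn_predict(model, instances)
}
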