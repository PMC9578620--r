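# Training protocol: Adam with decoupled-from-nothing L2 weight decay (the
# classical Adam + weight-decay-in-gradient variant), mini-batches, and
# best-validation checkpointing.

#' Training protocol
#'
#' Defaults are the study's stated protocol: Adam with learning rate 1e-4,
#' weight decay 2e-4, betas (0.9, 0.999), batch size 300, 100 epochs, best
#' validation snapshot retained.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to the gradient.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epsilon Adam denominator offset.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param shuffle Reshuffle training pairs every epoch (seeded). Default TRUE.
#' @return List of class `training_protocol`.
#' @export
training_protocol <- function(learning_rate = 1e-4, weight_decay = 2e-4,
                              beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                              batch_size = 300L, epochs = 100L,
                              shuffle = TRUE) {
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), shuffle = isTRUE(shuffle)),
            class = "training_protocol")
}

# walk two identically shaped nested lists of numerics
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else {
    f(a)
  }
}

adam_state_init <- function(params) {
  list(m = tree_map(params, function(p) p * 0),
       v = tree_map(params, function(p) p * 0), t = 0L)
}

# one Adam update; weight decay enters the gradient (L2 regularization)
adam_update <- function(params, grads, state, proto) {
  state$t <- state$t + 1L
  grads <- tree_map2(grads, params, function(g, p) g + proto$weight_decay * p)
  state$m <- tree_map2(state$m, grads, function(m, g) proto$beta1 * m + (1 - proto$beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) proto$beta2 * v + (1 - proto$beta2) * g^2)
  bc1 <- 1 - proto$beta1^state$t
  bc2 <- 1 - proto$beta2^state$t
  step <- tree_map2(state$m, state$v, function(m, v) {
    proto$learning_rate * (m / bc1) / (sqrt(v / bc2) + proto$epsilon)
  })
  params <- tree_map2(params, step, `-`)
  list(params = params, state = state)
}

# batched forward pass (bounded memory)
predict_in_chunks <- function(model, inputs, chunk = 300L) {
  n <- nrow(inputs)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    out[start:end] <- predict(model, inputs[start:end, , drop = FALSE])
  }
  out
}

#' Train a predictor with best-validation checkpointing
#'
#' Minimizes mean-squared error over mini-batches; after every epoch the
#' validation loss is evaluated and the parameter snapshot with the lowest
#' validation loss so far is retained.
#'
#' @param model A `respigate_model` from [init_predictor()].
#' @param train_windows,val_windows [windowed_dataset()]s.
#' @param protocol A [training_protocol()].
#' @param seed Seed for batch shuffling; defaults to the model spec's seed.
#' @param verbose Print per-epoch losses.
#' @return Object of class `train_state`: `model` (best snapshot), `spec`,
#'   `protocol`, `epoch`, `val_loss` (final), `best_val_loss`,
#'   `train_history`, `val_history`.
#' @export
train <- function(model, train_windows, val_windows, protocol = training_protocol(),
                  seed = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "respigate_model"),
            inherits(train_windows, "windowed_dataset"),
            inherits(val_windows, "windowed_dataset"))
  if (length(train_windows$targets) == 0L || length(val_windows$targets) == 0L) {
    stop("invalid training: empty dataset", call. = FALSE)
  }
  if (is.null(seed)) seed <- model$spec$seed

  X <- train_windows$inputs
  y <- train_windows$targets
  n <- length(y)

  with_local_seed(seed, {
    opt <- adam_state_init(model$params)
    best_val <- Inf
    best_params <- model$params
    train_hist <- numeric(protocol$epochs)
    val_hist <- numeric(protocol$epochs)

    for (epoch in seq_len(protocol$epochs)) {
      idx <- if (protocol$shuffle) sample.int(n) else seq_len(n)
      starts <- seq(1L, n, by = protocol$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        b <- idx[s:min(s + protocol$batch_size - 1L, n)]
        res <- model_grad(model, X[b, , drop = FALSE], y[b])
        if (!is.finite(res$loss)) {
          stop(sprintf("divergence: non-finite loss at epoch %d", epoch),
               call. = FALSE)
        }
        epoch_loss <- epoch_loss + res$loss * length(b)
        upd <- adam_update(model$params, res$grads, opt, protocol)
        model$params <- upd$params
        opt <- upd$state
      }
      train_hist[epoch] <- epoch_loss / n

      val_pred <- predict_in_chunks(model, val_windows$inputs)
      val_loss <- mean((val_pred - val_windows$targets)^2)
      val_hist[epoch] <- val_loss
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- model$params
      }
      if (verbose) {
        message(sprintf("epoch %3d  train %.6f  val %.6f  best %.6f",
                        epoch, train_hist[epoch], val_loss, best_val))
      }
    }

    best_model <- model
    best_model$params <- best_params
    structure(
      list(model = best_model, spec = model$spec, protocol = protocol,
           epoch = protocol$epochs, val_loss = val_hist[protocol$epochs],
           best_val_loss = best_val, train_history = train_hist,
           val_history = val_hist),
      class = "train_state"
    )
  })
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state %s>: %d epochs, best val MSE %.6g (final %.6g)\n",
              x$spec$kind, x$epoch, x$best_val_loss, x$val_loss))
  invisible(x)
}

#' Save a trained model checkpoint
#'
#' Single-file archive holding the best parameter snapshot, the architecture
#' spec, the training protocol and the best validation loss, with a format
#' version field.
#'
#' @param state A [train()] result (or a `respigate_model`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  obj <- if (inherits(state, "train_state")) {
    list(version = 1L, spec = state$spec, protocol = state$protocol,
         params = state$model$params, best_val_loss = state$best_val_loss)
  } else if (inherits(state, "respigate_model")) {
    list(version = 1L, spec = state$spec, protocol = NULL,
         params = state$params, best_val_loss = NA_real_)
  } else {
    stop("state must be a train_state or respigate_model", call. = FALSE)
  }
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `respigate_model` with attribute `protocol` and `best_val_loss`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version)) stop("not a respigate checkpoint", call. = FALSE)
  model <- structure(list(spec = obj$spec, params = obj$params),
                     class = "respigate_model")
  attr(model, "protocol") <- obj$protocol
  attr(model, "best_val_loss") <- obj$best_val_loss
  model
}
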