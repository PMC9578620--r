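# Predictor specifications, parameter initialization and forward wrappers for
# the three sequence forecasters. Heavy lifting lives in src/nn.cpp.

#' Specify a sequence predictor
#'
#' Architectures follow the comparison study this package reproduces: the
#' recurrent models use 15 stacked layers of 3 hidden units; the Transformer
#' uses 8 attention heads with 6 encoder and 6 decoder layers (4 of each is
#' the documented alternative depth).
#'
#' @param kind One of `"lstm"`, `"bilstm"`, `"transformer"`.
#' @param hidden_layers Stacked recurrent layers (recurrent kinds). Default 15.
#' @param hidden_size Hidden units per recurrent layer. Default 3.
#' @param n_heads Attention heads (transformer). Default 8.
#' @param n_encoder_layers,n_decoder_layers Transformer stack depths. Default 6.
#' @param model_dim Attention embedding width; must be divisible by `n_heads`.
#'   Default 32, ample for a scalar signal and sized for single-CPU training
#'   (64 is the conventional small-Transformer width and works unchanged).
#' @param feedforward_dim Width of the position-wise feed-forward nets.
#'   Default 128.
#' @param tied_input_candidate If TRUE the input gate shares the candidate
#'   weights `W_c`, `b_c` (the literal gate equations); default FALSE, the
#'   standard LSTM with separate input-gate parameters.
#' @param init_gain Multiplier on the uniform fan-in initialization range of
#'   the recurrent weight matrices. A plain `1/sqrt(fan_in)` range annihilates
#'   the signal through 15 stacked 3-unit cells (each layer damps its input by
#'   ~0.2, so the top of the stack sees nothing and only the mean can be fit);
#'   the default gain of 4 gives near-unity signal gain per layer at this
#'   width. Ignored by the transformer.
#' @param forget_bias Initial forget-gate bias of every LSTM cell. Default 1,
#'   the standard device to keep the cell-state path open at the start of
#'   training.
#' @param seed Initialization seed.
#' @return Object of class `predictor_spec`.
#' @export
predictor_spec <- function(kind = c("lstm", "bilstm", "transformer"),
                           hidden_layers = 15L, hidden_size = 3L,
                           n_heads = 8L, n_encoder_layers = 6L,
                           n_decoder_layers = 6L, model_dim = 32L,
                           feedforward_dim = 128L,
                           tied_input_candidate = FALSE, init_gain = 4,
                           forget_bias = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "transformer" && model_dim %% n_heads != 0) {
    stop("model_dim must be divisible by n_heads", call. = FALSE)
  }
  if (hidden_layers < 1 || hidden_size < 1) {
    stop("hidden_layers and hidden_size must be >= 1", call. = FALSE)
  }
  structure(
    list(kind = kind, hidden_layers = as.integer(hidden_layers),
         hidden_size = as.integer(hidden_size), n_heads = as.integer(n_heads),
         n_encoder_layers = as.integer(n_encoder_layers),
         n_decoder_layers = as.integer(n_decoder_layers),
         model_dim = as.integer(model_dim),
         feedforward_dim = as.integer(feedforward_dim),
         tied_input_candidate = isTRUE(tied_input_candidate),
         init_gain = init_gain, forget_bias = forget_bias,
         seed = as.integer(seed)),
    class = "predictor_spec"
  )
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nrow, ncol, fan_in) {
  matrix(stats::runif(nrow * ncol, -1, 1) / sqrt(fan_in), nrow, ncol)
}

init_lstm_layer <- function(H, I, gain = 1, forget_bias = 0) {
  fi <- (H + I) / gain^2  # effective fan-in: widens the uniform range by gain
  list(Wf = init_mat(H, H + I, fi), Wi = init_mat(H, H + I, fi),
       Wc = init_mat(H, H + I, fi), Wo = init_mat(H, H + I, fi),
       bf = rep(forget_bias, H), bi = rep(0, H), bc = rep(0, H), bo = rep(0, H))
}

init_attn <- function(d) {
  list(Wq = init_mat(d, d, d), Wk = init_mat(d, d, d), Wv = init_mat(d, d, d),
       Wo = init_mat(d, d, d), bq = rep(0, d), bk = rep(0, d),
       bv = rep(0, d), bo = rep(0, d))
}

init_ln <- function(d) list(g = rep(1, d), b = rep(0, d))

init_ff <- function(d, dff) {
  list(W1 = init_mat(d, dff, d), b1 = rep(0, dff),
       W2 = init_mat(dff, d, dff), b2 = rep(0, d))
}

#' Initialize a predictor's parameters
#'
#' Weights drawn uniformly with fan-in scaling under the spec's seed; biases
#' start at zero, layer-norm gains at one.
#'
#' @param spec A [predictor_spec()].
#' @return Object of class `respigate_model`: list with `spec` and `params`.
#' @export
init_predictor <- function(spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  params <- with_local_seed(spec$seed, {
    H <- spec$hidden_size
    gn <- spec$init_gain
    fb <- spec$forget_bias
    if (spec$kind == "lstm") {
      layers <- lapply(seq_len(spec$hidden_layers), function(l) {
        init_lstm_layer(H, if (l == 1L) 1L else H, gn, fb)
      })
      list(layers = layers, wout = stats::runif(H, -1, 1) / sqrt(H), bout = 0)
    } else if (spec$kind == "bilstm") {
      layers <- lapply(seq_len(spec$hidden_layers), function(l) {
        I <- if (l == 1L) 1L else H
        list(fwd = init_lstm_layer(H, I, gn, fb),
             bwd = init_lstm_layer(H, I, gn, fb),
             Wfy = init_mat(H, H, H / gn^2), Wby = init_mat(H, H, H / gn^2),
             by = rep(0, H))
      })
      list(layers = layers, wout = stats::runif(H, -1, 1) / sqrt(H), bout = 0)
    } else {
      d <- spec$model_dim
      list(
        wemb = stats::runif(d, -1, 1), bemb = rep(0, d),
        enc = lapply(seq_len(spec$n_encoder_layers), function(l) {
          list(attn = init_attn(d), ln1 = init_ln(d),
               ff = init_ff(d, spec$feedforward_dim), ln2 = init_ln(d))
        }),
        dec = lapply(seq_len(spec$n_decoder_layers), function(l) {
          list(self_attn = init_attn(d), ln1 = init_ln(d),
               cross = init_attn(d), ln2 = init_ln(d),
               ff = init_ff(d, spec$feedforward_dim), ln3 = init_ln(d))
        }),
        wout = stats::runif(d, -1, 1) / sqrt(d), bout = 0
      )
    }
  })
  structure(list(spec = spec, params = params), class = "respigate_model")
}

#' @export
print.respigate_model <- function(x, ...) {
  s <- x$spec
  arch <- if (s$kind == "transformer") {
    sprintf("d=%d, heads=%d, enc=%d, dec=%d, ff=%d", s$model_dim, s$n_heads,
            s$n_encoder_layers, s$n_decoder_layers, s$feedforward_dim)
  } else {
    sprintf("%d layers x %d units", s$hidden_layers, s$hidden_size)
  }
  cat(sprintf("<respigate_model %s>: %s\n", s$kind, arch))
  invisible(x)
}

#' Predict targets for a batch of input windows
#'
#' @param object A `respigate_model`.
#' @param inputs Matrix of input windows (rows) or a single window vector.
#' @param ... Unused.
#' @return Numeric vector of one-point forecasts.
#' @export
predict.respigate_model <- function(object, inputs, ...) {
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1L)
  s <- object$spec
  as.numeric(switch(s$kind,
    lstm = cpp_lstm_predict(object$params, inputs, s$tied_input_candidate),
    bilstm = cpp_bilstm_predict(object$params, inputs, s$tied_input_candidate),
    transformer = cpp_transformer_predict(object$params, inputs, s$n_heads)
  ))
}

# MSE loss and full gradient tree for one mini-batch
model_grad <- function(model, inputs, targets) {
  s <- model$spec
  switch(s$kind,
    lstm = cpp_lstm_grad(model$params, inputs, targets, s$tied_input_candidate),
    bilstm = cpp_bilstm_grad(model$params, inputs, targets, s$tied_input_candidate),
    transformer = cpp_transformer_grad(model$params, inputs, targets, s$n_heads)
  )
}

#' One LSTM cell step
#'
#' The gate equations: `f = sigma(W_f [h, x] + b_f)`, `i = sigma(W_i [h, x] +
#' b_i)`, `g = tanh(W_c [h, x] + b_c)`, `C = f * C_prev + i * g`,
#' `o = sigma(W_o [h, x] + b_o)`, `h = o * tanh(C)`. With
#' `tied = TRUE` the input gate reuses `W_c`, `b_c`.
#'
#' @param x_t Input vector.
#' @param h_prev,C_prev Previous hidden and cell state (length = hidden size).
#' @param parameters List with `Wf`, `Wi`, `Wc`, `Wo` (each `H x (H + I)`) and
#'   `bf`, `bi`, `bc`, `bo` (length `H`).
#' @param tied Share `W_c`, `b_c` between input gate and candidate.
#' @return List with `h`, `C` and the gate activations `f`, `i`, `g`, `o`.
#' @export
lstm_cell_step <- function(x_t, h_prev, C_prev, parameters, tied = FALSE) {
  res <- cpp_lstm_cell(as.numeric(x_t), as.numeric(h_prev), as.numeric(C_prev),
                       parameters, tied)
  lapply(res, drop)
}

#' Combine forward and backward LSTM outputs
#'
#' `y = W_fy h_forward + W_by h_backward + b_y`, the affine merge of a
#' bidirectional layer's two directions.
#'
#' @param h_forward,h_backward Hidden-state vectors from the two directions.
#' @param parameters List with matrices `Wfy`, `Wby` and vector `by`.
#' @return Numeric vector `y`.
#' @export
bilstm_combine <- function(h_forward, h_backward, parameters) {
  if (ncol(parameters$Wfy) != length(h_forward) ||
      ncol(parameters$Wby) != length(h_backward)) {
    stop("dimension mismatch in bilstm_combine", call. = FALSE)
  }
  drop(parameters$Wfy %*% h_forward + parameters$Wby %*% h_backward +
         parameters$by)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`. An optional additive mask (e.g. `-Inf` above
#' the diagonal for look-ahead masking) is applied to the scores before the
#' softmax.
#'
#' @param Q,K,V Matrices; `Q` and `K` share the feature dimension `d_k`, `K`
#'   and `V` the sequence length.
#' @param mask Optional additive mask, `nrow(Q) x nrow(K)`.
#' @return List with `context` (`nrow(Q) x ncol(V)`) and the attention
#'   `weights` (rows sum to 1).
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    mask[!is.finite(mask)] <- -1e30
  }
  cpp_attention(as.matrix(Q), as.matrix(K), as.matrix(V), mask)
}

#' Look-ahead (causal) mask
#'
#' Additive mask that forbids position `i` from attending to positions
#' `j > i`.
#'
#' @param n Sequence length.
#' @return `n x n` matrix, 0 on and below the diagonal, `-Inf` above.
#' @export
look_ahead_mask <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- -Inf
  m
}

#' Forward pass of a recurrent predictor on one window
#'
#' @param input_window Numeric vector of `T_s` samples.
#' @param model An initialized or trained `respigate_model` of kind `lstm` or
#'   `bilstm`.
#' @return Scalar forecast.
#' @export
recurrent_forward <- function(input_window, model) {
  stopifnot(model$spec$kind %in% c("lstm", "bilstm"))
  as.numeric(predict(model, input_window))
}

#' Forward pass of the Transformer on one window
#'
#' The window is embedded, summed with sinusoidal position encodings, passed
#' through the encoder stack; the decoder consumes the window delayed by one
#' position under a look-ahead mask, attends to the encoder memory, and its
#' final position is mapped to the scalar forecast.
#'
#' @param input_window Numeric vector of `T_s` samples.
#' @param model A `respigate_model` of kind `transformer`.
#' @return Scalar forecast.
#' @export
transformer_forward <- function(input_window, model) {
  stopifnot(model$spec$kind == "transformer")
  as.numeric(predict(model, input_window))
}
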