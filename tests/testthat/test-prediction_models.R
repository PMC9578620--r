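# LSTM cell closed forms and oracle, attention properties, transformer
# causality, gradient correctness, and the training contract.

test_that("zero-parameter LSTM cell matches its closed form", {
  p <- const_lstm_params(H = 2, I = 1, w = 0, b = 0)
  st <- lstm_cell_step(0.7, c(0, 0), c(0, 0), p)
  expect_equal(st$f, c(0.5, 0.5))
  expect_equal(st$i, c(0.5, 0.5))
  expect_equal(st$o, c(0.5, 0.5))
  expect_equal(st$g, c(0, 0))
  expect_equal(st$C, c(0, 0))
  expect_equal(st$h, c(0, 0))

  # nonzero previous cell state: C = 0.5 c, h = 0.5 tanh(0.5 c)
  cprev <- c(0.8, -0.4)
  st <- lstm_cell_step(0.7, c(0, 0), cprev, p)
  expect_equal(st$C, 0.5 * cprev, tolerance = 1e-12)
  expect_equal(st$h, 0.5 * tanh(0.5 * cprev), tolerance = 1e-12)
})

test_that("lstm_cell_step matches a hand-coded scalar oracle", {
  sigmoid <- function(x) 1 / (1 + exp(-x))
  set.seed(101)
  for (i in 1:100) {
    H <- 2L; I <- 1L
    p <- list(Wf = matrix(rnorm(H * (H + I)), H), Wi = matrix(rnorm(H * (H + I)), H),
              Wc = matrix(rnorm(H * (H + I)), H), Wo = matrix(rnorm(H * (H + I)), H),
              bf = rnorm(H), bi = rnorm(H), bc = rnorm(H), bo = rnorm(H))
    x <- rnorm(I); h0 <- rnorm(H); c0 <- rnorm(H)
    z <- c(h0, x)
    f <- sigmoid(p$Wf %*% z + p$bf)
    ii <- sigmoid(p$Wi %*% z + p$bi)
    g <- tanh(p$Wc %*% z + p$bc)
    o <- sigmoid(p$Wo %*% z + p$bo)
    C <- f * c0 + ii * g
    h <- o * tanh(C)
    st <- lstm_cell_step(x, h0, c0, p)
    expect_equal(st$h, drop(h), tolerance = 1e-10)
    expect_equal(st$C, drop(C), tolerance = 1e-10)
  }
  # tied variant: input gate reuses Wc, bc
  p <- const_lstm_params(H = 2, I = 1, w = 0.3, b = 0.1)
  st_tied <- lstm_cell_step(0.5, c(0.1, 0.2), c(0, 0), p, tied = TRUE)
  sig_in <- sigmoid(drop(p$Wc %*% c(0.1, 0.2, 0.5) + p$bc))
  expect_equal(st_tied$i, sig_in, tolerance = 1e-12)
})

test_that("lstm_cell_step rejects inconsistent dimensions", {
  p <- const_lstm_params(H = 2, I = 1)
  expect_error(lstm_cell_step(c(1, 2), c(0, 0), c(0, 0), p), "mismatch")
})

test_that("bilstm_combine is the affine merge of the two directions", {
  p <- list(Wfy = diag(2), Wby = matrix(0, 2, 2), by = c(0, 0))
  expect_equal(bilstm_combine(c(1, 2), c(9, 9), p), c(1, 2))
  p <- list(Wfy = matrix(0, 2, 2), Wby = diag(2), by = c(0, 0))
  expect_equal(bilstm_combine(c(9, 9), c(3, 4), p), c(3, 4))
  p <- list(Wfy = matrix(1:4, 2), Wby = matrix(4:1, 2), by = c(0.5, -0.5))
  expect_equal(bilstm_combine(c(1, 1), c(2, 2), p),
               drop(p$Wfy %*% c(1, 1) + p$Wby %*% c(2, 2) + p$by))
  expect_error(bilstm_combine(c(1, 2, 3), c(1, 2), p), "mismatch")
})

test_that("scaled_dot_attention has softmax structure and matches brute force", {
  # single key/value: output is V regardless of Q
  out <- scaled_dot_attention(matrix(rnorm(8), 2, 4), matrix(1:4, 1),
                              matrix(c(5, 6, 7), 1))
  expect_equal(out$context, matrix(c(5, 6, 7), 2, 3, byrow = TRUE))

  # saturation: query aligned with one orthogonal key picks that value
  K <- diag(3)
  V <- matrix(rnorm(9), 3)
  out <- scaled_dot_attention(matrix(c(60, 0, 0), 1), K, V)
  expect_equal(drop(out$context), V[1, ], tolerance = 1e-8)

  set.seed(77)
  for (i in 1:100) {
    Q <- matrix(rnorm(12), 3, 4); K <- matrix(rnorm(12), 3, 4)
    V <- matrix(rnorm(15), 3, 5)
    S <- Q %*% t(K) / sqrt(4)
    A <- exp(S) / rowSums(exp(S))
    out <- scaled_dot_attention(Q, K, V)
    expect_equal(out$context, A %*% V, tolerance = 1e-10)
    expect_equal(rowSums(out$weights), rep(1, 3), tolerance = 1e-6)
  }

  # masked rows still sum to one over the allowed positions
  m <- look_ahead_mask(4)
  out <- scaled_dot_attention(matrix(rnorm(16), 4), matrix(rnorm(16), 4),
                              matrix(rnorm(16), 4), mask = m)
  expect_equal(rowSums(out$weights), rep(1, 4), tolerance = 1e-6)
  expect_true(all(out$weights[upper.tri(out$weights)] == 0))
  expect_error(scaled_dot_attention(matrix(1, 2, 3), matrix(1, 2, 4), matrix(1, 2, 2)),
               "feature dimension")
})

test_that("transformer decoder respects the look-ahead mask", {
  spec <- predictor_spec("transformer", n_heads = 2, n_encoder_layers = 1,
                         n_decoder_layers = 1, model_dim = 8,
                         feedforward_dim = 16, seed = 3L)
  model <- init_predictor(spec)
  w <- with_seed_rnorm(5, 12)
  base <- transformer_forward(w, model)
  expect_true(is.finite(base))
  expect_lt(abs(base), 10)  # sane scale for standardized input at init

  # deterministic inference
  expect_identical(base, transformer_forward(w, model))

  # the readout sits at the final decoder position, which may attend to every
  # encoder position; but perturbing the LAST window sample must not reach the
  # decoder self-attention stream (the decoder input is the delayed window)
  # -> check causality on the decoder input directly: identical delayed input
  # plus identical encoder memory gives identical prediction
  w2 <- w; w2[12] <- w2[12] + 1
  expect_false(identical(transformer_forward(w2, model), base))
})

test_that("recurrent_forward closed forms and reductions hold", {
  spec <- predictor_spec("lstm", hidden_layers = 2, hidden_size = 3, seed = 2L)
  model <- init_predictor(spec)
  # zero all parameters: prediction equals the output bias
  model$params <- rapply(model$params, function(x) x * 0, how = "replace")
  model$params$bout <- 1.75
  expect_equal(recurrent_forward(with_seed_rnorm(6, 20), model), 1.75)

  # hidden_layers = 1, hidden_size = 1: matches a scalar R recurrence
  spec1 <- predictor_spec("lstm", hidden_layers = 1, hidden_size = 1, seed = 9L)
  m1 <- init_predictor(spec1)
  w <- with_seed_rnorm(8, 10)
  sigmoid <- function(x) 1 / (1 + exp(-x))
  p <- m1$params$layers[[1]]
  h <- 0; C <- 0
  for (x in w) {
    z <- c(h, x)
    f <- sigmoid(sum(p$Wf * z) + p$bf)
    i <- sigmoid(sum(p$Wi * z) + p$bi)
    g <- tanh(sum(p$Wc * z) + p$bc)
    C <- f * C + i * g
    h <- sigmoid(sum(p$Wo * z) + p$bo) * tanh(C)
  }
  expect_equal(recurrent_forward(w, m1), h * m1$params$wout + m1$params$bout,
               tolerance = 1e-10)

  # Bi-LSTM with zeroed backward path reduces to the forward LSTM map
  specb <- predictor_spec("bilstm", hidden_layers = 1, hidden_size = 2, seed = 4L)
  mb <- init_predictor(specb)
  mb$params$layers[[1]]$Wby <- matrix(0, 2, 2)
  mb$params$layers[[1]]$by <- c(0, 0)
  ml <- init_predictor(predictor_spec("lstm", hidden_layers = 1, hidden_size = 2, seed = 4L))
  ml$params$layers[[1]] <- mb$params$layers[[1]]$fwd
  ml$params$wout <- drop(t(mb$params$layers[[1]]$Wfy) %*% mb$params$wout)
  ml$params$bout <- mb$params$bout + sum(mb$params$wout * mb$params$layers[[1]]$by)
  w <- with_seed_rnorm(10, 15)
  expect_equal(recurrent_forward(w, mb), recurrent_forward(w, ml),
               tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on tiny models", {
  specs <- list(
    predictor_spec("lstm", hidden_layers = 2, hidden_size = 3, seed = 7L),
    predictor_spec("bilstm", hidden_layers = 1, hidden_size = 2, seed = 8L),
    predictor_spec("transformer", n_heads = 2, n_encoder_layers = 1,
                   n_decoder_layers = 1, model_dim = 8, feedforward_dim = 16,
                   seed = 9L)
  )
  get_el <- function(p, path) { for (i in path$idx) p <- p[[i]]; p[path$k] }
  set_el <- function(p, path, v) {
    rec <- function(p, d) {
      if (d > length(path$idx)) { p[path$k] <- v; return(p) }
      p[[path$idx[d]]] <- rec(p[[path$idx[d]]], d + 1); p
    }
    rec(p, 1)
  }
  leaf_paths <- function(params) {
    out <- list()
    rec <- function(p, idx) {
      if (is.list(p)) for (i in seq_along(p)) rec(p[[i]], c(idx, i))
      else for (k in seq_len(length(p))) out[[length(out) + 1]] <<- list(idx = idx, k = k)
    }
    rec(params, integer(0))
    out
  }
  set.seed(202)
  for (spec in specs) {
    model <- init_predictor(spec)
    X <- matrix(rnorm(3 * 6), 3, 6)
    y <- rnorm(3)
    g <- respigate:::model_grad(model, X, y)
    paths <- leaf_paths(model$params)
    for (path in paths[sample(length(paths), 10)]) {
      eps <- 1e-6
      loss_at <- function(params) {
        m <- model; m$params <- params
        mean((predict(m, X) - y)^2)
      }
      ng <- (loss_at(set_el(model$params, path, get_el(model$params, path) + eps)) -
               loss_at(set_el(model$params, path, get_el(model$params, path) - eps))) / (2 * eps)
      ag <- get_el(g$grads, path)
      expect_lt(abs(ng - ag) / max(1e-4, abs(ng) + abs(ag)), 1e-4)
    }
  }
})

test_that("training fits constants, memorizes tiny data, and checkpoints", {
  set.seed(303)
  L <- 10L
  # constant targets: loss < 1e-4 within 20 epochs
  Xc <- matrix(rnorm(40 * L), 40, L)
  dc <- windowed_dataset(Xc, rep(2.5, 40), 500, 500, 20)
  st <- train(init_predictor(predictor_spec("lstm", hidden_layers = 2, seed = 1L)),
              dc, dc, training_protocol(epochs = 20, learning_rate = 1e-1,
                                        weight_decay = 0, batch_size = 20))
  expect_lt(st$best_val_loss, 1e-4)
  expect_equal(unname(predict(st$model, Xc[1:5, ])), rep(2.5, 5), tolerance = 0.05)

  # overfit sanity: 10 pairs, loss falls by >= 100x from epoch 1
  Xs <- matrix(rnorm(10 * L), 10, L)
  ds <- windowed_dataset(Xs, rnorm(10), 500, 500, 20)
  st <- train(init_predictor(predictor_spec("lstm", hidden_layers = 2, seed = 2L)),
              ds, ds, training_protocol(epochs = 200, learning_rate = 2e-2,
                                        weight_decay = 0, batch_size = 10))
  expect_lt(st$train_history[200] * 100, st$train_history[1])

  # checkpoint contract: best validation loss <= final-epoch validation loss
  expect_lte(st$best_val_loss, st$val_loss)
  expect_true(all(diff(cummin(st$val_history)) <= 0))

  # seeded training reproducibility
  st2 <- train(init_predictor(predictor_spec("lstm", hidden_layers = 2, seed = 2L)),
               ds, ds, training_protocol(epochs = 5, learning_rate = 2e-2))
  st3 <- train(init_predictor(predictor_spec("lstm", hidden_layers = 2, seed = 2L)),
               ds, ds, training_protocol(epochs = 5, learning_rate = 2e-2))
  expect_identical(st2$best_val_loss, st3$best_val_loss)
  expect_identical(st2$model$params, st3$model$params)

  expect_error(train(init_predictor(predictor_spec("lstm", seed = 1L)),
                     windowed_dataset(matrix(0, 0, L), numeric(0), 500, 500, 20),
                     ds), "empty dataset")
})

test_that("checkpoints round-trip through save and load", {
  set.seed(7)
  X <- matrix(rnorm(20 * 10), 20, 10)
  ds <- windowed_dataset(X, rnorm(20), 500, 500, 20)
  st <- train(init_predictor(predictor_spec("lstm", hidden_layers = 1, seed = 3L)),
              ds, ds, training_protocol(epochs = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, st$model$params)
  expect_equal(predict(back, X), predict(st$model, X))
  expect_equal(attr(back, "best_val_loss"), st$best_val_loss)
})
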