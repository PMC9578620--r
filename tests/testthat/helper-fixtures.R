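# Small deterministic fixtures shared across test files.

# strictly periodic cos^2n trace: no jitter, drift or noise
periodic_config <- function(duration_s = 20, n = 1, period = 4, rate = 20) {
  generator_config(base_period_s = period, exponent_n = n,
                   duration_s = duration_s, sampling_rate_hz = rate, seed = 1L)
}

sine_signal <- function(period_s = 4, duration_s = 20, rate = 20, phase = 0,
                        amplitude = 1, id = "sine") {
  t <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  respiration_signal(amplitude * sin(2 * pi * t / period_s + phase),
                     sampling_rate_hz = rate, id = id)
}

with_seed_rnorm <- function(seed, n, sd = 1) {
  withr::with_seed(seed, stats::rnorm(n, 0, sd))
}

# tiny LSTM parameter list with all weights/biases constant
const_lstm_params <- function(H = 2, I = 1, w = 0, b = 0) {
  m <- matrix(w, H, H + I)
  list(Wf = m, Wi = m, Wc = m, Wo = m,
       bf = rep(b, H), bi = rep(b, H), bc = rep(b, H), bo = rep(b, H))
}
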