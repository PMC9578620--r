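# Millimetre gating error at the 30%/70% respiratory phases.

test_that("scale_to_motion maps the global range onto the target excursion", {
  sig <- respiration_signal(c(-1, 0, 1, 0.5, -0.5), id = "s")
  mm <- scale_to_motion(sig, 10)
  expect_equal(range(mm$samples), c(-5, 5))
  expect_equal(max(mm$samples), 5)

  # idempotence
  mm2 <- scale_to_motion(mm, 10)
  expect_equal(mm2$samples, mm$samples, tolerance = 1e-12)

  # arbitrary signal: peak-to-peak exactly 10 within 1e-9
  x <- respiration_signal(with_seed_rnorm(3, 200), id = "r")
  expect_lt(abs(diff(range(scale_to_motion(x, 10)$samples)) - 10), 1e-9)
  # 5 mm variant
  expect_lt(abs(diff(range(scale_to_motion(x, 5)$samples)) - 5), 1e-9)

  expect_error(scale_to_motion(respiration_signal(rep(1, 5))), "degenerate")

  # the recorded map reproduces the transform on a companion series
  y <- apply_motion_map(x, scale_to_motion(x, 10)$metadata$mm_map)
  expect_equal(y$samples, scale_to_motion(x, 10)$samples, tolerance = 1e-12)
})

test_that("phase_decompose places the 30%/70% gates inside each cycle", {
  # cosine peaks at t = 0, 4, 8, ...: cycles start at peaks
  t <- seq(0, 20 - 0.05, by = 0.05)
  sig <- respiration_signal(cos(2 * pi * t / 4), id = "c")
  pd <- phase_decompose(sig)
  expect_s3_class(pd, "phase_decomposition")
  expect_equal(nrow(pd$cycles), length(pd$peak_times) - 1L)
  # gates at 0.3 and 0.7 of each measured cycle
  expect_equal(pd$cycles$gate_30_s, pd$cycles$start_s + 0.3 * (pd$cycles$end_s - pd$cycles$start_s))
  expect_equal(pd$cycles$gate_70_s, pd$cycles$start_s + 0.7 * (pd$cycles$end_s - pd$cycles$start_s))
  # the first detectable full cycle starts at the t = 4 peak (the t = 0 peak
  # sits on the record boundary): 30%/70% gates at start + 1.2 s / + 2.8 s
  expect_equal(pd$cycles$gate_30_s[1] - pd$cycles$start_s[1], 1.2, tolerance = 0.06)
  expect_equal(pd$cycles$gate_70_s[1] - pd$cycles$start_s[1], 2.8, tolerance = 0.06)
  # all gates strictly inside their cycles
  expect_true(all(pd$cycles$gate_30_s > pd$cycles$start_s &
                    pd$cycles$gate_70_s < pd$cycles$end_s))
})

test_that("jittered cycles get gates at 0.3/0.7 of their own period", {
  sig <- generate_signal(generator_config(period_jitter_sd = 0.5,
                                          duration_s = 60, seed = 12L))
  pd <- phase_decompose(sig, min_prominence = 0.1)
  # independent per-cycle oracle from the detected peak times
  pk <- detect_extrema(sig, min_prominence = 0.1)$peaks$time_s
  expect_gt(sd(diff(pk)), 0.2)  # periods really vary
  for (k in seq_len(nrow(pd$cycles))) {
    expect_equal(pd$cycles$gate_30_s[k], pk[k] + 0.3 * (pk[k + 1] - pk[k]),
                 tolerance = 1e-9)
    expect_equal(pd$cycles$gate_70_s[k], pk[k] + 0.7 * (pk[k + 1] - pk[k]),
                 tolerance = 1e-9)
  }
})

test_that("gating_error is zero for a perfect prediction and shift-invariant", {
  sig <- scale_to_motion(sine_signal(duration_s = 40), 10)
  rep0 <- gating_error(sig, sig, latency_ms = 500)
  expect_equal(rep0$mean_error_mm, 0)
  expect_equal(rep0$max_error_mm, 0)
  expect_true(all(rep0$errors$error_mm == 0))
  expect_lte(rep0$mean_error_mm, rep0$max_error_mm)

  # adding the same constant to both signals changes nothing
  a <- sig; a$samples <- a$samples + 3
  b <- sig; b$samples <- b$samples + 3
  rep1 <- gating_error(a, b, 500)
  expect_equal(rep1$errors$error_mm, rep0$errors$error_mm, tolerance = 1e-12)
})

test_that("a delayed sinusoid reproduces the closed-form gating error", {
  # z(t) = 5 sin(2 pi t / T); prediction = actual delayed by dt
  T_s <- 4; dt <- 0.25; rate <- 20
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  z <- function(tt) 5 * sin(2 * pi * tt / T_s)
  actual <- respiration_signal(z(t), rate, id = "act")
  delayed <- respiration_signal(z(t - dt), rate, id = "del")
  rep <- gating_error(actual, delayed, 500)
  # closed form at each gate time of the predicted signal
  for (r in seq_len(nrow(rep$errors))) {
    tg <- rep$errors$time_s[r]
    expect_equal(rep$errors$error_mm[r], abs(z(tg) - z(tg - dt)),
                 tolerance = 1e-6 + 2e-3)  # linear interpolation at 20 Hz
  }
  expect_gt(rep$mean_error_mm, 0)
})

test_that("both gating-error conventions run and agree for perfect prediction", {
  sig <- scale_to_motion(sine_signal(duration_s = 40), 10)
  r1 <- gating_error(sig, sig, 300, convention = "predicted_gates")
  r2 <- gating_error(sig, sig, 300, convention = "actual_vs_actual")
  expect_equal(r1$mean_error_mm, 0)
  expect_equal(r2$mean_error_mm, 0)
})

test_that("feasibility_study reports the full pattern x latency x model grid", {
  sigs <- list(
    regular = lapply(1:2, function(i) {
      generate_signal(generator_config(noise_sd = 0.01, duration_s = 40,
                                       seed = 40L + i), id = paste0("r", i))
    }),
    type1 = lapply(1:2, function(i) {
      generate_signal(generator_config(period_jitter_sd = 0.6, duration_s = 40,
                                       seed = 50L + i), id = paste0("t", i))
    })
  )
  models <- list(`300` = list(oracle = "oracle"), `500` = list(oracle = "oracle"))
  df <- feasibility_study(sigs, models, latencies_ms = c(300, 500),
                          n_cases_per_pattern = 2)
  # patterns x latencies x models x gates
  expect_equal(nrow(df), 2 * 2 * 1 * 2)
  expect_setequal(unique(df$gate_phase), c(30, 70))
  expect_true(all(df$mean_error_mm == 0))
  expect_true(all(df$max_error_mm == 0))

  expect_error(
    feasibility_study(sigs, models, latencies_ms = c(300, 700)),
    "configuration error")
})
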