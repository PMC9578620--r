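# Synthetic respiration generator: periodicity, determinism, jitter calibration.

test_that("zero-jitter trace is strictly periodic with the configured cycles", {
  sig <- generate_signal(periodic_config(duration_s = 20, n = 1, period = 4))
  expect_s3_class(sig, "respiration_signal")
  expect_length(sig$samples, 400L)

  # exactly 5 full cycles: sample k and sample k + 80 agree everywhere
  lag <- 80L
  expect_lt(max(abs(sig$samples[1:(400 - lag)] - sig$samples[(lag + 1):400])), 1e-12)

  # autocorrelation at the period lag equals lag-0 within 1e-9 (mean removed)
  x <- sig$samples - mean(sig$samples)
  n <- length(x) - lag
  ac_lag <- sum(x[1:n] * x[(lag + 1):(lag + n)]) / n
  ac_0 <- sum(x[1:n]^2) / n
  expect_lt(abs(ac_lag - ac_0), 1e-9)

  # identical peak heights across cycles
  pk <- detect_extrema(sig, min_prominence = 0.2)$peaks$amplitude
  expect_lt(diff(range(pk)), 1e-12)
})

test_that("identical seed and config give bit-identical samples", {
  cfg <- generator_config(period_jitter_sd = 0.4, amplitude_jitter_sd = 0.2,
                          noise_sd = 0.05, drift_rate = 0.002,
                          duration_s = 60, seed = 7L)
  s1 <- generate_signal(cfg)
  s2 <- generate_signal(cfg)
  expect_identical(s1$samples, s2$samples)
  s3 <- generate_signal(generator_config(period_jitter_sd = 0.4,
                                         amplitude_jitter_sd = 0.2,
                                         noise_sd = 0.05, drift_rate = 0.002,
                                         duration_s = 60, seed = 8L))
  expect_false(identical(s1$samples, s3$samples))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(base_period_s = -1), "must be > 0")
  expect_error(generator_config(noise_sd = -0.1), ">= 0")
  expect_error(generator_config(exponent_n = 0.5), ">= 1")
  expect_error(generator_config(base_period_s = NaN), "finite")
})

test_that("measured peak-to-valley amplitude SD matches the configured jitter", {
  # ~100 cycles; amplitude jitter 0.3 of base amplitude
  cfg <- generator_config(amplitude_jitter_sd = 0.3, duration_s = 400,
                          seed = 21L)
  sig <- generate_signal(cfg)
  ex <- detect_extrema(sig, min_prominence = 0.1)
  # per-cycle peak-to-valley: each peak minus the following valley
  pk <- ex$peaks; vl <- ex$valleys
  p2v <- vapply(seq_len(nrow(pk)), function(i) {
    nxt <- vl$time_s > pk$time_s[i]
    if (any(nxt)) pk$amplitude[i] - vl$amplitude[which(nxt)[1]] else NA_real_
  }, numeric(1))
  p2v <- p2v[!is.na(p2v)]
  expect_gt(length(p2v), 80)
  measured_sd <- sd(p2v)
  expect_lt(abs(measured_sd - 0.3), 0.2 * 0.3)
})

test_that("measured cycle-period SD matches the configured jitter", {
  cfg <- generator_config(period_jitter_sd = 0.5, duration_s = 500, seed = 22L)
  sig <- generate_signal(cfg)
  ex <- detect_extrema(sig, min_prominence = 0.1)
  periods <- diff(ex$peaks$time_s)
  expect_gt(length(periods), 90)
  expect_lt(abs(sd(periods) - 0.5), 0.2 * 0.5)
})

test_that("generate_cohort labels and sizes follow the group structure", {
  cohort <- generate_cohort(1, seed = 5L, duration_range_s = c(30, 40))
  expect_length(cohort, 4L)
  expect_setequal(vapply(cohort, function(s) s$metadata$group, character(1)),
                  c("regular", "type1", "type2", "type3"))

  cohort <- generate_cohort(3, seed = 5L, duration_range_s = c(30, 40))
  expect_length(cohort, 12L)
  durs <- vapply(cohort, `[[`, numeric(1), "duration_s")
  expect_true(all(durs >= 30 & durs <= 40))
  # reproducible under the same seed
  cohort2 <- generate_cohort(3, seed = 5L, duration_range_s = c(30, 40))
  expect_identical(lapply(cohort, `[[`, "samples"),
                   lapply(cohort2, `[[`, "samples"))
})

test_that("regular-group irregularity is below type3 for separated knobs", {
  cohort <- generate_cohort(4, seed = 9L, duration_range_s = c(60, 90))
  profs <- lapply(cohort, irregularity_profile)
  gg <- vapply(profs, `[[`, character(1), "generating_group")
  amp <- vapply(profs, `[[`, numeric(1), "amplitude_irregularity")
  pha <- vapply(profs, `[[`, numeric(1), "phase_irregularity")
  comb <- scale(amp)[, 1] + scale(pha)[, 1]
  expect_lt(max(comb[gg == "regular"]), min(comb[gg == "type3"]))
})

test_that("signal CSV round-trips through the writer and reader", {
  sig <- generate_signal(periodic_config(duration_s = 10), id = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, path, config = sig$metadata$config)
  back <- read_signal_csv(path)
  expect_equal(back$samples, sig$samples, tolerance = 1e-5)
  expect_equal(back$sampling_rate_hz, 20)
  expect_true(file.exists(paste0(path, ".json")))

  # non-uniform timestamps are a format error
  df <- utils::read.csv(path)
  df$time_s[10] <- df$time_s[10] + 0.02
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(read_signal_csv(bad), "non-uniform")
})
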