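# Z-scoring, Savitzky-Golay filtering, window construction, cohort split.

test_that("zscore_normalize uses the population sd and is idempotent", {
  sig <- respiration_signal(c(1, 2, 3), id = "z")
  z <- zscore_normalize(sig)
  expect_equal(z$samples, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_lt(abs(mean(z$samples)), 1e-9)
  expect_lt(abs(sqrt(mean(z$samples^2)) - 1), 1e-9)

  z2 <- zscore_normalize(z)
  expect_equal(z2$samples, z$samples, tolerance = 1e-9)

  expect_error(zscore_normalize(respiration_signal(c(5, 5, 5))), "degenerate")
})

test_that("savitzky_golay reproduces polynomials exactly", {
  t <- seq(-2, 2, length.out = 41)
  cubic <- 2 - t + 0.5 * t^2 - 0.3 * t^3
  # interior samples are exact under mirror padding; the reflected edge
  # windows no longer see a cubic, so exactness there needs edge = "interp"
  sm <- savitzky_golay(cubic, 5, 3)
  expect_lt(max(abs(sm[3:39] - cubic[3:39])), 1e-9)
  sm_i <- savitzky_golay(cubic, 5, 3, edge = "interp")
  expect_lt(max(abs(sm_i - cubic)), 1e-9)

  const <- rep(4.2, 20)
  expect_equal(savitzky_golay(const, 5, 2), const, tolerance = 1e-12)
})

test_that("savitzky_golay matches a brute-force sliding polynomial fit", {
  set.seed(33)
  x <- rnorm(60)
  w <- 7L; p <- 2L; h <- 3L
  # oracle: explicit least-squares fit in every window of the mirror-padded
  # series, evaluated at the window centre
  padded <- c(rev(x[2:(h + 1)]), x, rev(x[(60 - h):(60 - 1)]))
  oracle <- vapply(seq_along(x), function(i) {
    win <- padded[(i):(i + w - 1)]
    tt <- seq(-h, h)
    unname(stats::lm.fit(outer(tt, 0:p, `^`), win)$coefficients[1])
  }, numeric(1))
  expect_lt(max(abs(savitzky_golay(x, w, p) - oracle)), 1e-9)

  expect_error(savitzky_golay(x, 6, 2), "odd")
  expect_error(savitzky_golay(x, 5, 5), "greater than polyorder")
})

test_that("make_windows produces the closed-form pair count and alignment", {
  sig <- respiration_signal(seq_len(50), id = "w")  # 50 samples at 20 Hz
  ds <- make_windows(sig, 1000, 500)                # L = 20, H = 10
  expect_s3_class(ds, "windowed_dataset")
  expect_equal(nrow(ds$inputs), 50 - 20 - 10 + 1)
  expect_equal(ncol(ds$inputs), 20)
  # stride one; target H samples past the window end
  expect_equal(ds$inputs[1, ], as.numeric(1:20))
  expect_equal(ds$inputs[2, ], as.numeric(2:21))
  expect_equal(ds$targets[1], 30)
  expect_equal(ds$targets[21], 50)

  one <- make_windows(respiration_signal(seq_len(30)), 1000, 500)
  expect_equal(length(one$targets), 1L)
  expect_equal(one$targets, 30)  # sample index 30 (1-based) = last sample

  expect_error(make_windows(respiration_signal(seq_len(29)), 1000, 500),
               "too short")
  expect_error(make_windows(sig, 1025, 500), "multiple of the sampling")
})

test_that("window count matches N - L - H + 1 across random geometries", {
  set.seed(44)
  for (i in 1:200) {
    L <- sample(2:30, 1)
    H <- sample(1:20, 1)
    N <- L + H - 1 + sample(0:40, 1)
    sig <- respiration_signal(rnorm(N), sampling_rate_hz = 20)
    if (N < L + H) {
      expect_error(make_windows(sig, L * 50, H * 50))
    } else {
      ds <- make_windows(sig, L * 50, H * 50)
      expect_equal(length(ds$targets), N - L - H + 1)
    }
  }
})

test_that("split_cohort reserves whole test signals and splits 7:3 in time", {
  cohort <- generate_cohort(3, seed = 2L, duration_range_s = c(30, 40))
  split <- split_cohort(cohort, n_test = 4, train_fraction = 0.7, seed = 9L)
  expect_length(split$test_ids, 4L)
  expect_length(split$trainval_ids, 8L)
  expect_length(intersect(split$test_ids, split$trainval_ids), 0L)

  n_samp <- vapply(cohort, function(s) length(s$samples), integer(1))
  names(n_samp) <- vapply(cohort, `[[`, character(1), "id")
  for (id in split$trainval_ids) {
    expect_equal(split$boundaries[[id]], round(0.7 * n_samp[[id]]))
  }

  split2 <- split_cohort(cohort, n_test = 4, train_fraction = 0.7, seed = 9L)
  expect_identical(split$test_ids, split2$test_ids)

  expect_error(split_cohort(cohort, n_test = 12), "smaller than the cohort")
})

test_that("validation windows never straddle or precede the split boundary", {
  cohort <- generate_cohort(2, seed = 6L, duration_range_s = c(30, 40))
  split <- split_cohort(cohort, n_test = 2, seed = 1L)
  ds <- build_datasets(cohort, split, 1000, 500)
  # training windows fit inside [1, boundary]: every input value must be
  # reproducible from the head segment alone
  for (id in split$trainval_ids) {
    sig <- zscore_normalize(cohort[[which(vapply(cohort, `[[`, character(1), "id") == id)]])
    b <- split$boundaries[[id]]
    n_train_windows <- b - 20 - 10 + 1
    expect_equal(sum(ds$train$source_ids == id), n_train_windows)
    n_val_windows <- (length(sig$samples) - b) - 20 - 10 + 1
    expect_equal(sum(ds$validation$source_ids == id), n_val_windows)
    # first validation target reconstructs from the tail segment only
    first_val <- ds$validation$targets[ds$validation$source_ids == id][1]
    expect_equal(first_val, sig$samples[b + 30])
  }
})
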