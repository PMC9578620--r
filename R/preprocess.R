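# Signal preprocessing: per-signal Z-scoring, Savitzky-Golay smoothing of
# predicted series, sliding-window dataset construction, and the cohort split.

#' Z-score normalize a signal
#'
#' Standardizes a signal with its own mean and population standard deviation
#' (divisor N). Per-signal normalization aligns the baselines of traces whose
#' recording device has no physical unit.
#'
#' @param signal A [respiration_signal()] with >= 2 samples and nonzero spread.
#' @return The standardized [respiration_signal()] (mean 0, population sd 1).
#' @export
zscore_normalize <- function(signal) {
  stopifnot(inherits(signal, "respiration_signal"))
  x <- signal$samples
  if (length(x) < 2) stop("need >= 2 samples to normalize", call. = FALSE)
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) stop("degenerate signal: zero spread", call. = FALSE)
  out <- signal
  out$samples <- (x - mu) / sd_pop
  out$metadata$zscore <- list(mean = mu, sd = sd_pop)
  out
}

# Convolution weights for the centre value of a degree-`polyorder` least
# squares fit over `window` symmetric points: first row of (A'A)^{-1} A'.
sg_coefficients <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  drop(solve(crossprod(A), t(A))[1, ])
}

#' Savitzky-Golay smoothing filter
#'
#' Replaces each sample by the centre value of a least-squares polynomial fit
#' to its surrounding window. Used as a postprocessing step on the models'
#' predicted series; raw signals are never filtered before entering a network.
#'
#' @param series Numeric vector, length >= `window_samples`.
#' @param window_samples Odd window length, > `polyorder`. Default 5 (250 ms at
#'   20 Hz).
#' @param polyorder Polynomial degree. Default 2.
#' @param edge Edge handling: `"mirror"` reflects the series about its end
#'   points (excluding them); `"interp"` evaluates the first/last full-window
#'   fit at the edge positions, which reproduces polynomials exactly
#'   everywhere.
#' @return Smoothed numeric vector, same length as `series`.
#' @export
savitzky_golay <- function(series, window_samples = 5L, polyorder = 2L,
                           edge = c("mirror", "interp")) {
  edge <- match.arg(edge)
  w <- as.integer(window_samples)
  p <- as.integer(polyorder)
  if (w %% 2L == 0L || w <= p) {
    stop("window_samples must be odd and greater than polyorder", call. = FALSE)
  }
  n <- length(series)
  if (n < w) stop("series shorter than the filter window", call. = FALSE)
  h <- (w - 1L) %/% 2L
  cw <- sg_coefficients(w, p)
  if (edge == "mirror") {
    padded <- c(rev(series[2:(h + 1L)]), series, rev(series[(n - h):(n - 1L)]))
    out <- as.numeric(stats::filter(padded, rev(cw), sides = 2L))[(h + 1L):(h + n)]
  } else {
    out <- as.numeric(stats::filter(series, rev(cw), sides = 2L))
    # evaluate the first and last full-window polynomial fits at edge offsets
    A <- outer(seq(-h, h), 0:p, `^`)
    proj <- A %*% solve(crossprod(A), t(A))
    out[1:h] <- (proj %*% series[1:w])[1:h]
    out[(n - h + 1L):n] <- (proj %*% series[(n - w + 1L):n])[(h + 2L):w]
  }
  out
}

#' Windowed (input sequence, target point) dataset
#'
#' @param inputs Matrix, one row per pair, `L` columns of consecutive samples.
#' @param targets Numeric vector; `targets[i]` is the amplitude `H` samples
#'   after the last sample of `inputs[i, ]`.
#' @param ts_ms,pt_ms Input-window length and prediction horizon in ms.
#' @param sampling_rate_hz Sampling rate of the source signals.
#' @param source_ids Originating signal id per pair.
#' @return An object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(inputs, targets, ts_ms, pt_ms, sampling_rate_hz,
                             source_ids = rep("signal", length(targets))) {
  stopifnot(is.matrix(inputs), nrow(inputs) == length(targets),
            length(source_ids) == length(targets))
  structure(
    list(inputs = inputs, targets = as.numeric(targets), ts_ms = ts_ms,
         pt_ms = pt_ms, sampling_rate_hz = sampling_rate_hz,
         source_ids = as.character(source_ids)),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset>: %d pairs, T_s = %d ms (%d samples), P_t = %d ms (%d samples)\n",
              length(x$targets), x$ts_ms, ncol(x$inputs), x$pt_ms,
              round(x$pt_ms / 1000 * x$sampling_rate_hz)))
  invisible(x)
}

ms_to_samples <- function(ms, rate_hz, what) {
  k <- ms / 1000 * rate_hz
  if (ms <= 0 || abs(k - round(k)) > 1e-9 || round(k) < 1) {
    stop(sprintf("%s (%g ms) must be a positive multiple of the sampling interval (%g ms)",
                 what, ms, 1000 / rate_hz), call. = FALSE)
  }
  as.integer(round(k))
}

#' Build sliding windows from one signal
#'
#' Stride-one sliding pairs: window `i` covers samples `i .. i+L-1` and its
#' target is sample `i+L+H-1`, where `L = ts_ms` and `H = pt_ms` converted to
#' samples. Pair count is `N - L - H + 1`.
#'
#' @param signal A [respiration_signal()].
#' @param ts_ms Input-window length in ms (positive multiple of the sampling
#'   interval). Default 1000 ms, the standard condition.
#' @param pt_ms Prediction horizon in ms. Default 500 ms.
#' @return A [windowed_dataset()].
#' @export
make_windows <- function(signal, ts_ms = 1000, pt_ms = 500) {
  stopifnot(inherits(signal, "respiration_signal"))
  rate <- signal$sampling_rate_hz
  L <- ms_to_samples(ts_ms, rate, "ts_ms")
  H <- ms_to_samples(pt_ms, rate, "pt_ms")
  x <- signal$samples
  n_pairs <- length(x) - L - H + 1L
  if (n_pairs < 1L) {
    stop(sprintf("signal too short: %d samples < L + H = %d", length(x), L + H),
         call. = FALSE)
  }
  idx <- seq_len(n_pairs)
  inputs <- matrix(x[outer(idx, 0:(L - 1L), `+`)], nrow = n_pairs)
  targets <- x[idx + L + H - 1L]
  windowed_dataset(inputs, targets, ts_ms, pt_ms, rate,
                   source_ids = rep(signal$id, n_pairs))
}

#' Split a cohort into test signals and per-signal train/validation segments
#'
#' Reserves `n_test` whole signals for testing (seeded draw). Every remaining
#' signal is split temporally: the first `train_fraction` of its samples feed
#' training windows, the remainder validation windows. A temporal (not random)
#' split avoids leaking future samples into training.
#'
#' @param signals List of [respiration_signal()].
#' @param n_test Number of whole signals reserved for the test role.
#' @param train_fraction Fraction of each remaining signal used for training.
#'   Default 0.7 (the 7:3 split).
#' @param seed Seed for the test-signal draw.
#' @return An object of class `data_split`: `test_ids`, `trainval_ids`, and
#'   `boundaries` (named integer vector: last training sample per signal).
#' @export
split_cohort <- function(signals, n_test, train_fraction = 0.7, seed = 1L) {
  ids <- vapply(signals, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("signal ids must be unique", call. = FALSE)
  if (n_test >= length(signals)) {
    stop("n_test must be smaller than the cohort size", call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  test_ids <- with_local_seed(seed, sample(ids, n_test))
  trainval_ids <- setdiff(ids, test_ids)
  n_samp <- vapply(signals, function(s) length(s$samples), integer(1))
  names(n_samp) <- ids
  boundaries <- vapply(trainval_ids, function(id) {
    as.integer(round(train_fraction * n_samp[[id]]))
  }, integer(1))
  structure(list(test_ids = sort(test_ids), trainval_ids = sort(trainval_ids),
                 boundaries = boundaries[sort(trainval_ids)]),
            class = "data_split")
}

# Concatenate windowed datasets (same ts/pt/rate).
bind_windows <- function(datasets) {
  datasets <- Filter(Negate(is.null), datasets)
  if (length(datasets) == 0L) stop("no windows to bind", call. = FALSE)
  windowed_dataset(
    do.call(rbind, lapply(datasets, `[[`, "inputs")),
    unlist(lapply(datasets, `[[`, "targets"), use.names = FALSE),
    datasets[[1]]$ts_ms, datasets[[1]]$pt_ms, datasets[[1]]$sampling_rate_hz,
    unlist(lapply(datasets, `[[`, "source_ids"), use.names = FALSE)
  )
}

# Thin a windowed dataset to every `stride`-th pair (training-set subsampling
# for budgeted runs; windows themselves stay stride-one).
thin_windows <- function(ds, stride = 1L) {
  if (stride <= 1L) return(ds)
  keep <- seq(1L, length(ds$targets), by = as.integer(stride))
  windowed_dataset(ds$inputs[keep, , drop = FALSE], ds$targets[keep],
                   ds$ts_ms, ds$pt_ms, ds$sampling_rate_hz, ds$source_ids[keep])
}

#' Build train/validation/test window sets from a split cohort
#'
#' Signals are Z-scored per signal, then windowed. Training windows are drawn
#' from samples before each signal's split boundary, validation windows
#' entirely from samples after it (no pair straddles the boundary). Test
#' signals are windowed whole, kept per signal so metrics can be averaged
#' per signal.
#'
#' @param signals List of [respiration_signal()].
#' @param split A [split_cohort()] result.
#' @param ts_ms,pt_ms Window geometry in ms.
#' @param train_thin Keep every `train_thin`-th training pair (default 1 =
#'   all).
#' @param val_thin Keep every `val_thin`-th validation pair (default 1); the
#'   per-epoch validation loss that drives checkpointing is insensitive to
#'   this subsampling because adjacent windows overlap almost entirely.
#' @param normalize Z-score each signal first (default TRUE).
#' @return List with `train` and `validation` [windowed_dataset()]s and `test`,
#'   a named list of per-signal [windowed_dataset()]s.
#' @export
build_datasets <- function(signals, split, ts_ms = 1000, pt_ms = 500,
                           train_thin = 1L, val_thin = 1L, normalize = TRUE) {
  stopifnot(inherits(split, "data_split"))
  by_id <- stats::setNames(signals, vapply(signals, `[[`, character(1), "id"))
  norm <- function(s) if (normalize) zscore_normalize(s) else s

  train_parts <- list(); val_parts <- list()
  for (id in split$trainval_ids) {
    s <- norm(by_id[[id]])
    b <- split$boundaries[[id]]
    head_sig <- respiration_signal(s$samples[seq_len(b)], s$sampling_rate_hz, id)
    tail_sig <- respiration_signal(s$samples[(b + 1L):length(s$samples)],
                                   s$sampling_rate_hz, id)
    train_parts[[id]] <- thin_windows(make_windows(head_sig, ts_ms, pt_ms),
                                      train_thin)
    val_parts[[id]] <- thin_windows(make_windows(tail_sig, ts_ms, pt_ms),
                                    val_thin)
  }
  test_sets <- lapply(by_id[split$test_ids], function(s) {
    make_windows(norm(s), ts_ms, pt_ms)
  })
  list(train = bind_windows(train_parts), validation = bind_windows(val_parts),
       test = test_sets)
}
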