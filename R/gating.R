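# Clinical gating feasibility: translate prediction error into millimetre
# error at the 30% and 70% respiratory phase gates under an assumed tumor
# excursion (10 mm peak-to-peak by default).

#' Rescale a signal to an assumed tumor excursion
#'
#' Affine map taking the signal's global peak-to-peak range to
#' `peak_to_peak_mm`, centred so the global maximum sits at
#' `+peak_to_peak_mm / 2`. Global (whole-record) scaling preserves per-cycle
#' amplitude irregularity. The map is stored in `metadata$mm_map` so the same
#' transform can be applied to a companion (predicted) series with
#' [apply_motion_map()].
#'
#' @param signal A [respiration_signal()] with nonzero spread.
#' @param peak_to_peak_mm Assumed tumor excursion. Default 10 mm.
#' @return The rescaled signal (amplitudes in mm).
#' @export
scale_to_motion <- function(signal, peak_to_peak_mm = 10) {
  stopifnot(inherits(signal, "respiration_signal"))
  r <- diff(range(signal$samples))
  if (r == 0) stop("degenerate signal: zero spread", call. = FALSE)
  slope <- peak_to_peak_mm / r
  intercept <- peak_to_peak_mm / 2 - slope * max(signal$samples)
  out <- signal
  out$samples <- slope * signal$samples + intercept
  out$metadata$mm_map <- list(slope = slope, intercept = intercept)
  out
}

#' Apply a previously computed mm map to another signal
#'
#' @param signal A [respiration_signal()] (e.g. a predicted series).
#' @param mm_map The `metadata$mm_map` of a [scale_to_motion()] result.
#' @return The mapped signal.
#' @export
apply_motion_map <- function(signal, mm_map) {
  out <- signal
  out$samples <- mm_map$slope * signal$samples + mm_map$intercept
  out$metadata$mm_map <- mm_map
  out
}

#' Decompose a signal into breathing cycles and phase gates
#'
#' Cycles run peak-to-peak (phase origin at the inhalation peak, the 4DCT
#' convention: 0% = peak inhale). Phase increases linearly from 0% at each
#' cycle-start peak to 100% at the next peak; the gate time for phase p% in
#' cycle `[t_k, t_{k+1}]` is `t_k + (p/100) (t_{k+1} - t_k)`.
#'
#' @param signal A [respiration_signal()] with >= 2 detectable peaks.
#' @param gates Phase percentages of the beam on/off gates. Default `c(30,
#'   70)`.
#' @param min_separation_s,min_prominence Passed to [detect_extrema()].
#' @return Object of class `phase_decomposition`: data frame `cycles`
#'   (`cycle`, `start_s`, `end_s`, one `gate_<p>_s` column per gate) and
#'   `peak_times`.
#' @export
phase_decompose <- function(signal, gates = c(30, 70), min_separation_s = 1.5,
                            min_prominence = 0.2) {
  ex <- detect_extrema(signal, min_separation_s, min_prominence)
  pk <- ex$peaks$time_s
  n_cyc <- length(pk) - 1L
  cycles <- data.frame(cycle = seq_len(n_cyc), start_s = pk[-length(pk)],
                       end_s = pk[-1])
  for (p in gates) {
    cycles[[sprintf("gate_%d_s", p)]] <-
      cycles$start_s + (p / 100) * (cycles$end_s - cycles$start_s)
  }
  structure(list(cycles = cycles, peak_times = pk, gates = gates),
            class = "phase_decomposition")
}

interp_amplitude <- function(signal, times) {
  stats::approx(signal_times(signal), signal$samples, xout = times,
                rule = 2)$y
}

#' Millimetre gating error between actual and predicted motion
#'
#' Phase-decomposes the predicted signal and, at each of its 30%/70% (or
#' custom) gate times `t_g`, computes `|actual(t_g) - predicted(t_g)|` with
#' amplitudes linearly interpolated between samples (the default convention:
#' both signals are read at the predicted signal's gate times). The
#' alternative reading compares the actual amplitude at the predicted gate
#' time against the actual amplitude at the actual signal's own gate time.
#'
#' @param actual_mm,predicted_mm [respiration_signal()]s in mm on a common
#'   time grid (same sampling rate and start).
#' @param latency_ms The compensated latency (metadata for the report).
#' @param gates Gate phases in percent. Default `c(30, 70)`.
#' @param convention `"predicted_gates"` (default) or `"actual_vs_actual"`.
#' @param pattern Optional regularity-group label carried into the report.
#' @param ... Passed to [phase_decompose()].
#' @return Object of class `gating_error_report`: data frame `errors`
#'   (`cycle`, `gate`, `time_s`, `error_mm`), `latency_ms`, `pattern`,
#'   `mean_error_mm`, `max_error_mm`.
#' @export
gating_error <- function(actual_mm, predicted_mm, latency_ms,
                         gates = c(30, 70),
                         convention = c("predicted_gates", "actual_vs_actual"),
                         pattern = NA_character_, ...) {
  convention <- match.arg(convention)
  stopifnot(inherits(actual_mm, "respiration_signal"),
            inherits(predicted_mm, "respiration_signal"),
            actual_mm$sampling_rate_hz == predicted_mm$sampling_rate_hz,
            length(actual_mm$samples) == length(predicted_mm$samples))
  pd_pred <- phase_decompose(predicted_mm, gates, ...)
  rows <- list()
  if (convention == "actual_vs_actual") {
    pd_act <- phase_decompose(actual_mm, gates, ...)
    n_cyc <- min(nrow(pd_pred$cycles), nrow(pd_act$cycles))
  }
  for (p in gates) {
    col <- sprintf("gate_%d_s", p)
    tg <- pd_pred$cycles[[col]]
    if (convention == "predicted_gates") {
      err <- abs(interp_amplitude(actual_mm, tg) -
                   interp_amplitude(predicted_mm, tg))
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = pd_pred$cycles$cycle, gate = p, time_s = tg, error_mm = err)
    } else {
      tg <- tg[seq_len(n_cyc)]
      ta <- pd_act$cycles[[col]][seq_len(n_cyc)]
      err <- abs(interp_amplitude(actual_mm, tg) -
                   interp_amplitude(actual_mm, ta))
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = seq_len(n_cyc), gate = p, time_s = tg, error_mm = err)
    }
  }
  errors <- do.call(rbind, rows)
  structure(
    list(errors = errors, latency_ms = latency_ms, pattern = pattern,
         mean_error_mm = mean(errors$error_mm),
         max_error_mm = max(errors$error_mm)),
    class = "gating_error_report"
  )
}

#' @export
print.gating_error_report <- function(x, ...) {
  cat(sprintf(
    "<gating_error_report>: latency %s ms, %d gate errors, mean %.3f mm, max %.3f mm\n",
    format(x$latency_ms), nrow(x$errors), x$mean_error_mm, x$max_error_mm))
  invisible(x)
}

#' Gating feasibility study across patterns, latencies and models
#'
#' For each regularity pattern, latency and model: the model trained at
#' `P_t = latency` forecasts each signal, both series are scaled with the
#' actual signal's mm map, and the gating error is computed. Reported per
#' gate phase: the mean of per-signal mean errors and the overall maximum —
#' the quantities a gating-latency feasibility analysis plots.
#'
#' @param signals_by_pattern Named list: pattern -> list of
#'   [respiration_signal()]s (raw; they are Z-scored here).
#' @param models_by_latency Named list: latency (ms, as character or via
#'   order) -> named list of trained `respigate_model`s (or `"oracle"`) per
#'   model kind.
#' @param latencies_ms Latencies to evaluate. Default `c(300, 500, 700)`.
#' @param motion_mm Assumed peak-to-peak tumor excursion. Default 10.
#' @param ts_ms Input-window length. Default 1000.
#' @param n_cases_per_pattern Signals evaluated per pattern. Default 10.
#' @param gates Gate phases. Default `c(30, 70)`.
#' @param ... Passed to [gating_error()] / [phase_decompose()].
#' @return Data frame with columns `pattern`, `model`, `latency_ms`,
#'   `gate_phase`, `mean_error_mm`, `max_error_mm`, `n_cycles`.
#' @export
feasibility_study <- function(signals_by_pattern, models_by_latency,
                              latencies_ms = c(300, 500, 700), motion_mm = 10,
                              ts_ms = 1000, n_cases_per_pattern = 10,
                              gates = c(30, 70), ...) {
  rows <- list()
  for (lat in latencies_ms) {
    lat_key <- as.character(lat)
    if (!lat_key %in% names(models_by_latency)) {
      stop(sprintf("configuration error: no models trained for latency %d ms", lat),
           call. = FALSE)
    }
    models <- models_by_latency[[lat_key]]
    for (pattern in names(signals_by_pattern)) {
      sigs <- signals_by_pattern[[pattern]]
      sigs <- sigs[seq_len(min(n_cases_per_pattern, length(sigs)))]
      for (kind in names(models)) {
        per_gate <- stats::setNames(
          lapply(gates, function(g) list(means = numeric(0), max = -Inf, n = 0L)),
          as.character(gates))
        for (sig in sigs) {
          z <- zscore_normalize(sig)
          ps <- predicted_signal(models[[kind]], z, ts_ms = ts_ms, pt_ms = lat)
          act_mm <- scale_to_motion(ps$actual, motion_mm)
          pred_mm <- apply_motion_map(ps$predicted, act_mm$metadata$mm_map)
          rep <- gating_error(act_mm, pred_mm, lat, gates = gates,
                              pattern = pattern, ...)
          for (g in gates) {
            gk <- as.character(g)
            e <- rep$errors$error_mm[rep$errors$gate == g]
            per_gate[[gk]]$means <- c(per_gate[[gk]]$means, mean(e))
            per_gate[[gk]]$max <- max(per_gate[[gk]]$max, max(e))
            per_gate[[gk]]$n <- per_gate[[gk]]$n + length(e)
          }
        }
        for (g in gates) {
          gk <- as.character(g)
          rows[[length(rows) + 1L]] <- data.frame(
            pattern = pattern, model = kind, latency_ms = lat, gate_phase = g,
            mean_error_mm = mean(per_gate[[gk]]$means),
            max_error_mm = per_gate[[gk]]$max, n_cycles = per_gate[[gk]]$n)
        }
      }
    }
  }
  do.call(rbind, rows)
}
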