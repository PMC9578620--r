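# Breathing irregularity: peak/valley detection, the mean-of-two-STDs
# irregularity value, and cohort classification into the four regularity
# groups (regular / irregular period / irregular amplitude / both).

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# prominence of a local extremum: height above the higher of the two minima
# separating it from the nearest taller samples (or the record edges)
extremum_prominence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    peak <- x[i]
    left_min <- peak
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (x[j] > peak) break
      left_min <- min(left_min, x[j])
    }
    right_min <- peak
    j <- i
    while (j < n) {
      j <- j + 1L
      if (x[j] > peak) break
      right_min <- min(right_min, x[j])
    }
    peak - max(left_min, right_min)
  }, numeric(1))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(diff(sign(diff(x))) < 0) + 1L
}

# keep at most one extremum per `min_sep` samples, preferring the taller
enforce_separation <- function(idx, height, min_sep) {
  if (length(idx) <= 1L) return(idx)
  ord <- order(-height, idx)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - idx[kept]) >= min_sep)) kept <- c(kept, i)
  }
  sort(idx[kept])
}

#' Detect alternating peaks and valleys of a respiration signal
#'
#' Local maxima/minima filtered by prominence and a minimum temporal
#' separation; strict peak/valley alternation is then enforced by dropping the
#' lesser of two same-kind neighbours.
#'
#' @param signal A [respiration_signal()] with >= 3 samples.
#' @param min_separation_s Minimum spacing between two detected extrema of the
#'   same kind, seconds. Default 1.5 s, shorter than any plausible breath.
#' @param min_prominence Minimum prominence (signal units; ~z-units for
#'   standardized traces). Default 0.2.
#' @return List with data frames `peaks` and `valleys` (`index`, `time_s`,
#'   `amplitude`), alternating in time.
#' @export
detect_extrema <- function(signal, min_separation_s = 1.5, min_prominence = 0.2) {
  stopifnot(inherits(signal, "respiration_signal"))
  x <- signal$samples
  if (length(x) < 3L) stop("insufficient cycles: signal too short", call. = FALSE)
  min_sep <- min_separation_s * signal$sampling_rate_hz

  pick <- function(series) {
    idx <- local_maxima(series)
    if (length(idx)) {
      prom <- extremum_prominence(series, idx)
      idx <- idx[prom >= min_prominence]
    }
    enforce_separation(idx, series[idx], min_sep)
  }
  p_idx <- pick(x)
  v_idx <- pick(-x)

  # alternation: between consecutive same-kind extrema keep the stronger
  if (length(p_idx) && length(v_idx)) {
    ev <- rbind(data.frame(index = p_idx, kind = 1L),
                data.frame(index = v_idx, kind = -1L))
    ev <- ev[order(ev$index), ]
    keep <- rep(TRUE, nrow(ev))
    i <- 1L
    while (i < nrow(ev)) {
      j <- i + 1L
      while (j <= nrow(ev) && !keep[j]) j <- j + 1L
      if (j > nrow(ev)) break
      if (ev$kind[i] == ev$kind[j]) {
        hi <- ev$kind[i] * x[ev$index[i]]
        hj <- ev$kind[j] * x[ev$index[j]]
        if (hi >= hj) keep[j] <- FALSE else { keep[i] <- FALSE; i <- j }
      } else {
        i <- j
      }
    }
    ev <- ev[keep, ]
    p_idx <- ev$index[ev$kind == 1L]
    v_idx <- ev$index[ev$kind == -1L]
  }

  if (length(p_idx) < 2L || length(v_idx) < 2L) {
    stop("insufficient cycles: fewer than 2 peaks or 2 valleys detected",
         call. = FALSE)
  }
  t <- signal_times(signal)
  list(
    peaks = data.frame(index = p_idx, time_s = t[p_idx], amplitude = x[p_idx]),
    valleys = data.frame(index = v_idx, time_s = t[v_idx], amplitude = x[v_idx])
  )
}

#' Irregularity value: mean of the peak-series and valley-series STDs
#'
#' `(STD(peaks) + STD(valleys)) / 2` with population STD. Applied to extremum
#' amplitudes it measures amplitude irregularity; applied to peak-to-peak and
#' valley-to-valley periods it measures phase irregularity.
#'
#' @param peak_series,valley_series Numeric vectors with >= 2 entries each
#'   (amplitudes, or cycle periods in seconds).
#' @return Non-negative scalar.
#' @export
irregularity_value <- function(peak_series, valley_series) {
  if (length(peak_series) < 2L || length(valley_series) < 2L) {
    stop("insufficient cycles: each series needs >= 2 entries", call. = FALSE)
  }
  (pop_sd(peak_series) + pop_sd(valley_series)) / 2
}

#' Irregularity profile of one signal
#'
#' Detects extrema, then computes the amplitude-irregularity value (on
#' extremum amplitudes) and the phase-irregularity value (on peak-to-peak and
#' valley-to-valley periods, seconds).
#'
#' @inheritParams detect_extrema
#' @return An object of class `irregularity_profile`: extrema tables, the two
#'   irregularity values, and `group` (NA until [classify_cohort()] assigns it).
#' @export
irregularity_profile <- function(signal, min_separation_s = 1.5,
                                 min_prominence = 0.2) {
  ex <- detect_extrema(signal, min_separation_s, min_prominence)
  if (nrow(ex$peaks) < 3L || nrow(ex$valleys) < 3L) {
    stop("insufficient cycles: need >= 3 peaks and valleys for period series",
         call. = FALSE)
  }
  structure(
    list(
      signal_id = signal$id,
      peaks = ex$peaks, valleys = ex$valleys,
      amplitude_irregularity = irregularity_value(ex$peaks$amplitude,
                                                  ex$valleys$amplitude),
      phase_irregularity = irregularity_value(diff(ex$peaks$time_s),
                                              diff(ex$valleys$time_s)),
      combined_irregularity = NA_real_,
      group = NA_character_,
      generating_group = signal$metadata$group %||% NA_character_
    ),
    class = "irregularity_profile"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rank_top <- function(value, ids, candidates, k) {
  pool <- candidates[order(-value[candidates], ids[candidates])]
  pool[seq_len(k)]
}

#' Assign regularity groups across a cohort
#'
#' Both irregularity axes are standardized within the cohort (they are
#' incommensurable: amplitude in signal units, period in seconds), then groups
#' of `group_size` are assigned with exclusion in the order: highest combined
#' (sum of both standardized axes) -> `type3`; highest phase irregularity ->
#' `type1` (irregular period); highest amplitude irregularity -> `type2`
#' (irregular amplitude); lowest combined -> `regular`. Ties break by signal
#' id. Signals beyond `4 * group_size` stay unassigned.
#'
#' @param profiles List of [irregularity_profile()].
#' @param group_size Signals per group; cohort must hold >= 4 * group_size.
#' @param flip_axes If TRUE, swap the axes used for type1/type2 (the
#'   alternative reading in which type1 ranks on amplitude irregularity).
#' @return The profiles, with `group` and `combined_irregularity` filled in.
#' @export
classify_cohort <- function(profiles, group_size, flip_axes = FALSE) {
  n <- length(profiles)
  if (n < 4L * group_size) {
    stop("invalid cohort: need at least 4 * group_size signals", call. = FALSE)
  }
  ids <- vapply(profiles, `[[`, character(1), "signal_id")
  amp <- vapply(profiles, `[[`, numeric(1), "amplitude_irregularity")
  pha <- vapply(profiles, `[[`, numeric(1), "phase_irregularity")
  zs <- function(v) if (pop_sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / pop_sd(v)
  z_amp <- zs(amp); z_pha <- zs(pha)
  combined <- z_amp + z_pha
  if (flip_axes) { tmp <- z_amp; z_amp <- z_pha; z_pha <- tmp }

  remaining <- seq_len(n)
  type3 <- rank_top(combined, ids, remaining, group_size)
  remaining <- setdiff(remaining, type3)
  type1 <- rank_top(z_pha, ids, remaining, group_size)
  remaining <- setdiff(remaining, type1)
  type2 <- rank_top(z_amp, ids, remaining, group_size)
  remaining <- setdiff(remaining, type2)
  regular <- rank_top(-combined, ids, remaining, group_size)

  group <- rep(NA_character_, n)
  group[type3] <- "type3"; group[type1] <- "type1"
  group[type2] <- "type2"; group[regular] <- "regular"
  for (i in seq_len(n)) {
    profiles[[i]]$group <- group[i]
    profiles[[i]]$combined_irregularity <- combined[i]
  }
  profiles
}

#' Cohort irregularity report as a data frame
#'
#' @param profiles List of (classified) [irregularity_profile()].
#' @param path Optional CSV output path.
#' @return Data frame with columns `signal_id`, `amp_irr`, `phase_irr`,
#'   `combined_irr`, `group`.
#' @export
irregularity_report <- function(profiles, path = NULL) {
  df <- data.frame(
    signal_id = vapply(profiles, `[[`, character(1), "signal_id"),
    amp_irr = vapply(profiles, `[[`, numeric(1), "amplitude_irregularity"),
    phase_irr = vapply(profiles, `[[`, numeric(1), "phase_irregularity"),
    combined_irr = vapply(profiles, `[[`, numeric(1), "combined_irregularity"),
    group = vapply(profiles, `[[`, character(1), "group")
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
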