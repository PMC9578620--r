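# Synthetic respiration generator: quasi-periodic cos^2n cycles with per-cycle
# period/amplitude jitter, linear baseline drift and additive sample noise.

# Run `code` under a private RNG stream; the caller's .Random.seed is restored.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic respiration generator
#'
#' The waveform family is the cos^2n ("Lujan-style") breathing model: each
#' cycle i has period `tau_i = base_period_s + e_tau` and peak-to-valley
#' amplitude `b_i = base_amplitude + e_b`, with the jitters drawn from
#' zero-mean normals (truncated at `0.5 * base_period_s` and
#' `0.2 * base_amplitude` so no cycle degenerates). Within a cycle the shape is
#' `b_i * cos^(2n)(pi * t / tau_i)` minus its cycle mean; cycles are
#' concatenated continuously, then linear drift `drift_rate * t` and N(0,
#' noise_sd) per-sample noise are added. Larger `exponent_n` sharpens the
#' inhale peak and lengthens the exhale dwell, the asymmetry typical of real
#' surrogate traces.
#'
#' @param base_period_s Mean breathing period in seconds (> 0). Default 4 s,
#'   mid-range of quiet breathing (3-6 s).
#' @param base_amplitude Mean peak-to-valley extent (unitless). Default 1.
#' @param exponent_n Waveform sharpness n >= 1 in cos^(2n). Default 2.
#' @param period_jitter_sd Per-cycle period SD in seconds (>= 0).
#' @param amplitude_jitter_sd Per-cycle amplitude SD (>= 0, amplitude units).
#' @param drift_rate Baseline drift per second. Default 0.
#' @param noise_sd Additive per-sample noise SD (>= 0).
#' @param duration_s Trace length in seconds.
#' @param sampling_rate_hz Sampling rate. Default 20 Hz.
#' @param seed Random-stream initializer; identical seed + config gives
#'   bit-identical output.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(base_period_s = 4, base_amplitude = 1,
                             exponent_n = 2, period_jitter_sd = 0,
                             amplitude_jitter_sd = 0, drift_rate = 0,
                             noise_sd = 0, duration_s = 120,
                             sampling_rate_hz = 20, seed = 1L) {
  cfg <- list(
    base_period_s = base_period_s, base_amplitude = base_amplitude,
    exponent_n = exponent_n, period_jitter_sd = period_jitter_sd,
    amplitude_jitter_sd = amplitude_jitter_sd, drift_rate = drift_rate,
    noise_sd = noise_sd, duration_s = duration_s,
    sampling_rate_hz = sampling_rate_hz, seed = as.integer(seed)
  )
  num <- cfg[setdiff(names(cfg), "seed")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1)))) {
    stop("generator config values must be single finite numbers", call. = FALSE)
  }
  if (cfg$base_period_s <= 0 || cfg$base_amplitude <= 0 ||
      cfg$duration_s <= 0 || cfg$sampling_rate_hz <= 0) {
    stop("base_period_s, base_amplitude, duration_s, sampling_rate_hz must be > 0",
         call. = FALSE)
  }
  if (cfg$exponent_n < 1) stop("exponent_n must be >= 1", call. = FALSE)
  if (cfg$period_jitter_sd < 0 || cfg$amplitude_jitter_sd < 0 || cfg$noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# Mean of cos^(2n)(u) over a full period: (2n-1)!! / (2n)!! = C(2n, n) / 4^n.
cos2n_mean <- function(n) choose(2 * n, n) / 4^n

#' Generate one synthetic respiration signal
#'
#' Builds the trace cycle-by-cycle as described in [generator_config()]. With
#' all jitter, drift and noise zero the trace is exactly periodic.
#'
#' @param config A [generator_config()].
#' @param id Signal identifier stored on the result.
#' @return A [respiration_signal()]; `metadata$config` holds the generator
#'   parameters.
#' @export
generate_signal <- function(config, id = "synthetic") {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  n_samples <- round(config$duration_s * config$sampling_rate_hz)
  if (n_samples < 1) stop("duration too short for one sample", call. = FALSE)

  samples <- with_local_seed(config$seed, {
    # draw cycles until they cover the full duration
    periods <- numeric(0)
    amps <- numeric(0)
    total <- 0
    while (total < config$duration_s) {
      tau <- config$base_period_s +
        (if (config$period_jitter_sd > 0) stats::rnorm(1, 0, config$period_jitter_sd) else 0)
      tau <- max(tau, 0.5 * config$base_period_s)
      b <- config$base_amplitude +
        (if (config$amplitude_jitter_sd > 0) stats::rnorm(1, 0, config$amplitude_jitter_sd) else 0)
      b <- max(b, 0.2 * config$base_amplitude)
      periods <- c(periods, tau)
      amps <- c(amps, b)
      total <- total + tau
    }
    starts <- cumsum(c(0, periods))
    t <- (seq_len(n_samples) - 1) / config$sampling_rate_hz
    cyc <- findInterval(t, starts, rightmost.closed = FALSE)
    cyc[cyc < 1] <- 1L
    cyc[cyc > length(periods)] <- length(periods)
    local_t <- t - starts[cyc]
    m <- cos2n_mean(config$exponent_n)
    x <- amps[cyc] *
      (cos(pi * local_t / periods[cyc])^(2 * config$exponent_n) - m)
    x <- x + config$drift_rate * t
    if (config$noise_sd > 0) x <- x + stats::rnorm(n_samples, 0, config$noise_sd)
    x
  })

  respiration_signal(samples, sampling_rate_hz = config$sampling_rate_hz,
                     id = id, metadata = list(config = unclass(config)))
}

#' Default per-group generator configurations
#'
#' Jitter knobs for the four regularity classes: `regular` (small residual
#' jitter, as trained free-breathing patients show), `type1` (irregular
#' period), `type2` (irregular amplitude), `type3` (both). Values are
#' plausibility choices for guided free breathing, not cohort fits; the knobs
#' are well separated so the irregularity taxonomy can recover the labels.
#'
#' @param base A [generator_config()] supplying the non-jitter fields.
#' @return Named list of four `generator_config` objects.
#' @export
default_group_configs <- function(base = generator_config(noise_sd = 0.02,
                                                          drift_rate = 0.001)) {
  tweak <- function(pj, aj) {
    cfg <- unclass(base)
    cfg$period_jitter_sd <- pj
    cfg$amplitude_jitter_sd <- aj
    do.call(generator_config, cfg)
  }
  list(
    regular = tweak(0.05, 0.02),
    type1   = tweak(0.80, 0.02),   # irregular period
    type2   = tweak(0.05, 0.35),   # irregular amplitude
    type3   = tweak(0.80, 0.35)    # both
  )
}

#' Generate a labeled synthetic cohort
#'
#' `n_per_group` signals for each of the four regularity classes; durations are
#' drawn uniformly from `duration_range_s` (default the range of the clinical
#' recordings this generator emulates, 84.35-272.50 s).
#'
#' @param n_per_group Signals per class, >= 1.
#' @param group_configs Named list of [generator_config()] per class; default
#'   [default_group_configs()].
#' @param seed Master seed; signal seeds and durations derive from it.
#' @param duration_range_s Length-2 numeric, uniform duration range in seconds.
#' @return List of [respiration_signal()]; each has `metadata$group` set to its
#'   generating label.
#' @export
generate_cohort <- function(n_per_group, group_configs = default_group_configs(),
                            seed = 1L, duration_range_s = c(84.35, 272.50)) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  stopifnot(length(duration_range_s) == 2, all(duration_range_s > 0))
  groups <- names(group_configs)
  n_total <- n_per_group * length(groups)
  durations <- with_local_seed(seed, stats::runif(n_total, duration_range_s[1],
                                                  duration_range_s[2]))
  signals <- vector("list", n_total)
  k <- 0L
  for (g in groups) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      cfg <- unclass(group_configs[[g]])
      cfg$duration_s <- durations[k]
      cfg$seed <- as.integer((as.double(seed) * 10007 + k) %% 2147483647)
      sig <- generate_signal(do.call(generator_config, cfg),
                             id = sprintf("%s_%03d", g, i))
      sig$metadata$group <- g
      signals[[k]] <- sig
    }
  }
  signals
}
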