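# End-to-end experiment: simulate -> classify -> split -> train -> evaluate ->
# feasibility, with a JSON config, per-stage seed fan-out, structured logging
# and a hashed artifact manifest.

#' Experiment configuration
#'
#' One serializable object holding every stage's settings. Defaults mirror
#' the study's standard condition (T_s = 1000 ms, P_t = 500 ms, Adam protocol)
#' at a desk-scale cohort size.
#'
#' @param n_per_group Synthetic signals per regularity group.
#' @param duration_range_s Uniform duration range of generated signals.
#' @param n_test Whole signals reserved for the test role.
#' @param train_fraction Temporal train share per signal. Default 0.7.
#' @param ts_grid,pt_grid Window geometries (ms) to sweep.
#' @param models Model kinds to train.
#' @param epochs,batch_size,learning_rate,weight_decay Training protocol
#'   fields (betas stay at 0.9/0.999).
#' @param group_size Signals per regularity group in classification; default
#'   `n_per_group`.
#' @param latencies_ms Feasibility latencies; each must appear in `pt_grid`.
#' @param motion_mm Assumed tumor excursion for gating errors.
#' @param patterns Regularity groups entering the feasibility study.
#' @param n_cases_per_pattern Representative signals per pattern.
#' @param train_thin Keep every k-th training window (budget control).
#' @param val_thin Keep every k-th validation window for the per-epoch
#'   checkpointing loss (budget control).
#' @param seed Master seed; every stage derives its own stream from it.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_per_group = 10, duration_range_s = c(84.35, 272.50),
                              n_test = 10, train_fraction = 0.7,
                              ts_grid = 1000, pt_grid = 500,
                              models = c("lstm", "bilstm", "transformer"),
                              epochs = 100, batch_size = 300,
                              learning_rate = 1e-4, weight_decay = 2e-4,
                              group_size = NULL, latencies_ms = numeric(0),
                              motion_mm = 10,
                              patterns = c("regular", "type1", "type2"),
                              n_cases_per_pattern = 10, train_thin = 1,
                              val_thin = 1, seed = 1L) {
  if (is.null(group_size)) group_size <- n_per_group
  cfg <- list(
    n_per_group = n_per_group, duration_range_s = duration_range_s,
    n_test = n_test, train_fraction = train_fraction, ts_grid = ts_grid,
    pt_grid = pt_grid, models = models, epochs = epochs,
    batch_size = batch_size, learning_rate = learning_rate,
    weight_decay = weight_decay, group_size = group_size,
    latencies_ms = latencies_ms, motion_mm = motion_mm, patterns = patterns,
    n_cases_per_pattern = n_cases_per_pattern, train_thin = train_thin,
    val_thin = val_thin, seed = as.integer(seed)
  )
  if (length(cfg$latencies_ms) && !all(cfg$latencies_ms %in% cfg$pt_grid)) {
    stop("every feasibility latency must appear in pt_grid", call. = FALSE)
  }
  structure(cfg, class = "experiment_config")
}

#' Write / read an experiment config (JSON)
#'
#' Round-trip stable: `read_experiment_config(write_experiment_config(cfg,
#' path))` reproduces `cfg`.
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `path` (writer) / the config (reader).
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, raw)
}

# documented fan-out: stage k of master seed s draws from an LCG-style hash,
# kept below 2^31 so it is a valid R seed
stage_seed <- function(master, k) {
  as.integer((as.double(master) * 7919 + k * 104729) %% 2147483647)
}

log_line <- function(con, stage, msg, verbose = FALSE) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  writeLines(line, con)
  if (verbose) message(line)
}

#' Run a full experiment
#'
#' Executes simulate -> classify -> split/train/evaluate (per model and grid
#' cell) -> feasibility, writing every report to `out_dir`: signal CSVs, the
#' irregularity report, the metrics table, ANOVA summaries, model checkpoints,
#' the feasibility table, a run log, and `manifest.json` listing every
#' artifact with an MD5 content hash (the timing log itself is excluded from
#' hashing, so reruns with an identical config produce byte-identical
#' manifests).
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @param verbose Echo log lines.
#' @return Invisibly, a list with the artifact `manifest`, `metrics`,
#'   `anova`, and `feasibility` results.
#' @export
run_experiment <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, "w")
  on.exit(close(con), add = TRUE)
  t_stage <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      log_line(con, stage, paste("ERROR:", conditionMessage(e)), verbose)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    log_line(con, stage,
             sprintf("done in %.1f s (seed fan-out from %d)",
                     proc.time()[["elapsed"]] - t0, config$seed), verbose)
    res
  }

  # --- simulate ------------------------------------------------------------
  signals <- t_stage({
    cohort <- generate_cohort(config$n_per_group, seed = stage_seed(config$seed, 1),
                              duration_range_s = config$duration_range_s)
    sig_dir <- file.path(out_dir, "signals")
    dir.create(sig_dir, showWarnings = FALSE)
    for (s in cohort) {
      write_signal_csv(s, file.path(sig_dir, paste0(s$id, ".csv")),
                       config = s$metadata$config)
    }
    cohort
  }, "simulate")

  # --- classify ------------------------------------------------------------
  class_df <- t_stage({
    profiles <- lapply(signals, irregularity_profile)
    profiles <- classify_cohort(profiles, config$group_size)
    irregularity_report(profiles, file.path(out_dir, "irregularity.csv"))
  }, "classify")
  groups <- stats::setNames(class_df$group, class_df$signal_id)

  # --- train + evaluate ----------------------------------------------------
  sweep <- t_stage({
    run_sweep(signals, kinds = config$models, ts_grid = config$ts_grid,
              pt_grid = config$pt_grid,
              protocol = training_protocol(
                learning_rate = config$learning_rate,
                weight_decay = config$weight_decay,
                batch_size = config$batch_size, epochs = config$epochs),
              n_test = config$n_test, train_fraction = config$train_fraction,
              seed = stage_seed(config$seed, 2), groups = groups,
              train_thin = config$train_thin, val_thin = config$val_thin,
              verbose = verbose)
  }, "train")

  t_stage({
    utils::write.csv(format_metrics(sweep$metrics),
                     file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    ckpt_dir <- file.path(out_dir, "checkpoints")
    dir.create(ckpt_dir, showWarnings = FALSE)
    for (key in names(sweep$states)) {
      save_checkpoint(sweep$states[[key]], file.path(ckpt_dir, paste0(key, ".rds")))
    }
  }, "write-metrics")

  # --- anova ---------------------------------------------------------------
  anova_out <- t_stage({
    # ANOVA across models on per-signal test RMSE at the first grid cell
    first_ts <- config$ts_grid[1]; first_pt <- config$pt_grid[1]
    split <- sweep$split
    ds <- build_datasets(signals, split, first_ts, first_pt)
    per_model_rmse <- list()
    for (kind in config$models) {
      key <- sprintf("%s_ts%d_pt%d", kind, first_ts, first_pt)
      st <- sweep$states[[key]]
      if (is.null(st)) next
      per_model_rmse[[kind]] <- evaluate_model(st$model, ds$test)$per_signal$rmse
    }
    res <- if (length(per_model_rmse) >= 2) {
      a <- one_way_anova(per_model_rmse)
      list(F = a$F, p_value = a$p_value,
           group_sizes = as.list(a$group_sizes))
    } else {
      list(F = NA, p_value = NA, group_sizes = list())
    }
    jsonlite::write_json(res, file.path(out_dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res
  }, "anova")

  # --- feasibility ---------------------------------------------------------
  feas <- NULL
  if (length(config$latencies_ms)) {
    feas <- t_stage({
      by_pattern <- split(signals, groups[vapply(signals, `[[`, character(1), "id")])
      by_pattern <- by_pattern[intersect(config$patterns, names(by_pattern))]
      models_by_latency <- list()
      for (lat in config$latencies_ms) {
        ml <- list()
        for (kind in config$models) {
          key <- sprintf("%s_ts%d_pt%d", kind, config$ts_grid[1], lat)
          if (is.null(sweep$states[[key]])) {
            stop(sprintf("configuration error: no model for latency %d", lat),
                 call. = FALSE)
          }
          ml[[kind]] <- sweep$states[[key]]$model
        }
        models_by_latency[[as.character(lat)]] <- ml
      }
      df <- feasibility_study(by_pattern, models_by_latency,
                              latencies_ms = config$latencies_ms,
                              motion_mm = config$motion_mm,
                              ts_ms = config$ts_grid[1],
                              n_cases_per_pattern = config$n_cases_per_pattern)
      utils::write.csv(format_metrics(df), file.path(out_dir, "feasibility.csv"),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(mean_error_mm_by_latency = lapply(
          split(df$mean_error_mm, df$latency_ms), mean)),
        file.path(out_dir, "feasibility_summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      df
    }, "feasibility")
  }

  # --- manifest ------------------------------------------------------------
  manifest <- t_stage({
    files <- sort(setdiff(
      list.files(out_dir, recursive = TRUE),
      c("run.log", "manifest.json")))
    hashes <- unname(tools::md5sum(file.path(out_dir, files)))
    mf <- data.frame(file = files, md5 = hashes)
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"), pretty = TRUE)
    mf
  }, "manifest")

  invisible(list(manifest = manifest, metrics = sweep$metrics,
                 anova = anova_out, feasibility = feas))
}

# fixed-precision numeric formatting so CSV artifacts are byte-stable
format_metrics <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- sprintf("%.6f", df[[nm]])
    }
  }
  df
}
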