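# Evaluation: RMSE, Pearson correlation, one-way ANOVA across models, and the
# window-geometry sweep over T_s and P_t.

#' Root-mean-square error
#'
#' @param actual,predicted Equal-length nonzero numeric vectors.
#' @return `sqrt(mean((predicted - actual)^2))`.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted)) {
    stop("invalid input: vectors must be equal nonzero lengths", call. = FALSE)
  }
  sqrt(mean((predicted - actual)^2))
}

#' Pearson correlation coefficient
#'
#' Covariance over the product of standard deviations; lies in [-1, 1] and is
#' invariant under positive affine transforms of either argument.
#'
#' @param actual,predicted Equal-length numeric vectors (>= 2), each with
#'   nonzero variance.
#' @return Correlation in [-1, 1].
#' @export
pearson_cc <- function(actual, predicted) {
  if (length(actual) < 2L || length(actual) != length(predicted)) {
    stop("invalid input: need equal lengths >= 2", call. = FALSE)
  }
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  stats::cor(actual, predicted)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition with equal variances assumed;
#' delegates to [stats::oneway.test()].
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values), e.g. per-signal RMSEs, one list element per model.
#' @return List of class `anova_result`: `F`, `p_value`, `group_sizes`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("invalid input: need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  structure(list(F = unname(ht$statistic), p_value = unname(ht$p.value),
                 group_sizes = lengths(groups)),
            class = "anova_result")
}

#' Predicted series for one signal
#'
#' Slides the model over the signal's windows and assembles the one-point
#' forecasts into a series aligned with the actual targets: element `i` of
#' both series is the amplitude at sample `i + L + H - 1` of the signal. The
#' Savitzky-Golay filter is applied to the predicted series only, as a
#' postprocessing step.
#'
#' @param model A `respigate_model`, or the string `"oracle"` for a perfect
#'   predictor (predicted equals actual).
#' @param signal A [respiration_signal()] (typically already Z-scored).
#' @param ts_ms,pt_ms Window geometry.
#' @param sg Apply the S-G filter to the predictions. Default TRUE.
#' @param sg_window,sg_polyorder Filter parameters.
#' @return List with `actual` and `predicted` [respiration_signal()]s on a
#'   common grid, and `offset_samples`, the index of the first predicted
#'   sample in the source signal.
#' @export
predicted_signal <- function(model, signal, ts_ms = 1000, pt_ms = 500,
                             sg = TRUE, sg_window = 5L, sg_polyorder = 2L) {
  w <- make_windows(signal, ts_ms, pt_ms)
  preds <- if (identical(model, "oracle")) {
    w$targets
  } else {
    predict_in_chunks(model, w$inputs)
  }
  # the oracle bypasses postprocessing: it is the actual series itself
  if (sg && !identical(model, "oracle") && length(preds) >= sg_window) {
    preds <- savitzky_golay(preds, sg_window, sg_polyorder)
  }
  rate <- signal$sampling_rate_hz
  L <- ms_to_samples(ts_ms, rate, "ts_ms")
  H <- ms_to_samples(pt_ms, rate, "pt_ms")
  list(
    actual = respiration_signal(w$targets, rate, paste0(signal$id, "_actual")),
    predicted = respiration_signal(preds, rate, paste0(signal$id, "_pred")),
    offset_samples = L + H - 1L
  )
}

#' Evaluate a trained model on windowed data
#'
#' Metrics are computed per source signal (predicted series S-G filtered
#' first), then averaged across signals; `pooled = TRUE` computes them over
#' all pairs at once instead.
#'
#' @param model A `respigate_model`.
#' @param windows A [windowed_dataset()] or list of them (e.g. the per-signal
#'   test sets of [build_datasets()]).
#' @param sg,sg_window,sg_polyorder Postprocessing filter settings.
#' @param pooled Pool all pairs instead of averaging per signal.
#' @return List: `rmse`, `cc`, `n_pairs`, and `per_signal` data frame.
#' @export
evaluate_model <- function(model, windows, sg = TRUE, sg_window = 5L,
                           sg_polyorder = 2L, pooled = FALSE) {
  if (inherits(windows, "windowed_dataset")) windows <- list(windows)
  per <- list()
  for (w in windows) {
    preds_all <- predict_in_chunks(model, w$inputs)
    for (id in unique(w$source_ids)) {
      sel <- w$source_ids == id
      p <- preds_all[sel]
      a <- w$targets[sel]
      if (sg && length(p) >= sg_window) p <- savitzky_golay(p, sg_window, sg_polyorder)
      per[[length(per) + 1L]] <- data.frame(
        signal_id = id, rmse = rmse(a, p),
        cc = if (stats::sd(a) > 0 && stats::sd(p) > 0) pearson_cc(a, p) else NA_real_,
        n_pairs = length(a))
    }
  }
  df <- do.call(rbind, per)
  if (pooled) {
    # recompute over the pooled pairs
    all_a <- unlist(lapply(windows, `[[`, "targets"))
    all_p <- unlist(lapply(windows, function(w) {
      p <- predict_in_chunks(model, w$inputs)
      if (sg && length(p) >= sg_window) p <- savitzky_golay(p, sg_window, sg_polyorder)
      p
    }))
    list(rmse = rmse(all_a, all_p), cc = pearson_cc(all_a, all_p),
         n_pairs = length(all_a), per_signal = df)
  } else {
    list(rmse = mean(df$rmse), cc = mean(df$cc, na.rm = TRUE),
         n_pairs = sum(df$n_pairs), per_signal = df)
  }
}

metrics_record <- function(model_kind, role, ts_ms, pt_ms, group, ev) {
  data.frame(model = model_kind, role = role, ts_ms = ts_ms, pt_ms = pt_ms,
             group = group, rmse = ev$rmse, cc = ev$cc, n_pairs = ev$n_pairs)
}

#' Sweep window geometries and models
#'
#' Trains every model kind from scratch at each `(T_s, P_t)` grid cell (cells
#' are independent and seed-reproducible), then records validation and test
#' metrics, plus per-regularity-group test metrics when `groups` is given.
#'
#' @param signals Cohort of [respiration_signal()]s.
#' @param kinds Character vector of model kinds.
#' @param ts_grid,pt_grid Window geometries in ms, e.g. `c(1000, 1200, 1400)`
#'   and `c(300, 500, 700, 900)`.
#' @param protocol A [training_protocol()].
#' @param n_test Whole signals reserved for the test role.
#' @param train_fraction Per-signal temporal split. Default 0.7.
#' @param seed Master seed (split, initialization, batching).
#' @param groups Optional named character vector, signal id -> regularity
#'   group, for per-group test records.
#' @param train_thin Keep every k-th training pair (budgeted runs).
#' @param val_thin Keep every k-th validation pair for the per-epoch
#'   checkpointing loss (test metrics are never thinned).
#' @param keep_models Also return the trained models.
#' @param verbose Progress messages.
#' @return List: `metrics` (one data-frame row per record), `states` (named
#'   list of [train()] results, if kept).
#' @export
run_sweep <- function(signals, kinds = c("lstm", "bilstm", "transformer"),
                      ts_grid = 1000, pt_grid = 500,
                      protocol = training_protocol(), n_test = 10,
                      train_fraction = 0.7, seed = 1L, groups = NULL,
                      train_thin = 1L, val_thin = 1L, keep_models = TRUE,
                      verbose = FALSE) {
  split <- split_cohort(signals, n_test, train_fraction, seed)
  records <- list()
  states <- list()
  for (ts_ms in ts_grid) {
    for (pt_ms in pt_grid) {
      ds <- build_datasets(signals, split, ts_ms, pt_ms,
                           train_thin = train_thin, val_thin = val_thin)
      for (kind in kinds) {
        if (verbose) message(sprintf("training %s @ T_s=%d P_t=%d", kind, ts_ms, pt_ms))
        spec <- predictor_spec(kind, seed = as.integer((as.double(seed) * 131 + pt_ms + ts_ms) %% 2147483647))
        st <- train(init_predictor(spec), ds$train, ds$validation, protocol)
        key <- sprintf("%s_ts%d_pt%d", kind, ts_ms, pt_ms)
        if (keep_models) states[[key]] <- st
        ev_val <- evaluate_model(st$model, ds$validation)
        ev_test <- evaluate_model(st$model, ds$test)
        records[[length(records) + 1L]] <-
          metrics_record(kind, "validation", ts_ms, pt_ms, "all", ev_val)
        records[[length(records) + 1L]] <-
          metrics_record(kind, "test", ts_ms, pt_ms, "all", ev_test)
        if (!is.null(groups)) {
          df <- ev_test$per_signal
          df$group <- groups[df$signal_id]
          for (g in sort(unique(stats::na.omit(df$group)))) {
            sub <- df[!is.na(df$group) & df$group == g, ]
            records[[length(records) + 1L]] <- data.frame(
              model = kind, role = "test", ts_ms = ts_ms, pt_ms = pt_ms,
              group = g, rmse = mean(sub$rmse), cc = mean(sub$cc, na.rm = TRUE),
              n_pairs = sum(sub$n_pairs))
          }
        }
      }
    }
  }
  list(metrics = do.call(rbind, records), states = states, split = split)
}

#' Compare models with a one-way ANOVA on per-signal metrics
#'
#' @param sweep_metrics_per_signal Named list: model kind -> numeric vector of
#'   per-signal RMSE (or CC) values.
#' @return An `anova_result`.
#' @export
compare_models_anova <- function(sweep_metrics_per_signal) {
  one_way_anova(sweep_metrics_per_signal)
}
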