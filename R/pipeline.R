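#' Configuration of an end-to-end experiment
#'
#' Bundles the simulation (or preloaded recordings), segmentation,
#' augmentation, network, smoothing and evaluation settings behind a single
#' master seed. The workflow run by [run_experiment()] is: segment ->
#' k-fold split -> per fold: augment the training fold, fit the normalizer on
#' it, train the angle predictor end to end, transfer-learn the classifier on
#' the frozen extractor, predict on the test fold, EIA-smooth the predicted
#' angle per trial, compute metrics -> aggregate across folds.
#'
#' @param sim A [sim_config()] for synthetic data generation.
#' @param n_trials_per_class Trials per movement class to simulate.
#' @param recordings Optional list of `emg_recording` objects; when given,
#'   the simulator is not used.
#' @param window_ms,overlap_ms,stride_ms Segmentation parameters, see
#'   [segment_windows()].
#' @param augment An [augment_config()].
#' @param augment_train_only Augment only training folds (default). Set to
#'   `FALSE` to augment before splitting (strict replication of pipelines
#'   that augment the pooled segmented data, at the price of train/test
#'   leakage between an original and its virtual copies).
#' @param k Number of cross-validation folds.
#' @param split_by `"segment"` (random segment-level split, default) or
#'   `"trial"` (whole trials held out together).
#' @param lrcn An [lrcn_config()].
#' @param angle_epochs,class_epochs Epoch overrides for the two training
#'   stages; default to `lrcn$epochs`.
#' @param eia An [eia_config()].
#' @param mae_normalization Normalization for [mae_percent()].
#' @param out_dir Optional output directory for artifacts (fold manifest,
#'   models, per-fold and aggregate reports, log).
#' @param seed Master seed; fold seeds, the split and augmentation noise are
#'   derived from it.
#' @param verbose Emit stage-tagged progress messages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), n_trials_per_class = 2L,
                       recordings = NULL, window_ms = 256, overlap_ms = 64,
                       stride_ms = NULL, augment = augment_config(),
                       augment_train_only = TRUE, k = 3L,
                       split_by = c("segment", "trial"),
                       lrcn = lrcn_config(), angle_epochs = NULL,
                       class_epochs = NULL, eia = eia_config(),
                       mae_normalization = "range", out_dir = NULL,
                       seed = 1L, verbose = FALSE) {
  split_by <- match.arg(split_by)
  stopifnot(inherits(sim, "sim_config"), inherits(augment, "augment_config"),
            inherits(lrcn, "lrcn_config"), inherits(eia, "eia_config"))
  if (!is.null(recordings)) {
    stopifnot(all(vapply(recordings, inherits, TRUE, "emg_recording")))
  }
  structure(list(sim = sim, n_trials_per_class = as.integer(n_trials_per_class),
                 recordings = recordings, window_ms = window_ms,
                 overlap_ms = overlap_ms, stride_ms = stride_ms,
                 augment = augment, augment_train_only = augment_train_only,
                 k = as.integer(k), split_by = split_by, lrcn = lrcn,
                 angle_epochs = angle_epochs, class_epochs = class_epochs,
                 eia = eia, mae_normalization = mae_normalization,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

# stage-tagged, timestamped log line; optionally echoed and appended to file
log_line <- function(state, stage, fmt, ...) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(fmt, ...))
  if (!is.null(state$log_path)) cat(line, "\n", file = state$log_path,
                                    sep = "", append = TRUE)
  if (state$verbose) message(line)
  invisible(line)
}

# place per-window values at their true sample positions, averaging where
# windows overlap; returns the trace on the covered samples in time order
stitch_windows <- function(vals, starts) {
  W <- ncol(vals)
  n <- max(starts) + W
  acc <- numeric(n)
  cnt <- numeric(n)
  for (i in seq_len(nrow(vals))) {
    idx <- starts[i] + seq_len(W)
    acc[idx] <- acc[idx] + vals[i, ]
    cnt[idx] <- cnt[idx] + 1
  }
  covered <- cnt > 0
  acc[covered] / cnt[covered]
}

# per-trial evaluation: reconstruct each trial's predicted angle trace from
# its test windows (overlap-averaged), smooth it with EIA, and average
# MAE% / Pearson r across trials
trial_angle_metrics <- function(test_segs, pred, trial_of, eia_cfg,
                                mae_normalization) {
  trials <- unique(trial_of)
  mae <- r_eia <- r_raw <- numeric(0)
  for (tr in trials) {
    sel <- which(trial_of == tr)
    actual <- stitch_windows(test_segs$y_angle[sel, , drop = FALSE],
                             test_segs$start[sel])
    raw <- stitch_windows(pred[sel, , drop = FALSE], test_segs$start[sel])
    smooth <- eia_smooth(raw, eia_cfg)$smoothed
    mae <- c(mae, mae_percent(actual, smooth, mae_normalization))
    r_eia <- c(r_eia, pearson_corr(actual, smooth))
    r_raw <- c(r_raw, pearson_corr(actual, raw))
  }
  list(mae_percent = mean(mae), pearson_r = mean(r_eia),
       pearson_r_raw = mean(r_raw))
}

#' Run the full cross-validated experiment
#'
#' Executes the whole workflow described in [run_config()] and returns the
#' fold-averaged [metrics_report] (per-fold reports under `$folds`; the raw,
#' pre-smoothing correlation is reported alongside as `pearson_r_raw`). When
#' `cfg$out_dir` is set, all artifacts are written beneath it: `manifest.json`
#' (fold assignment and derived seeds), `model_foldK.rds`,
#' `report_foldK.json`, `report_aggregate.json` and `run.log`. Reruns with the
#' same configuration reproduce the aggregate exactly under single-threaded
#' BLAS.
#'
#' @param cfg A [run_config()].
#' @return The aggregate `metrics_report`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  state <- list(verbose = cfg$verbose, log_path = NULL)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    state$log_path <- file.path(cfg$out_dir, "run.log")
    cat("", file = state$log_path)
  }

  recs <- cfg$recordings
  if (is.null(recs)) {
    log_line(state, "simulate", "generating %d trials/class (%g s @ %g Hz)",
             cfg$n_trials_per_class, cfg$sim$duration_s, cfg$sim$fs)
    sim <- cfg$sim
    sim$seed <- cfg$seed
    recs <- gen_dataset(cfg$n_trials_per_class, sim)
  }

  seg_list <- lapply(recs, segment_windows, window_ms = cfg$window_ms,
                     overlap_ms = cfg$overlap_ms, stride_ms = cfg$stride_ms)
  trial_of <- rep(seq_along(recs), vapply(seg_list, n_segments, 1L))
  segs <- bind_segments(seg_list)
  log_line(state, "preprocess", "%d segments from %d recordings",
           n_segments(segs), length(recs))
  if (!cfg$augment_train_only && cfg$augment$factor > 1) {
    n0 <- n_segments(segs)
    segs <- augment_wgn(segs, cfg$augment)
    trial_of <- rep(trial_of, cfg$augment$factor)
    log_line(state, "preprocess", "pre-split augmentation: %d -> %d segments",
             n0, n_segments(segs))
  }

  if (cfg$split_by == "segment") {
    split <- kfold_split(n_segments(segs), k = cfg$k, seed = cfg$seed + 10L)
    fold_of <- split$assignments
  } else {
    tr_split <- kfold_split(length(unique(trial_of)), k = cfg$k,
                            seed = cfg$seed + 10L)
    fold_of <- tr_split$assignments[match(trial_of, unique(trial_of))]
    split <- structure(list(k = cfg$k, assignments = fold_of,
                            seed = cfg$seed + 10L), class = "fold_split")
  }

  if (!is.null(cfg$out_dir)) {
    jsonlite::write_json(
      list(seed = cfg$seed, k = cfg$k, split_by = cfg$split_by,
           n_segments = n_segments(segs), fold = fold_of,
           trial = trial_of, class = segs$y_class),
      file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE)
  }

  reports <- vector("list", cfg$k)
  for (f in seq_len(cfg$k)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    train <- segs[train_idx]
    test <- segs[test_idx]
    if (cfg$augment_train_only && cfg$augment$factor > 1) {
      aug <- cfg$augment
      aug$seed <- cfg$augment$seed + f
      train <- augment_wgn(train, aug)
      log_line(state, sprintf("fold%d", f), "augmented train %d -> %d segments",
               length(train_idx), n_segments(train))
    }
    norm <- fit_normalizer(train)
    train <- apply_normalizer(norm, train)
    test <- apply_normalizer(norm, test)

    lr <- cfg$lrcn
    lr$seed <- cfg$seed + 100L * f
    model <- build_lrcn(lr)
    log_line(state, sprintf("fold%d", f), "training angle predictor (%d epochs)",
             cfg$angle_epochs %||% lr$epochs)
    model <- train_angle_predictor(model, train, epochs = cfg$angle_epochs)
    log_line(state, sprintf("fold%d", f), "angle loss %.4f -> %.4f",
             model$history$angle_loss[1], tail_1(model$history$angle_loss))
    model <- transfer_to_classifier(model, train, epochs = cfg$class_epochs)
    log_line(state, sprintf("fold%d", f), "classifier loss %.4f -> %.4f",
             model$history$class_loss[1], tail_1(model$history$class_loss))

    pred_angle <- predict_angle(model, test)
    pred_move <- predict_movement(model, test)
    cls <- classification_metrics(test$y_class, pred_move$labels)
    cm <- confusion_matrix(test$y_class, pred_move$labels)
    am <- trial_angle_metrics(test, pred_angle, trial_of[test_idx], cfg$eia,
                              cfg$mae_normalization)
    reports[[f]] <- metrics_report(
      mae_percent = am$mae_percent, accuracy = cls$accuracy,
      pearson_r = am$pearson_r, per_class = cls$per_class, macro = cls$macro,
      confusion = cm, extra = list(pearson_r_raw = am$pearson_r_raw))
    log_line(state, sprintf("fold%d", f),
             "accuracy %.1f%%, MAE %.2f%%, r %.4f (raw %.4f)",
             cls$accuracy, am$mae_percent, am$pearson_r, am$pearson_r_raw)
    if (!is.null(cfg$out_dir)) {
      save_model(model, file.path(cfg$out_dir, sprintf("model_fold%d.rds", f)))
      write_metrics_report(reports[[f]],
                           file.path(cfg$out_dir, sprintf("report_fold%d.json", f)))
    }
  }

  agg <- aggregate_folds(reports)
  agg$pearson_r_raw <- mean(vapply(reports, `[[`, 0, "pearson_r_raw"))
  log_line(state, "aggregate", "accuracy %.1f +/- %.1f %%, MAE %.2f +/- %.2f %%, r %.4f",
           agg$accuracy, agg$accuracy_sd, agg$mae_percent, agg$mae_percent_sd,
           agg$pearson_r)
  if (!is.null(cfg$out_dir)) {
    write_metrics_report(agg, file.path(cfg$out_dir, "report_aggregate.json"))
  }
  agg
}

tail_1 <- function(x) x[length(x)]
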