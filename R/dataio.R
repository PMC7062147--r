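#' Construct a recording
#'
#' A recording is one subject/movement trial: a multichannel sEMG matrix in
#' arbitrary amplitude units, the time-aligned knee angle trace in degrees,
#' the sampling rate, the movement class and provenance metadata.
#'
#' @param emg Numeric matrix, samples x channels.
#' @param angle Numeric vector of knee angles in degrees, one per sample.
#' @param fs Sampling frequency in Hz.
#' @param cls Movement class (label or 0-based code), see [movement_classes()].
#' @param subject_id Subject/trial identifier.
#' @param cohort One of "healthy", "knee_pathology", "synthetic".
#' @return Object of class `emg_recording`: a list with fields `emg`, `angle`,
#'   `fs`, `cls` (0-based integer code), `subject_id`, `cohort`.
#' @export
recording <- function(emg, angle, fs, cls, subject_id = "unknown",
                      cohort = c("synthetic", "healthy", "knee_pathology")) {
  emg <- as.matrix(emg)
  cohort <- match.arg(cohort)
  if (nrow(emg) != length(angle)) {
    stopf("emg (%d samples) and angle (%d samples) must be aligned",
          nrow(emg), length(angle))
  }
  if (fs <= 0) stopf("fs must be positive")
  if (anyNA(emg) || anyNA(angle)) stopf("recording contains missing values")
  structure(list(emg = emg, angle = as.numeric(angle), fs = fs,
                 cls = as_class_code(cls), subject_id = subject_id,
                 cohort = cohort),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s | %s | %s\n", x$subject_id,
              movement_classes()[x$cls + 1L], x$cohort))
  cat(sprintf("  %d samples x %d channels @ %g Hz (%.1f s), angle %.1f-%.1f deg\n",
              nrow(x$emg), ncol(x$emg), x$fs, nrow(x$emg) / x$fs,
              min(x$angle), max(x$angle)))
  invisible(x)
}

#' Column mapping for delimited-text recordings
#'
#' Describes the layout of a delimited-text export: which columns hold the
#' sEMG channels and the goniometer angle, the delimiter, how many header
#' lines to skip, and the sampling rate. The defaults match the files written
#' by [write_recording()] (tab-separated, one header row, columns ch1..ch4
#' then angle).
#'
#' @param delimiter Field delimiter.
#' @param skip Number of header lines to skip.
#' @param emg_cols Integer column indices of the sEMG channels (1-based).
#' @param angle_col Integer column index of the angle trace.
#' @param fs Sampling frequency in Hz.
#' @return Object of class `column_map`.
#' @export
column_map <- function(delimiter = "\t", skip = 1L, emg_cols = 1:4,
                       angle_col = 5L, fs = 1000) {
  idx <- c(emg_cols, angle_col)
  if (anyDuplicated(idx)) stopf("column indices must be distinct")
  if (any(idx < 1)) stopf("column indices must be positive")
  structure(list(delimiter = delimiter, skip = as.integer(skip),
                 emg_cols = as.integer(emg_cols),
                 angle_col = as.integer(angle_col), fs = fs),
            class = "column_map")
}

#' Read a recording from delimited text
#'
#' @param path File path.
#' @param map A [column_map()] describing the file layout.
#' @param cls Movement class of the trial.
#' @param subject_id,cohort Metadata stored in the recording.
#' @return An `emg_recording`.
#' @export
read_recording <- function(path, map = column_map(), cls,
                           subject_id = "unknown", cohort = "healthy") {
  stopifnot(inherits(map, "column_map"))
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- read.table(path, sep = map$delimiter, skip = map$skip,
                    colClasses = "character", header = FALSE,
                    stringsAsFactors = FALSE)
  need <- c(map$emg_cols, map$angle_col)
  if (max(need) > ncol(raw)) {
    stopf("column map requests column %d but file %s has only %d columns",
          max(need), path, ncol(raw))
  }
  num <- suppressWarnings(
    vapply(need, function(j) as.numeric(raw[[j]]), numeric(nrow(raw)))
  )
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stopf("non-numeric value in %s at data row %d", path, bad)
  }
  k <- length(map$emg_cols)
  recording(num[, seq_len(k), drop = FALSE], num[, k + 1L], fs = map$fs,
            cls = cls, subject_id = subject_id, cohort = cohort)
}

#' Write a recording as delimited text
#'
#' Writes the layout consumed by [read_recording()] with the default
#' [column_map()]: one header row `ch1..chN<tab>angle`, then one line per
#' sample. Values are formatted with 8 significant digits, so a round trip is
#' exact to that precision.
#'
#' @param rec An `emg_recording`.
#' @param path Output file path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, delimiter = "\t") {
  stopifnot(inherits(rec, "emg_recording"))
  df <- as.data.frame(signif(cbind(rec$emg, rec$angle), 8))
  names(df) <- c(paste0("ch", seq_len(ncol(rec$emg))), "angle")
  write.table(df, path, sep = delimiter, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a trained model
#'
#' The model container preserves all weights bit-exactly together with the
#' block structure (`feature_extractor`, `angle_head`, `classification_head`),
#' the architecture configuration, the training stage and the angle target
#' scaling.
#'
#' @param model An `lrcn_model`.
#' @param path File path for the binary container.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns the
#'   restored `lrcn_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lrcn_model"))
  obj <- unclass(model)
  obj$format <- "emglrcn_lrcn_model"
  obj$format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stopf("not a valid model container: %s (%s)", path, conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, "emglrcn_lrcn_model")) {
    stopf("not a valid model container: %s (missing format header)", path)
  }
  if (!identical(obj$format_version, 1L)) {
    stopf("unsupported model container version: %s", obj$format_version)
  }
  obj$format <- NULL
  obj$format_version <- NULL
  model <- structure(obj, class = "lrcn_model")
  skel <- build_lrcn(model$cfg)
  for (nm in names(skel$params)) {
    if (is.null(model$params[[nm]])) stopf("model container missing block parameter %s", nm)
    if (!identical(dim1(model$params[[nm]]), dim1(skel$params[[nm]]))) {
      stopf("shape mismatch for %s on load", nm)
    }
  }
  model
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Write / read a metrics report
#'
#' Serializes a [metrics_report] (per-fold breakdown plus fold-averaged
#' summary) as structured JSON; `read_metrics_report()` restores it.
#'
#' @param report A `metrics_report`, see [aggregate_folds()].
#' @param path Output path.
#' @return `write_metrics_report()` returns `path` invisibly;
#'   `read_metrics_report()` the restored report.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- unclass(report)
  if (!is.null(obj$folds)) obj$folds <- lapply(obj$folds, unclass)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(r) {
    if (!is.null(r$confusion)) r$confusion <- as.matrix(r$confusion)
    if (!is.null(r$per_class)) r$per_class <- as.data.frame(r$per_class)
    r
  }
  obj <- fix(obj)
  if (!is.null(obj$folds)) {
    obj$folds <- lapply(seq_len(nrow_or_len(obj$folds)), function(i) {
      structure(fix(pick_fold(obj$folds, i)), class = "metrics_report")
    })
  }
  structure(obj, class = "metrics_report")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pick_fold <- function(x, i) if (is.data.frame(x)) as.list(x[i, ]) else x[[i]]
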