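#' Signed absolute error between actual and predicted joint angle
#'
#' Elementwise `aj - pj` in degrees (the signed error; its absolute value
#' feeds the MAE downstream).
#'
#' @param aj Actual joint angle vector, degrees.
#' @param pj Predicted joint angle vector, degrees.
#' @return Numeric vector `aj - pj`.
#' @export
absolute_error <- function(aj, pj) {
  if (length(aj) != length(pj)) {
    stopf("aj (%d) and pj (%d) must have equal length", length(aj), length(pj))
  }
  aj - pj
}

#' Normalized mean absolute error in percent
#'
#' `mean(|aj - pj|)` normalized and expressed in percent. Under the default
#' `"range"` normalization the divisor is the dynamic range of the actual
#' angle, `max(aj) - min(aj)`, so the result is invariant to a common affine
#' rescaling of both traces; `"max"` divides by `max(aj)`; `"none"` returns
#' the plain MAE in degrees.
#'
#' @param aj,pj Actual and predicted joint angle vectors, degrees.
#' @param normalization `"range"`, `"max"` or `"none"`.
#' @return MAE as a percentage (or degrees for `"none"`).
#' @export
#' @examples
#' mae_percent(c(0, 100), c(10, 90))  # 10
mae_percent <- function(aj, pj, normalization = c("range", "max", "none")) {
  normalization <- match.arg(normalization)
  if (length(aj) == 0) stopf("empty input")
  mae <- mean(abs(absolute_error(aj, pj)))
  switch(normalization,
    none = mae,
    max = {
      if (max(aj) <= 0) stopf("degenerate input: max(aj) <= 0")
      mae / max(aj) * 100
    },
    range = {
      rg <- max(aj) - min(aj)
      if (rg <= 0) stopf("degenerate input: actual angle has zero range")
      mae / rg * 100
    })
}

#' One-vs-rest classification metrics
#'
#' Counts TP/FP/FN/TN per class and derives precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)` and binary accuracy
#' `(TP+TN)/(TP+FP+FN+TN) x 100`. Per-class values are macro-averaged
#' (unweighted) across the three movements; `accuracy` is the overall
#' fraction of correct predictions in percent. A class absent from `y_true`
#' yields `NA` recall with a warning rather than a silent zero.
#'
#' @param y_true,y_pred Equal-length vectors of 0-based class codes or labels.
#' @param positive_class Optional single class; if given, only that class's
#'   one-vs-rest metrics are returned.
#' @param classes Class codes defining the label universe.
#' @return If `positive_class` is given, a list with `precision`, `recall`,
#'   `f1`, `accuracy`. Otherwise a list with `per_class` (data frame of
#'   per-class precision/recall/f1/binary accuracy), `macro` (unweighted
#'   means) and `accuracy` (overall, percent).
#' @export
classification_metrics <- function(y_true, y_pred, positive_class = NULL,
                                   classes = 0:2) {
  y_true <- as_class_code(y_true)
  y_pred <- as_class_code(y_pred)
  if (length(y_true) != length(y_pred)) stopf("label vectors must have equal length")
  one <- function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- sum(y_true != cl & y_pred != cl)
    if (tp + fn == 0) {
      warning(sprintf("class %d absent from y_true: recall undefined", cl))
    }
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
      NA_real_
    } else {
      2 * precision * recall / (precision + recall)
    }
    c(precision = precision, recall = recall, f1 = f1,
      accuracy = (tp + tn) / (tp + fp + fn + tn) * 100)
  }
  if (!is.null(positive_class)) {
    return(as.list(one(as_class_code(positive_class))))
  }
  m <- t(vapply(classes, one, numeric(4)))
  per_class <- data.frame(class = classes,
                          label = movement_classes()[classes + 1L],
                          precision = m[, "precision"], recall = m[, "recall"],
                          f1 = m[, "f1"], binary_accuracy = m[, "accuracy"])
  list(per_class = per_class,
       macro = list(precision = mean(m[, "precision"]),
                    recall = mean(m[, "recall"]),
                    f1 = mean(m[, "f1"])),
       accuracy = mean(y_true == y_pred) * 100)
}

#' Row-normalized confusion matrix in percent
#'
#' Entry (i, j) is the percentage of true-class-i segments predicted as class
#' j; each row sums to 100. A class absent from `y_true` yields an `NA` row
#' with a warning.
#'
#' @inheritParams classification_metrics
#' @return 3 x 3 numeric matrix with class labels as dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = 0:2) {
  y_true <- as_class_code(y_true)
  y_pred <- as_class_code(y_pred)
  if (length(y_true) != length(y_pred)) stopf("label vectors must have equal length")
  k <- length(classes)
  cm <- matrix(0, k, k, dimnames = list(movement_classes()[classes + 1L],
                                        movement_classes()[classes + 1L]))
  for (i in seq_len(k)) {
    sel <- y_true == classes[i]
    if (!any(sel)) {
      warning(sprintf("class %d absent from y_true: confusion row undefined",
                      classes[i]))
      cm[i, ] <- NA_real_
    } else {
      for (j in seq_len(k)) cm[i, j] <- mean(y_pred[sel] == classes[j]) * 100
    }
  }
  cm
}

#' Pearson correlation between two traces
#'
#' @param a,b Equal-length numeric vectors (e.g. actual and EIA-processed
#'   joint angle).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_corr <- function(a, b) {
  if (length(a) != length(b)) stopf("vectors must have equal length")
  cor(as.numeric(a), as.numeric(b))
}

#' Construct a per-fold metrics report
#'
#' @param mae_percent Normalized MAE in percent.
#' @param accuracy Overall classification accuracy in percent.
#' @param pearson_r Pearson correlation of actual vs (smoothed) predicted
#'   angle.
#' @param per_class Per-class precision/recall/f1 data frame.
#' @param macro Macro-averaged precision/recall/f1.
#' @param confusion Row-normalized confusion matrix in percent.
#' @param extra Optional named list of additional scalar metrics.
#' @return Object of class `metrics_report`.
#' @export
metrics_report <- function(mae_percent = NA_real_, accuracy = NA_real_,
                           pearson_r = NA_real_, per_class = NULL,
                           macro = NULL, confusion = NULL, extra = list()) {
  structure(c(list(mae_percent = mae_percent, accuracy = accuracy,
                   pearson_r = pearson_r, per_class = per_class,
                   macro = macro, confusion = confusion), extra),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  fmt <- function(v, s) {
    if (!is.null(s) && !is.na(s)) sprintf("%.2f +/- %.2f", v, s) else sprintf("%.2f", v)
  }
  cat("  MAE:", fmt(x$mae_percent, x$mae_percent_sd), "%\n")
  cat("  accuracy:", fmt(x$accuracy, x$accuracy_sd), "%\n")
  cat("  Pearson r:", fmt(x$pearson_r, x$pearson_r_sd), "\n")
  if (!is.null(x$confusion)) {
    cat("  confusion (row %):\n")
    print(round(x$confusion, 1))
  }
  invisible(x)
}

#' Average per-fold reports into a summary report
#'
#' Every scalar metric is summarized as arithmetic mean plus sample standard
#' deviation across folds (`*_sd` fields); confusion matrices are averaged
#' elementwise and re-normalized so rows sum to 100. With a single fold the
#' standard deviations are reported as 0 with a warning.
#'
#' @param reports List of per-fold `metrics_report` objects.
#' @return A `metrics_report` with the averaged metrics, their `*_sd`
#'   companions, and the input reports under `folds`.
#' @export
#' @examples
#' r1 <- metrics_report(accuracy = 90)
#' r2 <- metrics_report(accuracy = 100)
#' aggregate_folds(list(r1, r2))$accuracy_sd  # 7.07
aggregate_folds <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, TRUE, "metrics_report")))
  if (length(reports) == 1) {
    warning("single fold: standard deviations reported as 0")
  }
  scalar_names <- c("mae_percent", "accuracy", "pearson_r")
  out <- list()
  for (nm in scalar_names) {
    v <- vapply(reports, function(r) as.numeric(r[[nm]] %||% NA_real_), 0)
    out[[nm]] <- mean(v)
    out[[paste0(nm, "_sd")]] <- if (length(v) > 1) sd(v) else 0
  }
  if (!is.null(reports[[1]]$macro)) {
    out$macro <- lapply(c(precision = "precision", recall = "recall", f1 = "f1"),
                        function(nm) {
                          mean(vapply(reports, function(r) r$macro[[nm]], 0))
                        })
  }
  cms <- lapply(reports, `[[`, "confusion")
  if (!any(vapply(cms, is.null, TRUE))) {
    cm <- Reduce(`+`, cms) / length(cms)
    cm <- sweep(cm, 1, rowSums(cm), "/") * 100
    out$confusion <- cm
  }
  if (!is.null(reports[[1]]$per_class)) {
    pc <- reports[[1]]$per_class
    for (col in c("precision", "recall", "f1", "binary_accuracy")) {
      pc[[col]] <- rowMeans(vapply(reports, function(r) r$per_class[[col]],
                                   numeric(nrow(pc))))
    }
    out$per_class <- pc
  }
  out$folds <- reports
  structure(out, class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
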