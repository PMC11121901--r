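#' Confusion matrix for multiclass predictions
#'
#' @param truth,predicted Equal-length label vectors (characters or factors
#'   over `levels`).
#' @param levels Class levels, in order (default [class_levels()]).
#' @return A K x K integer matrix of class `confusion_matrix`; rows are true
#'   classes, columns predicted classes.
#' @export
confusion_matrix <- function(truth, predicted, levels = class_levels()) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  t_ <- factor(as.character(truth), levels = levels)
  p_ <- factor(as.character(predicted), levels = levels)
  if (anyNA(t_) || anyNA(p_)) abort("labels outside the declared levels")
  cm <- table(truth = t_, predicted = p_)
  cm <- matrix(as.integer(cm), nrow = length(levels),
               dimnames = list(truth = levels, predicted = levels))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

# one-vs-rest tallies for class index i
ovr_counts <- function(cm, i) {
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# zero-denominator convention: 0, not NaN
safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Harmonic-mean F1 of a precision/recall pair
#'
#' `f1 = 2 p r / (p + r)`, with the convention `f1 = 0` when `p + r = 0`.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' One-vs-rest metrics for a single class
#'
#' @param cm A [confusion_matrix()].
#' @param class Class label (a row/column name of `cm`).
#' @return One-row tibble: `class`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1`. Precision and recall are 0 when their denominator is
#'   0.
#' @export
class_metrics <- function(cm, class) {
  i <- match(class, rownames(cm))
  if (is.na(i)) abort(paste0("unknown class: ", class))
  ct <- ovr_counts(cm, i)
  p <- safe_div(ct["tp"], ct["tp"] + ct["fp"])
  r <- safe_div(ct["tp"], ct["tp"] + ct["fn"])
  tibble(class = class, tp = unname(ct["tp"]), fp = unname(ct["fp"]),
         fn = unname(ct["fn"]), tn = unname(ct["tn"]),
         precision = unname(p), recall = unname(r),
         f1 = unname(f1_score(p, r)))
}

#' Micro- and macro-averaged precision/recall/F1
#'
#' Macro averaging is the unweighted mean of per-class metrics over the
#' included classes; micro averaging recomputes the metrics from summed
#' one-vs-rest tp/fp/fn tallies. With `exclude_background = TRUE` the
#' background class's own tallies are dropped from the averages, but errors
#' *involving* the background still count: a background-true document
#' predicted as a foreground class is a false positive of that class, and a
#' foreground-true document predicted background is a false negative of its
#' class. Only correctly classified background documents vanish from the
#' scores.
#'
#' @param cm A [confusion_matrix()].
#' @param exclude_background Drop the background class from the averages?
#' @param background The background label (default `"OTHER"`).
#' @return Tibble with rows `micro` and `macro`: `average`, `precision`,
#'   `recall`, `f1`.
#' @export
averaged_metrics <- function(cm, exclude_background = FALSE,
                             background = "OTHER") {
  lv <- rownames(cm)
  included <- if (exclude_background) setdiff(lv, background) else lv
  counts <- vapply(match(included, lv), function(i) ovr_counts(cm, i),
                   numeric(4))
  prec <- vapply(seq_along(included), function(j) {
    safe_div(counts["tp", j], counts["tp", j] + counts["fp", j])
  }, numeric(1))
  rec <- vapply(seq_along(included), function(j) {
    safe_div(counts["tp", j], counts["tp", j] + counts["fn", j])
  }, numeric(1))
  tp <- sum(counts["tp", ]); fp <- sum(counts["fp", ])
  fn <- sum(counts["fn", ])
  micro_p <- safe_div(tp, tp + fp)
  micro_r <- safe_div(tp, tp + fn)
  tibble(
    average = c("micro", "macro"),
    precision = c(micro_p, mean(prec)),
    recall = c(micro_r, mean(rec)),
    f1 = c(f1_score(micro_p, micro_r), mean(f1_score(prec, rec)))
  )
}

#' Evaluate predictions into a full report
#'
#' @param truth,predicted Equal-length label vectors.
#' @param background Background label excluded from the headline averages.
#' @param levels Class levels.
#' @return An `evaluation_report`: confusion matrix, per-class metrics,
#'   accuracy, and micro/macro averages with and without the background
#'   class. All values are kept at full precision; rounding (2 decimals,
#'   round-half-even) is presentation-only.
#' @export
evaluate_predictions <- function(truth, predicted, background = "OTHER",
                                 levels = class_levels()) {
  if (length(truth) == 0) abort("cannot evaluate an empty test set")
  cm <- confusion_matrix(truth, predicted, levels)
  per_class <- dplyr::bind_rows(purrr::map(levels,
                                           function(cl) class_metrics(cm, cl)))
  averages <- dplyr::bind_rows(
    averaged_metrics(cm, FALSE, background) |> mutate(scope = "all_classes"),
    averaged_metrics(cm, TRUE, background) |>
      mutate(scope = "without_background")
  ) |>
    select("scope", "average", "precision", "recall", "f1")
  structure(list(confusion = cm, per_class = per_class,
                 accuracy = sum(diag(cm)) / sum(cm),
                 averages = averages, background = background),
            class = "evaluation_report")
}

#' Evaluate a trained classifier on a labeled test set
#'
#' Predicts every text with [predict_batch()] and scores the predictions
#' with [evaluate_predictions()].
#'
#' @param model A trained `rare_classifier`.
#' @param test_set Tibble with `text` and `label` columns; must be
#'   nonempty.
#' @param background Background label (default `"OTHER"`).
#' @return An `evaluation_report`.
#' @export
evaluate_classifier <- function(model, test_set, background = "OTHER") {
  if (nrow(test_set) == 0) abort("cannot evaluate an empty test set")
  preds <- predict_batch(model, test_set$text)
  evaluate_predictions(test_set$label, preds$.pred, background)
}

# round-half-even presentation at 2 decimals (R's round() is half-even)
present2 <- function(x) round(x, 2)

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n\nConfusion matrix (rows = truth):\n")
  print(unclass(x$confusion))
  cat(sprintf("\nAccuracy: %.2f\n\nPer class:\n", present2(x$accuracy)))
  pc <- x$per_class |>
    mutate(across(c("precision", "recall", "f1"), present2))
  print(as.data.frame(pc[, c("class", "precision", "recall", "f1")]),
        row.names = FALSE)
  cat(sprintf("\nAverages (background = %s):\n", x$background))
  av <- x$averages |>
    mutate(across(c("precision", "recall", "f1"), present2))
  print(as.data.frame(av), row.names = FALSE)
  invisible(x)
}

#' Tidiers for raremesh result objects
#'
#' `tidy()` on an `evaluation_report` returns per-class metrics; on a
#' `rare_classifier`, the per-epoch training trace. `glance()` returns a
#' one-row summary (accuracy plus micro/macro averages with and without the
#' background class for reports; dimensions and best epoch for models).
#'
#' @param x An `evaluation_report` or `rare_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_raremesh
NULL

#' @rdname tidy_raremesh
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  x$per_class
}

#' @rdname tidy_raremesh
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  wide <- x$averages |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric") |>
    mutate(key = paste(.data$average, .data$metric,
                       ifelse(.data$scope == "without_background",
                              "excl_bg", "all"),
                       sep = "_")) |>
    select("key", "value") |>
    tidyr::pivot_wider(names_from = "key", values_from = "value")
  dplyr::bind_cols(tibble(accuracy = x$accuracy), wide)
}

#' Plot an evaluation report's confusion matrix
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot heatmap, rows = true class, columns = predicted.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object$confusion)))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "truth", fill = "count") +
    ggplot2::theme_minimal()
}

#' Serialize an evaluation report
#'
#' Writes full-precision JSON and, optionally, a 2-decimal TSV laid out
#' like the published results tables (per-class rows, then micro/macro
#' averages with and without the background class).
#'
#' @param report An `evaluation_report`.
#' @param json_path Output JSON path.
#' @param tsv_path Optional output TSV path.
#' @return `json_path`, invisibly.
#' @export
write_evaluation_report <- function(report, json_path, tsv_path = NULL) {
  payload <- list(
    confusion = unclass(report$confusion),
    per_class = report$per_class,
    accuracy = report$accuracy,
    averages = report$averages,
    background = report$background
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    per <- report$per_class |>
      select("class", "precision", "recall", "f1") |>
      mutate(across(c("precision", "recall", "f1"), present2))
    av <- report$averages |>
      mutate(class = paste(.data$average, ifelse(
        .data$scope == "without_background", "(without background)", ""))) |>
      select("class", "precision", "recall", "f1") |>
      mutate(across(c("precision", "recall", "f1"), present2))
    readr::write_tsv(dplyr::bind_rows(per, av), tsv_path, progress = FALSE)
  }
  invisible(json_path)
}
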