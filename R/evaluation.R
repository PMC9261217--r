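#' Train/validation split specification
#'
#' @param train_fraction Fraction of the weak-labeled pool used for
#'   training (default 0.9).
#' @param seeds Integer seeds for the repeated runs whose metrics are
#'   averaged (default `c(24, 48, 128)`); the same seed drives the split
#'   and every model's fit within a run.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.9, seeds = c(24L, 48L, 128L)) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            length(seeds) >= 1L, !anyDuplicated(seeds))
  structure(list(train_fraction = train_fraction, seeds = as.integer(seeds)),
            class = "split_spec")
}

#' Split data into train and validation sets
#'
#' Disjoint, exhaustive, seeded. The same seed yields the same membership
#' for every model.
#'
#' @param data A data frame (>= 10 rows).
#' @param train_fraction Fraction assigned to training.
#' @param seed Integer seed.
#' @return A list with `train` and `eval` data frames.
#' @export
split_train_eval <- function(data, train_fraction = 0.9, seed = 1L) {
  n <- nrow(data)
  if (n < 10L) stop("need at least 10 rows to split", call. = FALSE)
  n_train <- round(train_fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = data[idx, , drop = FALSE],
       eval = data[-idx, , drop = FALSE])
}

#' Per-class and averaged classification metrics
#'
#' Precision, recall, F1 and support per class, plus support-weighted and
#' macro (unweighted) averages and overall accuracy. A metric whose
#' denominator is zero is reported as 0 (with a warning). Predictions
#' outside `class_set` (e.g. the rule labeler's `"NONE"`) are allowed and
#' count as a miss for every class; gold labels must lie in `class_set`.
#'
#' @param gold,predicted Character vectors of equal length.
#' @param class_set Classes to report (default: classes present in `gold`).
#' @return An object of class `eval_report`: `per_class` tibble,
#'   `weighted_avg` and `macro_avg` named vectors (precision/recall/f1),
#'   `accuracy`, `n_eval`, `provenance`.
#' @export
compute_metrics <- function(gold, predicted, class_set = sort(unique(gold))) {
  if (length(gold) != length(predicted)) {
    stop("gold and predicted labels must have equal length", call. = FALSE)
  }
  if (!all(gold %in% class_set)) {
    stop("gold labels outside class_set", call. = FALSE)
  }
  per <- lapply(class_set, function(cl) {
    tp <- sum(gold == cl & predicted == cl)
    fp <- sum(gold != cl & predicted == cl)
    fn <- sum(gold == cl & predicted != cl)
    div0 <- FALSE
    p <- if (tp + fp == 0) { div0 <- TRUE; 0 } else tp / (tp + fp)
    r <- if (tp + fn == 0) { div0 <- TRUE; 0 } else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    tibble::tibble(class = cl, precision = p, recall = r, f1 = f1,
                   support = tp + fn, zero_division = div0)
  })
  per <- do.call(rbind, per)
  if (any(per$zero_division)) {
    warning("zero denominator for class(es): ",
            paste(per$class[per$zero_division], collapse = ", "),
            "; metric reported as 0", call. = FALSE)
  }
  wts <- per$support / max(1L, sum(per$support))
  avg <- function(w) c(precision = sum(w * per$precision),
                       recall = sum(w * per$recall),
                       f1 = sum(w * per$f1))
  structure(
    list(per_class = per[, setdiff(names(per), "zero_division")],
         weighted_avg = avg(wts),
         macro_avg = avg(rep(1 / nrow(per), nrow(per))),
         accuracy = mean(gold == predicted),
         n_eval = length(gold),
         provenance = list()),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n_eval, "\n")
  print(as.data.frame(x$per_class), row.names = FALSE)
  cat(sprintf("  weighted avg: P=%.3f R=%.3f F1=%.3f | macro F1=%.3f | acc=%.3f\n",
              x$weighted_avg[["precision"]], x$weighted_avg[["recall"]],
              x$weighted_avg[["f1"]], x$macro_avg[["f1"]], x$accuracy))
  invisible(x)
}

#' Average evaluation reports over seeds
#'
#' Arithmetic mean of every metric (and of supports) across reports with
#' identical class sets; provenance accumulates all seeds.
#'
#' @param reports A list of `eval_report` objects.
#' @return An `eval_report` of per-metric means.
#' @export
average_over_seeds <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, TRUE, "eval_report")))
  classes <- reports[[1L]]$per_class$class
  for (r in reports) {
    if (!identical(r$per_class$class, classes)) {
      stop("reports have mismatched class sets", call. = FALSE)
    }
  }
  num_cols <- c("precision", "recall", "f1", "support")
  per <- reports[[1L]]$per_class
  for (col in num_cols) {
    per[[col]] <- rowMeans(vapply(reports, function(r) r$per_class[[col]],
                                  numeric(nrow(per))))
  }
  mean_vec <- function(field) {
    rowMeans(vapply(reports, function(r) r[[field]], numeric(3)))
  }
  structure(
    list(per_class = per,
         weighted_avg = mean_vec("weighted_avg"),
         macro_avg = mean_vec("macro_avg"),
         accuracy = mean(vapply(reports, `[[`, 0, "accuracy")),
         n_eval = mean(vapply(reports, `[[`, 0, "n_eval")),
         provenance = list(seeds = unlist(lapply(reports, function(r)
           r$provenance$seed)))),
    class = "eval_report"
  )
}

#' Evaluate a roster of models on a gold-standard stand-in
#'
#' One row per model (include the rule labeler via [rule_classifier()] to
#' mirror the published comparison tables). Training/evaluation overlap is
#' a hard failure.
#'
#' @param models Named list of objects with a `predict(object, texts)`
#'   method.
#' @param gsc A gold-labeled corpus tibble with `text` and `gold_label`.
#' @param class_set Classes to report (default: the task classes present in
#'   the gold labels).
#' @param train_texts Optional character vector of training sentences; if
#'   supplied, any overlap with `gsc$text` aborts.
#' @return A list with `reports` (named list of `eval_report`) and `table`
#'   (tibble of weighted precision/recall/F1 per model, with the best model
#'   per column flagged in `best_*` columns).
#' @export
evaluate_on_gsc <- function(models, gsc, class_set = sort(unique(gsc$gold_label)),
                            train_texts = NULL) {
  stopifnot(is.list(models), length(models) >= 1L, !is.null(names(models)))
  if (!is.null(train_texts) && length(intersect(train_texts, gsc$text))) {
    stop("training and evaluation sentences overlap", call. = FALSE)
  }
  reports <- lapply(models, function(m) {
    pred <- stats::predict(m, gsc$text)
    compute_metrics(gsc$gold_label, pred, class_set)
  })
  tab <- tibble::tibble(
    model = names(models),
    precision = vapply(reports, function(r) r$weighted_avg[["precision"]], 0),
    recall = vapply(reports, function(r) r$weighted_avg[["recall"]], 0),
    f1 = vapply(reports, function(r) r$weighted_avg[["f1"]], 0)
  )
  for (col in c("precision", "recall", "f1")) {
    tab[[paste0("best_", col)]] <- tab[[col]] == max(tab[[col]])
  }
  list(reports = reports, table = tab)
}

#' Render a model-comparison table as markdown
#'
#' @param tab The `table` element returned by [evaluate_on_gsc()] or a
#'   similar tibble with a `model` column and numeric metric columns.
#' @param digits Decimal places (default 2, the convention of published
#'   comparison tables).
#' @return A character scalar of markdown.
#' @export
report_markdown <- function(tab, digits = 2) {
  metric_cols <- names(tab)[vapply(tab, is.numeric, TRUE)]
  header <- paste0("| Model | ", paste(metric_cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(metric_cols) + 1L),
                           collapse = "|"), "|")
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    vals <- vapply(metric_cols, function(cl) {
      v <- formatC(tab[[cl]][i], digits = digits, format = "f")
      best_col <- paste0("best_", cl)
      if (best_col %in% names(tab) && isTRUE(tab[[best_col]][i])) {
        v <- paste0("**", v, "**")
      }
      v
    }, "")
    paste0("| ", tab$model[i], " | ", paste(vals, collapse = " | "), " |")
  }, "")
  paste(c(header, sep, rows), collapse = "\n")
}
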