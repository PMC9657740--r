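#' Pixelwise confusion counts
#'
#' @param pred,ref logical (or 0/1) matrices of equal shape; `TRUE` =
#'   foreground.
#' @return Object of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) {
    stop("prediction shape ", paste(dim(pred), collapse = "x"),
         " does not match reference ", paste(dim(ref), collapse = "x"))
  }
  p <- as.logical(pred); r <- as.logical(ref)
  structure(list(tp = sum(p & r), tn = sum(!p & !r),
                 fp = sum(p & !r), fn = sum(!p & r)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

ratio_or_convention <- function(num, den, tp, fp, fn) {
  if (den > 0) return(num / den)
  # zero-denominator convention: a truly empty problem (no predicted or
  # reference foreground) scores 1, any other degenerate ratio scores 0
  if (tp + fp + fn == 0) 1 else 0
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy, precision, recall, F1 and Jaccard index. Zero-denominator
#' ratios follow the convention: 1 when TP + FP + FN = 0 (nothing to find,
#' nothing found), else 0; such rows are flagged `degenerate`.
#'
#' @param counts a [confusion_counts()].
#' @return One-row tibble with the five metrics and a `degenerate` flag.
#' @export
seg_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("no pixels to evaluate")
  degenerate <- (tp + fp) == 0 || (tp + fn) == 0 || (tp + fp + fn) == 0
  tibble::tibble(
    accuracy = (tp + tn) / total,
    precision = ratio_or_convention(tp, tp + fp, tp, fp, fn),
    recall = ratio_or_convention(tp, tp + fn, tp, fp, fn),
    f1 = ratio_or_convention(2 * tp, 2 * tp + fp + fn, tp, fp, fn),
    jaccard = ratio_or_convention(tp, tp + fp + fn, tp, fp, fn),
    degenerate = degenerate
  )
}

#' Evaluate a predicted label map against a reference
#'
#' Multi-class maps are scored one-vs-rest per foreground class plus a
#' `"foreground"` roll-up (any non-background class).
#'
#' @param pred,ref integer matrices of 0-based class labels (0 =
#'   background).
#' @param classes integer vector of foreground class indices to score;
#'   defaults to all classes present in the reference.
#' @return Tibble with one row per scored class.
#' @export
evaluate_labels <- function(pred, ref, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(ref[ref > 0L]))
  rows <- lapply(classes, function(cl) {
    m <- seg_metrics(confusion_counts(pred == cl, ref == cl))
    tibble::add_column(m, class = as.character(cl), .before = 1L)
  })
  fg <- seg_metrics(confusion_counts(pred > 0L, ref > 0L))
  rows[[length(rows) + 1L]] <- tibble::add_column(fg, class = "foreground",
                                                  .before = 1L)
  do.call(rbind, rows)
}

fmt_pm <- function(mean, sd) sprintf("%.2f ± %.2f%%", 100 * mean, 100 * sd)

#' Aggregate per-image metric rows
#'
#' Mean and sample (n-1) standard deviation per metric, reported in the
#' conventional "mean +/- sd %" style; the sd of a single row is 0. When a
#' `method` column is present, one summary block per method is returned,
#' ranked by mean F1.
#'
#' @param rows tibble/data frame with numeric columns `accuracy`,
#'   `precision`, `recall`, `f1`, `jaccard` and optionally a `method`
#'   column.
#' @return Tibble with columns `method` (if grouped), `metric`, `mean`,
#'   `sd`, `formatted`, and `rank` (by mean F1) when grouped.
#' @export
aggregate_metrics <- function(rows) {
  if (nrow(rows) == 0L) stop("no metric rows to aggregate")
  metrics <- c("accuracy", "precision", "recall", "f1", "jaccard")
  one_block <- function(df) {
    tibble::tibble(
      metric = metrics,
      mean = vapply(metrics, function(m) mean(df[[m]]), numeric(1),
                    USE.NAMES = FALSE),
      sd = vapply(metrics, function(m) {
        if (nrow(df) > 1L) stats::sd(df[[m]]) else 0
      }, numeric(1), USE.NAMES = FALSE)
    )
  }
  if (!"method" %in% names(rows)) {
    out <- one_block(rows)
    out$formatted <- fmt_pm(out$mean, out$sd)
    return(out)
  }
  blocks <- lapply(split(rows, rows$method), one_block)
  f1mean <- vapply(blocks, function(b) b$mean[b$metric == "f1"], numeric(1))
  rank <- rank(-f1mean, ties.method = "first")
  out <- do.call(rbind, lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    tibble::add_column(b, method = nm, .before = 1L)
  }))
  out$formatted <- fmt_pm(out$mean, out$sd)
  out$rank <- rank[match(out$method, names(blocks))]
  out[order(out$rank), ]
}
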