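#' Multiclass confusion matrix with per-class TP/FP/TN/FN
#'
#' Builds the predicted-by-true count matrix and derives the per-class
#' counts: for class c, TP is the diagonal entry, FP the rest of row c
#' (predicted c but true elsewhere), FN the rest of column c, and TN the
#' remainder.
#'
#' @param truth True class label per observation.
#' @param estimate Predicted class label per observation.
#' @param classes Ordered class labels; defaults to the sorted union of
#'   both label vectors. Labels outside `classes` are an error.
#' @return An object of class `confusion_stats`: list with `classes`,
#'   `counts` (square matrix, rows = predicted, columns = true),
#'   `per_class` (tibble `class`, `tp`, `fp`, `tn`, `fn`) and `source`.
#' @export
confusion_matrix <- function(truth, estimate, classes = NULL) {
  stopifnot(length(truth) == length(estimate))
  classes <- classes %||% sort(unique(c(truth, estimate)))
  bad <- setdiff(unique(c(truth, estimate)), classes)
  if (length(bad) > 0) {
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(estimate, classes), factor(truth, classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(predicted = classes, true = classes))
  new_confusion(counts, source = "predictions")
}

new_confusion <- function(counts, per_class = NULL, source = "predictions") {
  classes <- rownames(counts)
  if (is.null(per_class)) {
    tp <- diag(counts)
    per_class <- tibble(
      class = classes,
      tp = as.integer(tp),
      fp = as.integer(rowSums(counts) - tp),
      fn = as.integer(colSums(counts) - tp),
      tn = as.integer(sum(counts) - rowSums(counts) - colSums(counts) + tp)
    )
  }
  structure(list(classes = classes, counts = counts,
                 per_class = per_class[c("class", "tp", "fp", "tn", "fn")],
                 source = source),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat("Multiclass confusion matrix (", x$source, "), ",
      length(x$classes), " classes, n = ", sum(x$counts), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

pc_row <- function(stats, class) {
  row <- stats$per_class[stats$per_class$class == class, ]
  if (nrow(row) != 1) stop("unknown class '", class, "'", call. = FALSE)
  row
}

measure_ratio <- function(num, den, measure, class) {
  if (den == 0) {
    stop("zero denominator computing ", measure, " for class '", class, "'",
         call. = FALSE)
  }
  num / den
}

#' Per-class performance measures
#'
#' The four standard measures computed from a class's TP/FP/TN/FN counts:
#' accuracy (TP+TN)/(TP+FP+TN+FN), sensitivity TP/(TP+FN), specificity
#' TN/(FP+TN), and f-score 2TP/(2TP+FP+FN). All lie in `[0, 1]`; a zero
#' denominator is an error naming the measure and class, except the f-score
#' which is 0 when TP = 0 but FP+FN > 0.
#'
#' @param stats A `confusion_stats` object.
#' @param class A class label present in `stats`.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(stats, class) {
  r <- pc_row(stats, class)
  measure_ratio(r$tp + r$tn, r$tp + r$fp + r$tn + r$fn, "accuracy", class)
}

#' @rdname accuracy
#' @export
sensitivity <- function(stats, class) {
  r <- pc_row(stats, class)
  measure_ratio(r$tp, r$tp + r$fn, "sensitivity", class)
}

#' @rdname accuracy
#' @export
specificity <- function(stats, class) {
  r <- pc_row(stats, class)
  measure_ratio(r$tn, r$fp + r$tn, "specificity", class)
}

#' @rdname accuracy
#' @export
f_score <- function(stats, class) {
  r <- pc_row(stats, class)
  measure_ratio(2 * r$tp, 2 * r$tp + r$fp + r$fn, "f-score", class)
}

#' Correct classification rate
#'
#' Fraction of observations on the diagonal of the predicted-by-true count
#' matrix (pooled trace/total).
#'
#' @param stats A `confusion_stats` object.
#' @return A number in `[0, 1]`.
#' @export
ccr <- function(stats) {
  total <- sum(stats$counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(stats$counts)) / total
}

#' All per-class measures as a tibble
#'
#' @param stats A `confusion_stats` object.
#' @return Tibble with one row per class: the TP/FP/TN/FN counts and
#'   accuracy, sensitivity, specificity, f-score.
#' @export
class_metrics <- function(stats) {
  stats$per_class |>
    mutate(
      accuracy = (.data$tp + .data$tn) /
        (.data$tp + .data$fp + .data$tn + .data$fn),
      sensitivity = .data$tp / (.data$tp + .data$fn),
      specificity = .data$tn / (.data$fp + .data$tn),
      f_score = 2 * .data$tp / (2 * .data$tp + .data$fp + .data$fn)
    )
}

#' Macro-averaged performance measures
#'
#' Unweighted arithmetic mean of each per-class measure over classes.
#'
#' @param stats A `confusion_stats` object (or a [class_metrics()] tibble).
#' @return One-row tibble: `macro_accuracy`, `macro_sensitivity`,
#'   `macro_specificity`, `macro_f_score`.
#' @export
macro_average <- function(stats) {
  m <- if (inherits(stats, "confusion_stats")) class_metrics(stats) else stats
  tibble(
    macro_accuracy = mean(m$accuracy),
    macro_sensitivity = mean(m$sensitivity),
    macro_specificity = mean(m$specificity),
    macro_f_score = mean(m$f_score)
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_stats` object.
#' @param ... Unused.
#' @return [class_metrics()] of `x`.
#' @method tidy confusion_stats
#' @export
tidy.confusion_stats <- function(x, ...) class_metrics(x)

#' Read a published confusion-table fixture
#'
#' The fixture dialect mirrors the published riboswitch tables: a TSV whose
#' first seven rows are the predicted-by-true counts (row label = predicted
#' family) and whose last four rows, labelled TP/FP/TN/FN, carry the
#' published per-class counts verbatim. The printed rows are used directly
#' rather than re-derived from the 7x7 counts, because the published
#' per-class denominators demonstrably follow those rows.
#'
#' @param path Path to a confusion fixture TSV.
#' @return A `confusion_stats` object with `source = "fixture"`.
#' @export
read_confusion_fixture <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    row = readr::col_character(), .default = readr::col_integer()
  ))
  classes <- setdiff(names(raw), "row")
  body <- raw[!raw$row %in% c("TP", "FP", "TN", "FN"), ]
  stopifnot(identical(body$row, classes))
  counts <- as.matrix(body[classes])
  dimnames(counts) <- list(predicted = classes, true = classes)
  pick <- function(lbl) as.integer(raw[raw$row == lbl, classes])
  per_class <- tibble(class = classes, tp = pick("TP"), fp = pick("FP"),
                      tn = pick("TN"), fn = pick("FN"))
  new_confusion(counts, per_class = per_class, source = "fixture")
}

#' Published riboswitch confusion matrices
#'
#' The four packaged confusion matrices (LDA, PNN, decision tree, KNN) for
#' the seven riboswitch families, with the published per-class TP/FP/TN/FN
#' rows.
#'
#' @param classifier One of `"lda"`, `"pnn"`, `"tree"`, `"knn"`.
#' @return A `confusion_stats` object.
#' @export
riboswitch_confusion <- function(classifier = c("lda", "pnn", "tree",
                                                "knn")) {
  classifier <- match.arg(classifier)
  read_confusion_fixture(system.file(
    "extdata", paste0("confusion_", classifier, ".tsv"),
    package = "riboblock"
  ))
}

#' Recompute published performance figures from the packaged tables
#'
#' Applies the performance-measure formulas to the packaged confusion
#' tables and compares each recomputed value (in percent, to 2 decimals)
#' with the corresponding published figure. Per-class measures and macro
#' averages come from the printed TP/FP/TN/FN rows; CCRs are pooled
#' trace/total of the 7x7 counts. The published PNN and decision-tree CCRs
#' are fold-mean values and are expected to deviate from trace/total; they
#' are reported here, not hidden.
#'
#' @return Tibble with columns `classifier`, `scope`, `measure`,
#'   `computed`, `printed`, `match` (agreement to 2 decimals on the
#'   percentage scale).
#' @export
paper_check <- function() {
  printed <- readr::read_tsv(
    system.file("extdata", "printed_measures.tsv", package = "riboblock"),
    col_types = readr::cols(
      classifier = readr::col_character(),
      scope = readr::col_character(),
      measure = readr::col_character(),
      printed = readr::col_double()
    )
  )
  measure_fun <- list(accuracy = accuracy, sensitivity = sensitivity,
                      specificity = specificity, f_score = f_score)
  computed <- purrr::pmap_dbl(printed, function(classifier, scope, measure,
                                                printed) {
    stats <- riboswitch_confusion(classifier)
    val <- if (scope == "ccr") {
      ccr(stats)
    } else if (scope == "macro") {
      macro_average(stats)[[paste0("macro_", measure)]]
    } else {
      measure_fun[[measure]](stats, scope)
    }
    100 * val
  })
  printed |>
    mutate(computed = round(computed, 2), .before = "printed") |>
    mutate(match = abs(.data$computed - .data$printed) < 0.005 + 1e-9)
}
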