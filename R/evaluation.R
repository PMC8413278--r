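#' Per-class accuracy
#'
#' For each class `c`, the fraction of rows with true label `c` that were
#' predicted as `c` (correct predictions divided by the total number of
#' cells per input label). Classes absent from `truth` get `NA`, not zero.
#'
#' @param truth Character/factor vector of true labels.
#' @param estimate Character/factor vector of predicted labels, aligned
#'   with `truth`.
#' @param classes Class universe (default [class_order()]).
#'
#' @return Tibble `class`, `n`, `accuracy`.
#' @export
per_class_accuracy <- function(truth, estimate, classes = class_order()) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  check_that(length(truth) == length(estimate),
             "`truth` and `estimate` must have the same length.")
  check_that(length(truth) > 0L, "Empty input.")
  tibble::tibble(
    class = classes,
    n = vapply(unname(classes), function(cl) sum(truth == cl), integer(1),
               USE.NAMES = FALSE),
    accuracy = vapply(unname(classes), function(cl) {
      ncl <- sum(truth == cl)
      if (ncl == 0L) NA_real_
      else sum(truth == cl & estimate == cl) / ncl
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Confusion matrix
#'
#' @inheritParams per_class_accuracy
#' @return Integer matrix, rows = true class, columns = predicted class;
#'   each row sums to that class's count.
#' @export
confusion_matrix <- function(truth, estimate, classes = class_order()) {
  truth <- factor(as.character(truth), levels = classes)
  estimate <- factor(as.character(estimate), levels = classes)
  check_that(length(truth) == length(estimate) && length(truth) > 0L,
             "`truth` and `estimate` must be aligned and non-empty.")
  m <- table(truth = truth, predicted = estimate)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(truth = classes, predicted = classes))
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps every distinct score threshold, computing the true-positive rate
#' against the false-positive rate, and integrates the curve with the
#' trapezoid rule. Collapsing tied scores into single curve vertices makes
#' the trapezoidal area identical to the rank statistic: the probability
#' that a random positive outranks a random negative, with ties counted
#' half.
#'
#' @param scores Numeric scores for the positive class (e.g. its softmax
#'   probability).
#' @param labels True labels; logical/0-1, or anything comparable to
#'   `positive_class`.
#' @param positive_class Which label value counts as positive; required
#'   when `labels` is not logical/0-1.
#'
#' @return An object of class `roc_ovr`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`, starting at (0,0) and ending at (1,1)),
#'   `auc` and `positive_class`. Errors when only one class is present.
#' @export
roc_ovr <- function(scores, labels, positive_class = NULL) {
  check_that(length(scores) == length(labels) && length(scores) > 0L,
             "`scores` and `labels` must be aligned and non-empty.")
  check_that(all(is.finite(scores)), "`scores` must be finite.")
  if (is.null(positive_class)) {
    check_that(is.logical(labels) || all(labels %in% c(0, 1)),
               "Provide `positive_class` for non-binary labels.")
    pos <- as.logical(labels)
  } else {
    pos <- as.character(labels) == as.character(positive_class)
  }
  n_pos <- sum(pos); n_neg <- sum(!pos)
  check_that(n_pos > 0L && n_neg > 0L,
             "AUC is undefined with a single class present.",
             class = "phasedeath_degenerate_labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # one vertex per distinct score value
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  points <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(points$fpr) *
               (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(
    list(points = points, auc = auc,
         positive_class = positive_class %||% TRUE,
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_ovr"
  )
}

#' @export
print.roc_ovr <- function(x, ...) {
  cat(sprintf("<roc_ovr> positive = %s: AUC = %.4f (%d pos / %d neg, %d vertices)\n",
              format(x$positive_class), x$auc, x$n_pos, x$n_neg,
              nrow(x$points)))
  invisible(x)
}

#' Assemble the evaluation report
#'
#' Bundles per-class accuracy, the 3x3 confusion matrix and one-vs-rest
#' ROC/AUC per class (using each class's softmax probability as its
#' score) into a single report object.
#'
#' @param predictions Prediction tibble from [predict.cell_classifier()]
#'   (columns `.pred_class` and `p_<class>` for each class).
#' @param truth True labels aligned with `predictions`; all classes in
#'   `classes` must be represented.
#' @param classes Class universe.
#'
#' @return An object of class `eval_report` with fields
#'   `per_class_accuracy`, `confusion`, `roc` (named list of vertex
#'   tibbles), `auc` (named vector), `n_per_class`, `overall_accuracy`.
#' @export
build_report <- function(predictions, truth, classes = class_order()) {
  check_that(
    is.data.frame(predictions) && ".pred_class" %in% names(predictions),
    "`predictions` must come from predict() (missing `.pred_class`)."
  )
  truth <- as.character(truth)
  check_that(nrow(predictions) == length(truth),
             "`predictions` and `truth` must be aligned.")
  check_that(all(classes %in% truth),
             "Every class must be represented in `truth`.")
  estimate <- as.character(predictions$.pred_class)
  acc <- per_class_accuracy(truth, estimate, classes)
  conf <- confusion_matrix(truth, estimate, classes)
  roc <- lapply(classes, function(cl) {
    col <- paste0("p_", cl)
    check_that(col %in% names(predictions),
               sprintf("`predictions` is missing the score column '%s'.", col))
    roc_ovr(predictions[[col]], truth, positive_class = cl)
  })
  names(roc) <- classes
  structure(
    list(
      per_class_accuracy = acc,
      confusion = conf,
      roc = lapply(roc, `[[`, "points"),
      auc = vapply(roc, `[[`, numeric(1), "auc"),
      n_per_class = stats::setNames(acc$n, acc$class),
      overall_accuracy = mean(estimate == truth),
      classes = classes
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (cl in x$classes) {
    i <- match(cl, x$per_class_accuracy$class)
    cat(sprintf("  %-12s n = %5d  accuracy = %s  AUC = %.3f\n",
                cl, x$per_class_accuracy$n[i],
                formatC(x$per_class_accuracy$accuracy[i], digits = 3,
                        format = "f"),
                x$auc[cl]))
  }
  cat(sprintf("  overall accuracy = %.3f\n", x$overall_accuracy))
  invisible(x)
}

#' @rdname build_report
#' @param x,object An `eval_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  dplyr::mutate(x$per_class_accuracy, auc = unname(x$auc[.data$class]))
}

#' @rdname build_report
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n = sum(x$n_per_class),
    overall_accuracy = x$overall_accuracy,
    macro_accuracy = mean(x$per_class_accuracy$accuracy, na.rm = TRUE),
    macro_auc = mean(x$auc)
  )
}

#' @rdname build_report
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  pts <- dplyr::bind_rows(
    lapply(object$classes, function(cl) {
      dplyr::mutate(object$roc[[cl]], class = cl)
    })
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      colour = NULL, title = "One-vs-rest ROC",
      subtitle = paste(
        sprintf("%s AUC = %.3f", object$classes, object$auc[object$classes]),
        collapse = "   "
      )
    )
}

#' Write an evaluation report to disk
#'
#' JSON report plus CSVs of the confusion matrix and ROC vertices.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      per_class_accuracy = report$per_class_accuracy,
      auc = as.list(report$auc),
      n_per_class = as.list(report$n_per_class),
      overall_accuracy = report$overall_accuracy,
      confusion = as.data.frame.matrix(report$confusion)
    ),
    file.path(dir, "eval_report.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   file.path(dir, "confusion.csv"))
  roc_df <- dplyr::bind_rows(
    lapply(report$classes,
           function(cl) dplyr::mutate(report$roc[[cl]], class = cl))
  )
  utils::write.csv(roc_df, file.path(dir, "roc_points.csv"),
                   row.names = FALSE)
  invisible(dir)
}
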