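#' Grade call from a linear prediction
#'
#' Threshold-at-zero rule: a negative score is called LGG, a positive score
#' HGG. A score of exactly 0 (a measure-zero event for continuous features)
#' is called HGG by convention, so the clinically costlier miss -- an
#' undercalled high-grade tumor -- is avoided.
#'
#' @param yhat numeric prediction(s); must be finite.
#' @return character vector of `"LGG"` / `"HGG"` calls.
#' @export
classify <- function(yhat) {
  if (any(!is.finite(yhat))) abort("non-finite prediction")
  ifelse(yhat < 0, "LGG", "HGG")
}

#' Clipped absolute error of a prediction
#'
#' Absolute deviation from the class ideal (-10 for LGG, +10 for HGG) after
#' clamping over-confident predictions to the ideal: an LGG scored below -10
#' or an HGG scored above +10 is not a bad result and contributes 0.
#'
#' @param yhat numeric prediction(s).
#' @param grade true grade(s), `"LGG"` / `"HGG"`.
#' @param targets named class ideals.
#' @return numeric error contribution(s) in `[0, 20]`.
#' @export
clipped_error <- function(yhat, grade, targets = c(LGG = -10, HGG = 10)) {
  if (any(!is.finite(yhat))) abort("non-finite prediction")
  assert_grades(grade)
  ifelse(grade == "LGG",
         abs(pmax(yhat, targets[["LGG"]]) - targets[["LGG"]]),
         abs(pmin(yhat, targets[["HGG"]]) - targets[["HGG"]]))
}

#' Evaluate a grading model on a labeled feature table
#'
#' Applies the model, makes threshold-0 calls, and computes the confusion
#' counts (HGG is the positive class), sensitivity, specificity and accuracy
#' in percent, and the clipped mean absolute error.
#'
#' @param model a `"glioma_model"`.
#' @param features labeled feature table (`id`, `grade`, model variables),
#'   typically the testing gliomas.
#' @return object of class `"glioma_eval"`: list with `predictions` (tibble
#'   `id`, `grade`, `yhat`, `call`, `error`), confusion counts `tp`, `tn`,
#'   `fp`, `fn`, and metrics `sensitivity`, `specificity`, `accuracy`
#'   (percent, full precision; printed to 2 decimals) and `mae`. A metric
#'   whose class is absent is `NaN`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
evaluate_model <- function(model, features) {
  stopifnot(is.data.frame(features), all(c("id", "grade") %in% names(features)))
  if (nrow(features) == 0) abort("empty testing set")
  assert_grades(features$grade)
  yhat <- predict(model, features)
  call <- classify(yhat)
  err <- clipped_error(yhat, features$grade, model$targets)
  tp <- sum(features$grade == "HGG" & call == "HGG")
  fn <- sum(features$grade == "HGG" & call == "LGG")
  tn <- sum(features$grade == "LGG" & call == "LGG")
  fp <- sum(features$grade == "LGG" & call == "HGG")
  structure(list(
    predictions = tibble::tibble(id = features$id, grade = features$grade,
                                 yhat = yhat, call = call, error = err),
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / nrow(features),
    mae = mean(err)
  ), class = "glioma_eval")
}

#' @export
print.glioma_eval <- function(x, ...) {
  cat(sprintf(paste0("Grading evaluation on %d gliomas (HGG positive):\n",
                     "  sensitivity %.2f%%  specificity %.2f%%  ",
                     "accuracy %.2f%%  mae %.2f\n"),
              nrow(x$predictions), x$sensitivity, x$specificity,
              x$accuracy, x$mae))
  invisible(x)
}

#' @rdname evaluate_model
#' @param x a `"glioma_eval"`.
#' @param ... unused.
#' @return `tidy()`: the per-glioma prediction tibble; `glance()`: one-row
#'   tibble of confusion counts and metrics.
#' @export
tidy.glioma_eval <- function(x, ...) x$predictions

#' @rdname evaluate_model
#' @export
glance.glioma_eval <- function(x, ...) {
  tibble::tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy, mae = x$mae)
}

#' Prediction dot plot for an evaluation
#'
#' One point per glioma at its linear score, grouped by true grade, with the
#' decision threshold at 0 and the class ideals at -10/+10; misclassified
#' gliomas are hollow.
#'
#' @param object a `"glioma_eval"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.glioma_eval <- function(object, ...) {
  df <- object$predictions |>
    dplyr::arrange(.data$grade, .data$yhat) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  correct = .data$grade == .data$call)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$yhat, y = .data$rank,
                                   shape = .data$grade,
                                   alpha = .data$correct)) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::geom_vline(xintercept = c(-10, 10), linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "prediction (au)", y = "glioma",
                  shape = "true grade",
                  title = "Model predictions vs decision threshold")
}
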