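#' Grade gliomas end to end
#'
#' Applies a grading model to either a ready-made feature table or a volume
#' cohort (in which case GLSZM features are computed first from the volumes,
#' which must already be intensity-normalized; see [normalize_cohort()]).
#'
#' @param x feature table (`id`, feature columns, optional `grade`) or a
#'   `"glioma_cohort"` tibble of normalized volumes.
#' @param model a `"glioma_model"`; default the published three-feature
#'   classifier.
#' @param sources sources to extract when `x` is a volume cohort.
#' @return tibble `id`, (`grade`,) `yhat`, `call`.
#' @export
run_grading <- function(x, model = published_model(),
                        sources = c("T1Gd_NCRNET", "T2_NCRNET")) {
  features <- if (inherits(x, "glioma_cohort")) {
    extract_cohort_features(x, sources)
  } else {
    x
  }
  yhat <- predict(model, features)
  out <- tibble::tibble(id = as.character(features$id), yhat = yhat,
                        call = classify(yhat))
  if ("grade" %in% names(features)) {
    out <- dplyr::mutate(out, grade = features$grade, .after = "id")
  }
  out
}

#' Run the full under-sampling training experiment
#'
#' Reproduces the model-building study on a labeled feature table: make the
#' split (balanced testing subset + `n_subsets` balanced training subsets),
#' rank features per subset with the rank-sum test for every contrast-region
#' combination, exclude combinations with `d = 0`, build the `d` averaged
#' models per surviving combination, evaluate each on the testing subset,
#' pick the best model (highest accuracy, then lowest clipped MAE, then
#' fewest variables, then listing order), and -- when the best model has at
#' least two variables -- build and evaluate its reduced models.
#'
#' @param features labeled cohort feature table.
#' @param sources feature sources defining the combinations (each must have
#'   its 13 columns in `features`).
#' @param n_test_per_class,n_train_per_class,n_subsets split sizes, see
#'   [make_split()].
#' @param seed root seed for the split.
#' @param alpha rank-sum significance threshold.
#' @param targets class targets for the regressions.
#' @param mode consensus matching mode, see [select_matching_subsets()].
#' @return object of class `"grading_experiment"`: list with
#'   \describe{
#'     \item{split}{the `"data_split"`.}
#'     \item{combinations}{tibble `combination`, `n_features`, `d`,
#'       `excluded`.}
#'     \item{models}{tibble `combination`, `t`, `w`, `model` (list), and the
#'       testing metrics of every built model.}
#'     \item{best}{the best `"glioma_model"` and `best_eval`.}
#'     \item{reduced}{tibble like `models` keyed by variable positions, or
#'       `NULL` when the best model has one variable.}
#'     \item{best_reduced}{best reduced model (same selection rule).}
#'   }
#' @export
run_training_experiment <- function(features,
                                    sources = default_sources(),
                                    n_test_per_class = 34L,
                                    n_train_per_class = 30L,
                                    n_subsets = 100L,
                                    seed = 1L, alpha = 0.05,
                                    targets = c(LGG = -10, HGG = 10),
                                    mode = c("set", "order")) {
  mode <- match.arg(mode)
  cols <- feature_columns(sources)
  miss <- setdiff(cols, names(features))
  if (length(miss) > 0) {
    abort(paste0("feature table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  split <- make_split(features, n_test_per_class, n_train_per_class,
                      n_subsets, seed)
  testing <- features[match(split$testing$id, features$id), ]
  p_matrix <- ranksum_matrix(features, split, cols)
  combos <- enumerate_combinations(sources)

  model_rows <- list()
  comb_d <- integer(nrow(combos))
  per_comb <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    fc <- feature_columns(combos$sources[[k]])
    ranked <- ranked_from_matrix(p_matrix, fc, alpha)
    consensus <- build_consensus(ranked)
    comb_d[k] <- consensus$d
    if (consensus$d == 0) {
      inform(paste0("combination ", combos$combination[k],
                    " excluded: no universally significant features (d = 0)"))
      next
    }
    per_comb[[k]] <- list(ranked = ranked, consensus = consensus)
    for (t in seq_len(consensus$d)) {
      m <- tryCatch(
        build_unique_model(features, split, ranked, consensus, t, mode,
                           targets, combination = combos$combination[k]),
        error = function(e) NULL)
      if (is.null(m)) next
      ev <- evaluate_model(m, testing)
      model_rows[[length(model_rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(combination = combos$combination[k], t = t, w = m$w,
                       model = list(m), eval = list(ev)),
        glance(ev)[c("sensitivity", "specificity", "accuracy", "mae")])
    }
  }
  combinations <- dplyr::mutate(combos[c("combination", "n_features")],
                                d = comb_d, excluded = comb_d == 0)
  models <- dplyr::bind_rows(model_rows)

  best <- NULL; best_eval <- NULL; reduced <- NULL; best_reduced <- NULL
  best_reduced_eval <- NULL
  if (nrow(models) > 0) {
    ord <- order(-models$accuracy, models$mae, models$t)
    bi <- ord[1]
    best <- models$model[[bi]]
    best_eval <- models$eval[[bi]]
    if (length(best$variables) >= 2) {
      k <- match(models$combination[bi], combos$combination)
      rm_list <- build_reduced_models(best, features, split,
                                      per_comb[[k]]$ranked,
                                      per_comb[[k]]$consensus, targets)
      red_rows <- purrr::imap(rm_list, function(m, key) {
        ev <- evaluate_model(m, testing)
        dplyr::bind_cols(
          tibble::tibble(variables = key, t = length(m$variables), w = m$w,
                         model = list(m), eval = list(ev)),
          glance(ev)[c("sensitivity", "specificity", "accuracy", "mae")])
      })
      reduced <- dplyr::bind_rows(red_rows)
      ord_r <- order(-reduced$accuracy, reduced$mae, reduced$t)
      best_reduced <- reduced$model[[ord_r[1]]]
      best_reduced_eval <- reduced$eval[[ord_r[1]]]
    }
  }
  structure(list(split = split, combinations = combinations, models = models,
                 best = best, best_eval = best_eval, reduced = reduced,
                 best_reduced = best_reduced,
                 best_reduced_eval = best_reduced_eval,
                 sources = sources, seed = seed),
            class = "grading_experiment")
}

#' @export
print.grading_experiment <- function(x, ...) {
  cat("Grading experiment over", nrow(x$combinations), "combinations;",
      sum(!x$combinations$excluded), "survived (d >= 1),",
      nrow(x$models) %||% 0, "averaged models built\n")
  if (!is.null(x$best)) {
    cat("Best model:\n")
    print(x$best)
    print(x$best_eval)
  }
  invisible(x)
}

#' @rdname run_training_experiment
#' @param x a `"grading_experiment"`.
#' @param ... unused.
#' @return `tidy()`: the per-model metrics tibble (`combination`, `t`, `w`,
#'   sensitivity/specificity/accuracy/mae); `glance()`: one row describing
#'   the experiment and its best model.
#' @export
tidy.grading_experiment <- function(x, ...) {
  if (nrow(x$models) == 0) return(x$models)
  dplyr::select(x$models, !dplyr::any_of(c("model", "eval")))
}

#' @rdname run_training_experiment
#' @export
glance.grading_experiment <- function(x, ...) {
  tibble::tibble(
    n_combinations = nrow(x$combinations),
    n_excluded = sum(x$combinations$excluded),
    n_models = if (is.null(x$models)) 0L else nrow(x$models),
    best_combination = if (is.null(x$best)) NA_character_ else x$best$combination,
    best_t = if (is.null(x$best)) NA_integer_ else length(x$best$variables),
    best_accuracy = if (is.null(x$best_eval)) NA_real_ else x$best_eval$accuracy,
    best_mae = if (is.null(x$best_eval)) NA_real_ else x$best_eval$mae
  )
}

#' Metrics-vs-model-size plot for an experiment
#'
#' Sensitivity, specificity and accuracy of every averaged model against its
#' number of variables, one panel per surviving combination.
#'
#' @param object a `"grading_experiment"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.grading_experiment <- function(object, ...) {
  df <- tidy(object)
  if (is.null(df) || nrow(df) == 0) abort("no models to plot")
  long <- tidyr::pivot_longer(df, c("sensitivity", "specificity", "accuracy"),
                              names_to = "metric", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$percent,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$combination)) +
    ggplot2::labs(x = "number of variables", y = "percent",
                  title = "Testing performance of averaged models")
}
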