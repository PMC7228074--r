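#' Enumerate contrast-region combinations
#'
#' All non-empty subsets of the feature sources, ordered by size then by the
#' source order given (for the four default sources this reproduces the
#' study's 15-combination table, with 13/26/39/52 feature columns).
#'
#' @param sources distinct source ids (1 to 4 of them in the studied design).
#' @return tibble with `combination` (id string, sources joined by `+`),
#'   `sources` (list-column) and `n_features` (13 per source).
#' @examples
#' enumerate_combinations(default_sources())
#' @export
enumerate_combinations <- function(sources = default_sources()) {
  if (anyDuplicated(sources)) abort("`sources` must be distinct")
  k <- length(sources)
  subsets <- unlist(lapply(seq_len(k), function(m) {
    combn(seq_len(k), m, simplify = FALSE)
  }), recursive = FALSE)
  tibble::tibble(
    combination = vapply(subsets, function(s) paste(sources[s], collapse = "+"), ""),
    sources = lapply(subsets, function(s) sources[s]),
    n_features = vapply(subsets, function(s) 13L * length(s), integer(1))
  )
}

#' Training subsets whose top-ranked features match the consensus
#'
#' A training subset qualifies for the `t`-variable model when its first `t`
#' ordered significant features coincide with the first `t` consensus
#' features. "Coincide" defaults to set equality over those positions (the
#' interpretation consistent with the reduced-model subset rule); strict
#' order equality is available via `mode = "order"`.
#'
#' @param ranked list of [rank_subset()] results.
#' @param consensus a [build_consensus()] result.
#' @param t number of leading variables, `1 <= t <= d`.
#' @param mode `"set"` (default) or `"order"`.
#' @return integer vector of qualifying subset indices (length `w`); errors
#'   when no subset qualifies.
#' @export
select_matching_subsets <- function(ranked, consensus, t, mode = c("set", "order")) {
  mode <- match.arg(mode)
  if (t < 1 || t > consensus$d) abort("`t` must satisfy 1 <= t <= d")
  target <- consensus$features[seq_len(t)]
  ok <- vapply(ranked, function(r) {
    if (attr(r, "D") < t) return(FALSE)
    top <- r$feature[seq_len(t)]
    if (mode == "set") setequal(top, target) else identical(top, target)
  }, logical(1))
  w <- which(ok)
  if (length(w) == 0) abort(paste0("no qualifying subsets for t = ", t))
  w
}

#' Ordinary least-squares fit of one training subset
#'
#' Regresses the class target (-10 for LGG, +10 for HGG) on the given raw
#' feature values for the subset's 60 gliomas.
#'
#' @param features cohort feature table.
#' @param subset list with `LGG` and `HGG` id vectors.
#' @param variables ordered feature column ids to use as regressors.
#' @param targets named targets per class.
#' @return named coefficient vector: the `variables` then `"(Intercept)"`
#'   last. Rank-deficient designs raise an error.
#' @export
fit_subset_regression <- function(features, subset, variables,
                                  targets = c(LGG = -10, HGG = 10)) {
  if (length(variables) < 1) abort("at least one regressor variable required")
  rows <- match(c(subset$LGG, subset$HGG), features$id)
  if (anyNA(rows)) abort("subset ids missing from feature table")
  x <- as.matrix(features[rows, variables, drop = FALSE])
  y <- c(rep(targets[["LGG"]], length(subset$LGG)),
         rep(targets[["HGG"]], length(subset$HGG)))
  df <- data.frame(y = y, x, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) abort("rank-deficient design: collinear regressors")
  c(cf[variables], cf["(Intercept)"])
}

new_glioma_model <- function(variables, coefficients, intercept, w = 1L,
                             combination = NA_character_,
                             targets = c(LGG = -10, HGG = 10)) {
  structure(list(variables = variables,
                 coefficients = setNames(coefficients, variables),
                 intercept = unname(intercept), w = w,
                 combination = combination, targets = targets),
            class = "glioma_model")
}

#' Averaged ("unique") classification model for t leading variables
#'
#' Fits one OLS model per qualifying training subset (see
#' [select_matching_subsets()]) on the first `t` consensus features, then
#' averages the coefficients (including the constant term) across the `w`
#' qualifying subsets.
#'
#' @inheritParams select_matching_subsets
#' @inheritParams fit_subset_regression
#' @param split a [make_split()], providing the subset memberships.
#' @param combination combination id carried on the model.
#' @return object of class `"glioma_model"`: ordered `variables`, averaged
#'   `coefficients`, `intercept`, contributing-subset count `w`, the
#'   `combination` and the class `targets`. Supports [predict()], [tidy()],
#'   [glance()].
#' @export
build_unique_model <- function(features, split, ranked, consensus, t,
                               mode = c("set", "order"),
                               targets = c(LGG = -10, HGG = 10),
                               combination = NA_character_) {
  mode <- match.arg(mode)
  vars <- consensus$features[seq_len(t)]
  idx <- select_matching_subsets(ranked, consensus, t, mode)
  fits <- vapply(idx, function(i) {
    fit_subset_regression(features, subset_ids(split, i), vars, targets)
  }, numeric(t + 1))
  fits <- matrix(fits, nrow = t + 1)
  avg <- rowMeans(fits)
  new_glioma_model(vars, avg[seq_len(t)], avg[t + 1], w = length(idx),
                   combination = combination, targets = targets)
}

#' Reduced models over all variable subsets of a parent model
#'
#' For a parent averaged model with ordered variables `x_1..x_t`, builds one
#' reduced model per non-empty subset `C` of variable positions. The
#' training subsets feeding subset `C` are those whose first `m = max(C)`
#' ordered features coincide (as a set) with `x_1..x_m`; on those, OLS fits
#' restricted to the variables in `C` are averaged as usual.
#'
#' @param model parent `"glioma_model"` with `t >= 2` variables.
#' @inheritParams build_unique_model
#' @return named list of `"glioma_model"`s keyed like `"1-2-5"` (variable
#'   positions in the parent order); combinations with no qualifying subsets
#'   are skipped with a warning.
#' @export
build_reduced_models <- function(model, features, split, ranked, consensus,
                                 targets = c(LGG = -10, HGG = 10)) {
  t <- length(model$variables)
  if (t < 2) abort("reduced models need a parent model with >= 2 variables")
  combos <- unlist(lapply(seq_len(t), function(m) {
    combn(seq_len(t), m, simplify = FALSE)
  }), recursive = FALSE)
  out <- list()
  for (C in combos) {
    key <- paste(C, collapse = "-")
    m <- max(C)
    idx <- tryCatch(select_matching_subsets(ranked, consensus, m, mode = "set"),
                    error = function(e) NULL)
    if (is.null(idx)) {
      warn(paste0("reduced model ", key, ": no qualifying subsets; skipped"))
      next
    }
    vars <- model$variables[C]
    fits <- vapply(idx, function(i) {
      fit_subset_regression(features, subset_ids(split, i), vars, targets)
    }, numeric(length(C) + 1))
    fits <- matrix(fits, nrow = length(C) + 1)
    avg <- rowMeans(fits)
    out[[key]] <- new_glioma_model(vars, avg[seq_along(C)], avg[length(C) + 1],
                                   w = length(idx),
                                   combination = model$combination,
                                   targets = targets)
  }
  out
}

#' Apply a linear grading model
#'
#' @param object a `"glioma_model"`.
#' @param newdata feature table (or single-row list/vector) containing every
#'   model variable.
#' @param ... unused.
#' @return numeric vector of predictions, one per row: the linear score
#'   whose sign decides the grade (negative LGG, positive HGG).
#' @export
predict.glioma_model <- function(object, newdata, ...) {
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss) > 0) {
    abort(paste0("missing model variable(s): ", paste(miss, collapse = ", ")))
  }
  x <- sapply(object$variables, function(v) as.numeric(newdata[[v]]))
  x <- matrix(x, ncol = length(object$variables))
  if (any(!is.finite(x))) abort("non-finite feature values")
  drop(x %*% object$coefficients + object$intercept)
}

#' @rdname predict.glioma_model
#' @param model a `"glioma_model"`.
#' @param features feature table.
#' @export
apply_model <- function(model, features) predict(model, features)

#' @export
print.glioma_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*%s", x$coefficients, x$variables), collapse = " ")
  cat("Averaged linear grading model", if (!is.na(x$combination))
    paste0("[", x$combination, "]") else "", "\n")
  cat("  y^ =", terms, sprintf("%+.4g", x$intercept), "\n")
  cat("  averaged over w =", x$w, "training subset fit(s);",
      "targets", x$targets[["LGG"]], "(LGG) /", x$targets[["HGG"]], "(HGG)\n")
  invisible(x)
}

#' Broom-style accessors for grading models
#'
#' @param x a `"glioma_model"`.
#' @param ... unused.
#' @return `tidy()`: tibble (`term`, `estimate`) with the intercept last;
#'   `glance()`: one-row tibble (`n_variables`, `w`, `combination`).
#' @export
tidy.glioma_model <- function(x, ...) {
  tibble::tibble(term = c(x$variables, "(Intercept)"),
                 estimate = c(unname(x$coefficients), x$intercept))
}

#' @rdname tidy.glioma_model
#' @export
glance.glioma_model <- function(x, ...) {
  tibble::tibble(n_variables = length(x$variables), w = x$w,
                 combination = x$combination)
}

#' Serialize grading models as JSON
#'
#' @param model a `"glioma_model"`.
#' @param path output path.
#' @return `path` / the model, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(variables = model$variables,
         coefficients = unname(model$coefficients),
         intercept = model$intercept, w = model$w,
         combination = model$combination,
         targets = as.list(model$targets)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_glioma_model(m$variables, m$coefficients, m$intercept,
                   w = if (is.null(m$w)) NA_integer_ else m$w,
                   combination = m$combination %||% NA_character_,
                   targets = unlist(m$targets))
}

#' The published three-feature grading model
#'
#' The explicitly reported best reduced classifier: zone percentage and
#' zone-size variance measured on T2 in the NCR/NET core, and zone-size
#' nonuniformity measured on T1Gd in the NCR/NET core, with averaged
#' coefficients 13.693, -0.410 and 31.842 and constant term -19.500. A
#' negative score grades the glioma LGG, a positive score HGG.
#'
#' @return the packaged `"glioma_model"` (read from the JSON asset shipped
#'   with the package).
#' @examples
#' m <- published_model()
#' predict(m, tibble::tibble(T2_NCRNET_z.perc = 1, T2_NCRNET_zs.var = 0,
#'                           T1Gd_NCRNET_zsnu = 1))
#' @export
published_model <- function() {
  path <- system.file("extdata", "published_model.json", package = "gliotex",
                      mustWork = TRUE)
  read_model(path)
}
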