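#' Testing subset and balanced under-sampled training subsets
#'
#' Implements the data division used by the grading study: one fixed testing
#' subset with equal class counts, and `n_subsets` balanced training subsets
#' drawn from the remainder. The LGG training block is drawn once and shared
#' by every subset (when exactly `n_train_per_class` LGGs remain after the
#' test draw -- the studied cohort's 64 - 34 = 30 case -- it is simply all of
#' them); the HGG members are redrawn independently for each subset, so an
#' HGG may recur across subsets but never overlaps the testing set.
#'
#' @param cohort tibble with `id` and `grade` columns (post reference-volume
#'   exclusion), or a feature table.
#' @param n_test_per_class testing gliomas per class (default 34).
#' @param n_train_per_class training gliomas per class per subset (default 30).
#' @param n_subsets number of training subsets (default 100).
#' @param seed integer seed; the split is deterministic given it.
#' @return object of class `"data_split"`: list with
#'   `testing` (tibble `id`, `grade`), `lgg_train` (character ids), and
#'   `hgg_train` (list of `n_subsets` character vectors), plus the sizes and
#'   seed. `as_tibble()` flattens it to long form (`id`, `grade`, `role`,
#'   `subset`).
#' @export
make_split <- function(cohort, n_test_per_class = 34L, n_train_per_class = 30L,
                       n_subsets = 100L, seed = 1L) {
  stopifnot(is.data.frame(cohort), all(c("id", "grade") %in% names(cohort)))
  assert_grades(cohort$grade)
  ids <- split(as.character(cohort$id), cohort$grade)
  need <- n_test_per_class + n_train_per_class
  for (g in grade_levels()) {
    have <- length(ids[[g]])
    if (is.null(ids[[g]]) || have < need) {
      abort(paste0("not enough ", g, " gliomas: need ", need, " (",
                   n_test_per_class, " test + ", n_train_per_class,
                   " train), have ", have %||% 0))
    }
  }
  withr::with_seed(child_seed(seed, "split"), {
    test_lgg <- sample(ids$LGG, n_test_per_class)
    test_hgg <- sample(ids$HGG, n_test_per_class)
    pool_lgg <- setdiff(ids$LGG, test_lgg)
    pool_hgg <- setdiff(ids$HGG, test_hgg)
    lgg_train <- if (length(pool_lgg) == n_train_per_class) pool_lgg else
      sample(pool_lgg, n_train_per_class)
    hgg_train <- lapply(seq_len(n_subsets), function(i) sample(pool_hgg, n_train_per_class))
  })
  structure(list(testing = tibble::tibble(
    id = c(test_lgg, test_hgg),
    grade = rep(grade_levels(), each = n_test_per_class)),
    lgg_train = lgg_train, hgg_train = hgg_train,
    n_test_per_class = n_test_per_class,
    n_train_per_class = n_train_per_class,
    n_subsets = n_subsets, seed = seed),
    class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("Data split:", x$n_test_per_class, "+", x$n_test_per_class,
      "testing gliomas;", x$n_subsets, "training subsets of",
      x$n_train_per_class, "+", x$n_train_per_class,
      "(shared LGG block)\n")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.data_split <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$testing, role = "testing", subset = NA_integer_),
    tibble::tibble(id = x$lgg_train, grade = "LGG", role = "training",
                   subset = NA_integer_),
    purrr::imap_dfr(x$hgg_train, function(ids, i) {
      tibble::tibble(id = ids, grade = "HGG", role = "training", subset = i)
    })
  )
}

# ids of one training subset (shared LGG block + i-th HGG draw)
subset_ids <- function(split, i) {
  list(LGG = split$lgg_train, HGG = split$hgg_train[[i]])
}
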