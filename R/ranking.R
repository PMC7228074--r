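#' Two-sided Wilcoxon rank-sum p-value
#'
#' Thin, deterministic wrapper used by the per-subset feature ranking. Small
#' tie-free samples are tested exactly (permutation enumeration of the
#' rank-sum statistic); otherwise the normal approximation with tie and
#' continuity correction is used, which is the regime of the 30-vs-30
#' training subsets. Two samples with all values identical carry no ordering
#' information and return p = 1.
#'
#' @param a,b nonempty numeric samples.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact computation;
#'   `NULL` (default) chooses exact for tie-free samples below 50 per group.
#' @return two-sided p-value in (0, 1]; symmetric in `a` and `b`.
#' @export
ranksum_p <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be nonempty")
  if (length(unique(c(a, b))) == 1) return(1)
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
  if (!is.finite(p)) 1 else min(p, 1)
}

#' Rank a combination's features within one training subset
#'
#' Compares every feature between the subset's 30 LGGs and 30 HGGs with the
#' Wilcoxon rank-sum test, orders features by ascending p-value, and keeps
#' only the significant ones (p below `alpha`). The number kept is the
#' subset's `D_i`.
#'
#' @param features cohort feature table (`id`, `grade`, feature columns).
#' @param subset subset membership: list with `LGG` and `HGG` id vectors (as
#'   produced internally by [make_split()]).
#' @param feature_cols which feature columns to rank (default: all).
#' @param alpha significance threshold (default 0.05).
#' @param exact passed to [ranksum_p()].
#' @return object of class `"ranked_features"`: tibble (`feature`, `p`) in
#'   ascending p order truncated at `p < alpha`, with attributes `D` (the
#'   count) and `p_all` (named p-values of every tested feature). p ties
#'   break lexicographically by feature id.
#' @export
rank_subset <- function(features, subset, feature_cols = NULL, alpha = 0.05,
                        exact = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features), c("id", "grade"))
  }
  miss <- setdiff(feature_cols, names(features))
  if (length(miss) > 0) {
    abort(paste0("missing feature column(s): ", paste(miss, collapse = ", ")))
  }
  rows_l <- match(subset$LGG, features$id)
  rows_h <- match(subset$HGG, features$id)
  if (anyNA(rows_l) || anyNA(rows_h)) abort("subset ids missing from feature table")
  p <- vapply(feature_cols, function(f) {
    va <- features[[f]][rows_l]
    vb <- features[[f]][rows_h]
    if (anyNA(va) || anyNA(vb)) abort(paste0("missing values in feature ", f))
    ranksum_p(va, vb, exact = exact)
  }, numeric(1))
  ord <- order(p, feature_cols)
  keep <- ord[p[ord] < alpha]
  structure(tibble::tibble(feature = feature_cols[keep], p = unname(p[keep])),
            D = length(keep), p_all = p, class = c("ranked_features", "tbl_df",
                                                   "tbl", "data.frame"))
}

# p-value matrix (features x subsets) computed once and sliced per combination
ranksum_matrix <- function(features, split, feature_cols = NULL, exact = FALSE) {
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features), c("id", "grade"))
  }
  p <- vapply(seq_len(split$n_subsets), function(i) {
    ids <- subset_ids(split, i)
    rows_l <- match(ids$LGG, features$id)
    rows_h <- match(ids$HGG, features$id)
    vapply(feature_cols, function(f) {
      ranksum_p(features[[f]][rows_l], features[[f]][rows_h], exact = exact)
    }, numeric(1))
  }, numeric(length(feature_cols)))
  p <- matrix(p, nrow = length(feature_cols),
              dimnames = list(feature_cols, NULL))
  p
}

# ranked_features objects for one combination from a precomputed p matrix
ranked_from_matrix <- function(p_matrix, feature_cols, alpha = 0.05) {
  lapply(seq_len(ncol(p_matrix)), function(i) {
    p <- p_matrix[feature_cols, i]
    ord <- order(p, feature_cols)
    keep <- ord[p[ord] < alpha]
    structure(tibble::tibble(feature = feature_cols[keep], p = unname(p[keep])),
              D = length(keep), p_all = p,
              class = c("ranked_features", "tbl_df", "tbl", "data.frame"))
  })
}

#' Ordered highest-frequency consensus features across subsets
#'
#' Aggregates the per-subset rankings: `d = min D_i` caps the model size; for
#' each rank position `s = 1..d` a histogram of the features observed at that
#' position is formed over the subsets, and the most frequent feature not
#' already chosen is taken, yielding `d` distinct ordered features. When a
#' position's histogram offers only already-chosen features, the most
#' frequent unchosen feature pooled over all positions is taken instead (the
#' deterministic extension documented in the methods vignette). Frequency
#' ties break by the lower mean p-value across subsets, then
#' lexicographically.
#'
#' @param ranked list of [rank_subset()] results, one per training subset.
#' @return object of class `"feature_consensus"`: list with `d`, `features`
#'   (character vector of length `d`, the ordered consensus) and `histograms`
#'   (list of `d` frequency tables). `d = 0` yields an empty consensus,
#'   signaling that the combination should be excluded.
#' @export
build_consensus <- function(ranked) {
  if (length(ranked) < 1) abort("need at least one ranked subset")
  D <- vapply(ranked, function(r) attr(r, "D"), integer(1))
  d <- min(D)
  hist_s <- list()
  if (d == 0) {
    return(structure(list(d = 0L, features = character(0), histograms = list()),
                     class = "feature_consensus"))
  }
  # mean p across subsets, the documented frequency tie-break
  p_all <- do.call(rbind, lapply(ranked, function(r) attr(r, "p_all")))
  mean_p <- colMeans(p_all)

  pick <- function(tab, chosen) {
    cand <- tab[!names(tab) %in% chosen]
    if (length(cand) == 0) return(NA_character_)
    ord <- order(-cand, mean_p[names(cand)], names(cand))
    names(cand)[ord[1]]
  }

  chosen <- character(0)
  for (s in seq_len(d)) {
    at_s <- vapply(ranked, function(r) r$feature[s], character(1))
    tab <- table(at_s)
    hist_s[[s]] <- tab
    sel <- pick(tab, chosen)
    if (is.na(sel)) {
      pooled <- table(unlist(lapply(ranked, function(r) r$feature[seq_len(d)])))
      sel <- pick(pooled, chosen)
    }
    if (is.na(sel)) abort("fewer distinct significant features than d")
    chosen <- c(chosen, sel)
  }
  structure(list(d = d, features = chosen, histograms = hist_s),
            class = "feature_consensus")
}

#' @export
print.feature_consensus <- function(x, ...) {
  cat("Feature consensus: d =", x$d, "\n")
  if (x$d > 0) cat(paste0(seq_len(x$d), ". ", x$features, collapse = "\n"), "\n")
  invisible(x)
}
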