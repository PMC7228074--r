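#' The thirteen GLSZM texture features
#'
#' Computes the standard zone-size feature set from a GLSZM. With
#' `s(i, j)` the zone counts, `N_s` the number of zones, `N_v` the number of
#' region voxels and `p(i, j) = s(i, j) / N_s`:
#' \describe{
#'   \item{sze / lze}{small / large zone emphasis,
#'     `(1/N_s) sum s(i,j) / j^2` and `(1/N_s) sum s(i,j) j^2`.}
#'   \item{glnu / zsnu}{gray-level / zone-size nonuniformity,
#'     `(1/N_s) sum_i g_i^2` and `(1/N_s) sum_j z_j^2` over the marginals.}
#'   \item{z.perc}{zone percentage `N_s / N_v`; higher values mean a finer,
#'     more fragmented texture (every zone close to a single voxel).}
#'   \item{lgze / hgze}{low / high gray-level zone emphasis,
#'     `(1/N_s) sum s(i,j) / i^2` and `(1/N_s) sum s(i,j) i^2`.}
#'   \item{szlge, szhge, lzlge, lzhge}{the four joint size/level emphases
#'     with weights `1/(i^2 j^2)`, `i^2/j^2`, `j^2/i^2`, `i^2 j^2`.}
#'   \item{gl.var / zs.var}{variance of the gray level / zone size over the
#'     zone distribution `p(i, j)`.}
#' }
#'
#' @param matrix a [compute_glszm()] result with at least one zone.
#' @return a named numeric vector of length 13 in [glszm_feature_names()]
#'   order.
#' @examples
#' vol <- array(c(1, 2, 1, 3), dim = c(2, 2, 1))
#' compute_features(compute_glszm(vol, array(TRUE, dim(vol))))
#' @export
compute_features <- function(matrix) {
  stopifnot(inherits(matrix, "glszm"))
  s <- matrix$counts$count
  i <- matrix$counts$gray_level
  j <- matrix$counts$zone_size
  ns <- matrix$n_zones
  nv <- matrix$n_voxels
  if (ns < 1) abort("empty GLSZM: no zones")
  p <- s / ns
  marg <- zone_marginals(matrix)
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  out <- c(
    sze    = sum(s / j^2) / ns,
    lze    = sum(s * j^2) / ns,
    glnu   = sum(marg$gray$g^2) / ns,
    zsnu   = sum(marg$size$z^2) / ns,
    z.perc = ns / nv,
    lgze   = sum(s / i^2) / ns,
    hgze   = sum(s * i^2) / ns,
    szlge  = sum(s / (i^2 * j^2)) / ns,
    szhge  = sum(s * i^2 / j^2) / ns,
    lzlge  = sum(s * j^2 / i^2) / ns,
    lzhge  = sum(s * i^2 * j^2) / ns,
    gl.var = sum(p * (i - mu_i)^2),
    zs.var = sum(p * (j - mu_j)^2)
  )
  stopifnot(all(is.finite(out)))
  out
}

#' Per-glioma feature table from a volume cohort
#'
#' Computes, for each glioma in a cohort and each requested source
#' (contrast + region), the 13 GLSZM features, and assembles the cohort
#' feature table used by the splitting / ranking / modeling stages.
#'
#' @param cohort a volume cohort as returned by [generate_volume_cohort()] or
#'   [read_volume_cohort()]: a tibble with one row per (glioma, contrast) and
#'   list-columns `volume` and `mask`.
#' @param sources character vector of source ids, e.g.
#'   `c("T1Gd_NCRNET", "T2_NCRNET")`.
#' @param label_map named integer vector mapping region names to mask labels.
#' @return tibble with columns `id`, `grade` and `13 * length(sources)`
#'   feature columns named `"<source>_<feature>"`. Gliomas missing a required
#'   region are dropped with a warning.
#' @export
extract_cohort_features <- function(cohort, sources = c("T1Gd_NCRNET", "T2_NCRNET"),
                                    label_map = brats_label_map()) {
  stopifnot(is.data.frame(cohort))
  parts <- strsplit(sources, "_", fixed = TRUE)
  contrasts <- vapply(parts, `[`, "", 1L)
  regions <- vapply(parts, function(p) paste(p[-1], collapse = "_"), "")

  ids <- unique(cohort$id)
  header <- c("id", "grade", feature_columns(sources))
  rows <- purrr::map(ids, function(gid) {
    sub <- cohort[cohort$id == gid, , drop = FALSE]
    vals <- numeric(0)
    for (k in seq_along(sources)) {
      row <- which(sub$contrast == contrasts[k])
      if (length(row) != 1) {
        warn(paste0("glioma ", gid, ": contrast ", contrasts[k],
                    " missing; row excluded"))
        return(NULL)
      }
      m <- tryCatch(
        compute_glszm(sub$volume[[row]], sub$mask[[row]],
                      region = regions[k], label_map = label_map),
        error = function(e) {
          warn(paste0("glioma ", gid, ": ", conditionMessage(e),
                      "; row excluded"))
          NULL
        }
      )
      if (is.null(m)) return(NULL)
      vals <- c(vals, compute_features(m))
    }
    tibble::tibble(id = gid, grade = sub$grade[1],
                   !!!setNames(as.list(vals), feature_columns(sources)))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble::as_tibble(setNames(
      c(list(character(0), character(0)),
        rep(list(numeric(0)), 13 * length(sources))), header))
  }
  out
}

#' Read / write cohort feature tables
#'
#' Feature tables are CSV files with header `id,grade,<source>_<feature>,...`.
#'
#' @param path file path.
#' @return `read_feature_table()`: a tibble; unknown grade labels raise an
#'   error.
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("id", "grade") %in% names(tbl))) {
    abort("feature table must have `id` and `grade` columns")
  }
  tbl$id <- as.character(tbl$id)
  assert_grades(tbl$grade)
  tbl
}

#' @rdname read_feature_table
#' @param table feature tibble.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
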