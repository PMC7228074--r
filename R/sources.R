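#' Feature names, sources and column naming
#'
#' A feature *source* is one (MRI contrast, tumor region) pair, written
#' `"<contrast>_<region>"`, e.g. `"T1Gd_NCRNET"`. Each source contributes the
#' thirteen GLSZM features; a feature column in a cohort table is named
#' `"<contrast>_<region>_<feature>"`, e.g. `"T2_NCRNET_z.perc"`.
#'
#' @details
#' The thirteen zone-size features (short names used in column headers):
#' `sze` small zone emphasis, `lze` large zone emphasis, `glnu` gray-level
#' nonuniformity, `zsnu` zone-size nonuniformity, `z.perc` zone percentage,
#' `lgze` low gray-level zone emphasis, `hgze` high gray-level zone emphasis,
#' `szlge`/`szhge` small zone low/high gray-level emphasis, `lzlge`/`lzhge`
#' large zone low/high gray-level emphasis, `gl.var` gray-level variance,
#' `zs.var` zone-size variance.
#'
#' @return `glszm_feature_names()`: character vector of the 13 feature short
#'   names. `default_sources()`: the four default sources (two contrasts x
#'   two regions, necrotic/non-enhancing core `NCRNET` and peritumoral edema
#'   `ED`). `feature_columns(sources)`: the full column-name set for a set of
#'   sources (13 per source).
#' @examples
#' glszm_feature_names()
#' feature_columns("T1Gd_NCRNET")
#' @export
glszm_feature_names <- function() {
  c("sze", "lze", "glnu", "zsnu", "z.perc", "lgze", "hgze",
    "szlge", "szhge", "lzlge", "lzhge", "gl.var", "zs.var")
}

#' @rdname glszm_feature_names
#' @export
default_sources <- function() {
  c("T1Gd_NCRNET", "T1Gd_ED", "T2_NCRNET", "T2_ED")
}

#' @rdname glszm_feature_names
#' @param sources character vector of source ids (`"<contrast>_<region>"`).
#' @export
feature_columns <- function(sources) {
  as.vector(t(outer(sources, glszm_feature_names(), paste, sep = "_")))
}

#' Grade labels and BRATS-style segmentation label map
#'
#' Grades are the strings `"LGG"` and `"HGG"`. Segmentation masks use the
#' BRATS integer convention: 0 background, 1 necrotic and non-enhancing tumor
#' core (NCR/NET), 2 peritumoral edema (ED), 4 Gd-enhancing tumor (ET).
#'
#' @return named integer vector mapping region names to mask labels.
#' @export
brats_label_map <- function() {
  c(background = 0L, NCRNET = 1L, ED = 2L, ET = 4L)
}

grade_levels <- function() c("LGG", "HGG")

tumor_labels <- function(label_map = brats_label_map()) {
  unname(label_map[c("NCRNET", "ED", "ET")])
}

assert_grades <- function(grade) {
  bad <- setdiff(unique(grade), grade_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown grade label(s): ", paste(bad, collapse = ", "),
                 " (expected \"LGG\"/\"HGG\")"))
  }
  invisible(grade)
}

# derive a 32-bit child seed from a root seed and a stream name
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 13) %% 2147483647)
}
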