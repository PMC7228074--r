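#' Mean brain intensity excluding the tumor
#'
#' Average intensity over voxels that are inside the brain (nonzero) and not
#' labeled as any tumor region (NCR/NET, ED or ET). Used to pick the
#' reference volumes for normalization: the tumor environment is highly
#' heterogeneous, so it is left out of the summary.
#'
#' @param volume raw intensity array (nonnegative; 0 = background).
#' @param mask segmentation label array of the same shape.
#' @param label_map named integer label map, see [brats_label_map()].
#' @return scalar mean; errors when no qualifying voxel exists.
#' @export
mean_intensity_excluding_tumor <- function(volume, mask,
                                           label_map = brats_label_map()) {
  if (!identical(dim(volume), dim(mask))) abort("`volume` and `mask` shapes differ")
  sel <- as.vector(volume) != 0 & !(as.vector(mask) %in% tumor_labels(label_map))
  if (!any(sel)) abort("no non-tumor brain voxels to average")
  mean(as.vector(volume)[sel])
}

#' Select reference volumes for intensity normalization
#'
#' Within every stratum (contrast x grade x dataset group), picks the volume
#' with the lowest and the volume with the highest mean non-tumor brain
#' intensity. The gliomas contributing any reference volume should be
#' excluded from all subsequent analysis; [reference_glioma_ids()] returns
#' that set.
#'
#' @param cohort a `"glioma_cohort"` tibble (list-columns `volume`, `mask`);
#'   an optional `group` column stratifies by dataset group.
#' @param label_map named integer label map.
#' @return tibble with one row per stratum: `contrast`, `grade`, (`group`,)
#'   `low_id`, `high_id`. Ties in the mean break toward the lexicographically
#'   smaller id. Strata with fewer than two volumes raise an error.
#' @export
select_reference_volumes <- function(cohort, label_map = brats_label_map()) {
  stopifnot(is.data.frame(cohort))
  by <- intersect(c("contrast", "grade", "group"), names(cohort))
  means <- cohort |>
    dplyr::mutate(.mean = purrr::map2_dbl(.data$volume, .data$mask,
                                          mean_intensity_excluding_tumor,
                                          label_map = label_map))
  refs <- means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        abort(paste0("stratum with fewer than 2 volumes: ",
                     paste(unlist(key), collapse = "/")))
      }
      df <- df[order(df$.mean, df$id), ]
      tibble::tibble(low_id = df$id[1], high_id = df$id[nrow(df)])
    }) |>
    dplyr::ungroup()
  refs
}

#' @rdname select_reference_volumes
#' @param refs a reference table from [select_reference_volumes()].
#' @return [reference_glioma_ids()]: character vector of distinct glioma ids
#'   used as references across all strata.
#' @export
reference_glioma_ids <- function(refs) {
  sort(unique(c(refs$low_id, refs$high_id)))
}

default_landmarks <- function() c(1, seq(10, 90, by = 10), 99)

# landmark intensities of one volume over non-tumor brain voxels
volume_landmarks <- function(volume, mask, percentiles,
                             label_map = brats_label_map()) {
  sel <- as.vector(volume) != 0 & !(as.vector(mask) %in% tumor_labels(label_map))
  vox <- as.vector(volume)[sel]
  if (length(vox) == 0) abort("no non-tumor brain voxels")
  lm <- unname(quantile(vox, percentiles / 100, type = 7))
  if (lm[length(lm)] <= lm[1]) abort("degenerate volume: constant intensities")
  lm
}

#' Learn a standard intensity scale from reference volumes
#'
#' Landmark-based (Nyul-style) scale: each reference volume's landmark
#' intensities (percentiles of the non-tumor brain voxels) are mapped
#' affinely so that the lowest/highest percentile cutoffs land on 1 and 255,
#' then averaged across references. The averaged positions define the common
#' 0-255 output scale (0 stays reserved for background).
#'
#' @param volumes list of raw intensity arrays (the reference volumes).
#' @param masks list of matching segmentation masks.
#' @param percentiles strictly increasing landmark percentiles in (0, 100);
#'   default: 1st and 99th cutoffs plus the deciles 10..90.
#' @param contrast contrast tag carried on the scale.
#' @param label_map named integer label map.
#' @return object of class `"standard_scale"`: list with `percentiles`,
#'   strictly increasing `positions` on \[1, 255\], and `contrast`.
#' @export
learn_standard_scale <- function(volumes, masks,
                                 percentiles = default_landmarks(),
                                 contrast = NA_character_,
                                 label_map = brats_label_map()) {
  if (length(volumes) < 1) abort("need at least one reference volume")
  if (length(volumes) != length(masks)) abort("`volumes` and `masks` lengths differ")
  if (any(diff(percentiles) <= 0) || any(percentiles <= 0) || any(percentiles >= 100)) {
    abort("`percentiles` must be strictly increasing within (0, 100)")
  }
  mapped <- purrr::map2(volumes, masks, function(v, m) {
    lm <- volume_landmarks(v, m, percentiles, label_map)
    1 + (lm - lm[1]) / (lm[length(lm)] - lm[1]) * 254
  })
  pos <- Reduce(`+`, mapped) / length(mapped)
  if (any(diff(pos) < 0)) abort("averaged landmarks are not increasing")
  structure(list(percentiles = percentiles, positions = pos,
                 contrast = contrast),
            class = "standard_scale")
}

#' Normalize a raw volume onto the standard 0-255 scale
#'
#' Applies the monotone piecewise-linear map sending the volume's own
#' landmark intensities to the learned standard positions. Brain voxels are
#' rounded to integers and clamped to \[1, 255\]; background voxels (value 0)
#' stay 0, so 0 keeps meaning "absence of a value".
#'
#' @param volume raw intensity array.
#' @param mask segmentation label array (tumor voxels are excluded from the
#'   landmark estimation but are mapped like every other brain voxel).
#' @param scale a [learn_standard_scale()] result.
#' @param label_map named integer label map.
#' @return integer array of the same shape with values in `{0} U [1, 255]`.
#' @export
normalize_volume <- function(volume, mask, scale,
                             label_map = brats_label_map()) {
  stopifnot(inherits(scale, "standard_scale"))
  if (!identical(dim(volume), dim(mask))) abort("`volume` and `mask` shapes differ")
  own <- volume_landmarks(volume, mask, scale$percentiles, label_map)
  # collapse duplicated own-landmarks so the interpolation knots are strict
  keep <- !duplicated(own)
  own_u <- own[keep]
  pos_u <- scale$positions[keep]
  v <- as.vector(volume)
  brain <- v != 0
  mapped <- approx(own_u, pos_u, xout = v[brain], rule = 2, ties = "ordered")$y
  out <- numeric(length(v))
  out[brain] <- pmin(255, pmax(1, round(mapped)))
  array(as.integer(out), dim(volume))
}

#' Normalize a whole cohort
#'
#' Learns one standard scale per contrast from the reference volumes chosen
#' by [select_reference_volumes()], normalizes every non-reference volume,
#' and drops the reference gliomas from the returned cohort (they are
#' consumed by the normalization and excluded from further work).
#'
#' @param cohort a `"glioma_cohort"` tibble with raw volumes.
#' @param percentiles landmark percentiles, see [learn_standard_scale()].
#' @param label_map named integer label map.
#' @return list with `cohort` (normalized, references removed), `refs`
#'   (reference table) and `scales` (named list of `"standard_scale"`s).
#' @export
normalize_cohort <- function(cohort, percentiles = default_landmarks(),
                             label_map = brats_label_map()) {
  refs <- select_reference_volumes(cohort, label_map)
  ref_ids <- reference_glioma_ids(refs)
  scales <- purrr::map(
    setNames(unique(cohort$contrast), unique(cohort$contrast)),
    function(ctr) {
      sub <- cohort[cohort$contrast == ctr & cohort$id %in% ref_ids, ]
      learn_standard_scale(sub$volume, sub$mask, percentiles, contrast = ctr,
                           label_map = label_map)
    })
  rest <- cohort[!cohort$id %in% ref_ids, ]
  rest$volume <- purrr::pmap(list(rest$volume, rest$mask, rest$contrast),
                             function(v, m, ctr) {
                               normalize_volume(v, m, scales[[ctr]], label_map)
                             })
  list(cohort = rest, refs = refs, scales = scales)
}
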