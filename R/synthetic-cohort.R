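#' Specification of a synthetic two-class glioma cohort
#'
#' Describes an imbalanced LGG/HGG cohort whose classes differ in zone-size
#' statistics inside the necrotic/non-enhancing core (NCR/NET), differently
#' per MRI contrast. Volumes are built by nearest-seed (Voronoi-style)
#' labeling of Poisson-seeded points -- the mean seed spacing is the
#' characteristic zone edge length, which directly controls the zone sizes
#' the GLSZM measures -- followed by uniform gray-level assignment of cells
#' and per-voxel relabeling noise.
#'
#' @param n_lgg,n_hgg class sizes; defaults mirror the studied cohort after
#'   reference-volume exclusion (64 LGG, 191 HGG).
#' @param grid_shape 3D extent in voxels (default `c(32, 32, 32)`, chosen to
#'   keep volume-level tests in seconds).
#' @param region_fraction fraction of the grid covered by the NCR/NET mask,
#'   in (0, 1].
#' @param zone_scale named list `list(LGG = c(T1Gd = ., T2 = .), HGG = ...)`
#'   of characteristic zone edge lengths (voxels, >= 1) per class and
#'   contrast. The default gives HGG coarser zones than LGG on T1Gd and the
#'   reverse on T2, the asymmetry the grading model exploits.
#' @param gray_levels number of distinct levels (1..gray_levels inside brain).
#' @param noise_prob per-voxel relabel probability in \[0, 1\].
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `"synthetic_spec"` (validated list).
#' @export
synthetic_spec <- function(n_lgg = 64L, n_hgg = 191L,
                           grid_shape = c(32L, 32L, 32L),
                           region_fraction = 0.15,
                           zone_scale = list(LGG = c(T1Gd = 1, T2 = 3),
                                             HGG = c(T1Gd = 3, T2 = 1)),
                           gray_levels = 16L, noise_prob = 0.05,
                           seed = 1L) {
  spec <- list(n_lgg = as.integer(n_lgg), n_hgg = as.integer(n_hgg),
               grid_shape = as.integer(grid_shape),
               region_fraction = region_fraction,
               zone_scale = zone_scale, gray_levels = as.integer(gray_levels),
               noise_prob = noise_prob, seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  if (spec$n_lgg < 0) abort("invalid `n_lgg`: must be >= 0")
  if (spec$n_hgg < 0) abort("invalid `n_hgg`: must be >= 0")
  if (spec$n_lgg + spec$n_hgg < 1) abort("invalid cohort size: n_lgg + n_hgg must be >= 1")
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 2)) {
    abort("invalid `grid_shape`: three extents >= 2 required")
  }
  if (!(spec$region_fraction > 0 && spec$region_fraction <= 1)) {
    abort("invalid `region_fraction`: must lie in (0, 1]")
  }
  if (!all(grade_levels() %in% names(spec$zone_scale))) {
    abort("invalid `zone_scale`: needs entries for LGG and HGG")
  }
  for (g in grade_levels()) {
    sc <- spec$zone_scale[[g]]
    if (is.null(names(sc)) || any(sc < 1)) {
      abort("invalid `zone_scale`: named per-contrast edge lengths >= 1 required")
    }
  }
  if (spec$gray_levels < 1) abort("invalid `gray_levels`: must be >= 1")
  if (spec$noise_prob < 0 || spec$noise_prob > 1) {
    abort("invalid `noise_prob`: must lie in [0, 1]")
  }
  invisible(spec)
}

# concentric geometry at the grid center: NCR/NET ball of the requested
# volume fraction, an ED shell of equal volume around it, and a "brain" ball
# (the inscribed sphere) outside of which intensities are background 0
build_geometry <- function(grid_shape, region_fraction) {
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(k) seq_len(grid_shape[k]) - ctr[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  brain <- r2 <= (min(grid_shape) / 2)^2
  n_core <- max(1L, round(region_fraction * prod(grid_shape)))
  cut_core <- sort(as.vector(r2))[n_core]
  n_shell <- min(sum(brain), n_core * 2L)
  cut_shell <- sort(as.vector(r2))[n_shell]
  mask <- array(0L, grid_shape)
  mask[r2 <= cut_shell] <- brats_label_map()[["ED"]]
  mask[r2 <= cut_core] <- brats_label_map()[["NCRNET"]]
  list(mask = mask, brain = brain)
}

# one blocky volume: Poisson-count uniform seeds with mean spacing `scale`,
# nearest-seed cell labels, uniform gray levels per cell, relabel noise
blocky_volume <- function(grid_shape, scale, gray_levels, noise_prob) {
  nvox <- prod(grid_shape)
  n_seeds <- max(1L, rpois(1, nvox / scale^3))
  seeds <- cbind(runif(n_seeds, 0.5, grid_shape[1] + 0.5),
                 runif(n_seeds, 0.5, grid_shape[2] + 0.5),
                 runif(n_seeds, 0.5, grid_shape[3] + 0.5))
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                  y = seq_len(grid_shape[2]),
                                  z = seq_len(grid_shape[3])))
  # nearest seed per voxel, chunked to bound the distance-matrix size
  cell <- integer(nvox)
  chunk <- max(1L, floor(2e6 / n_seeds))
  for (start in seq(1L, nvox, by = chunk)) {
    idx <- start:min(nvox, start + chunk - 1L)
    d2 <- outer(rowSums(coords[idx, , drop = FALSE]^2), rowSums(seeds^2), `+`) -
      2 * coords[idx, , drop = FALSE] %*% t(seeds)
    cell[idx] <- max.col(-d2, ties.method = "first")
  }
  cell_level <- sample.int(gray_levels, n_seeds, replace = TRUE)
  v <- cell_level[cell]
  flip <- runif(nvox) < noise_prob
  v[flip] <- sample.int(gray_levels, sum(flip), replace = TRUE)
  array(as.integer(v), grid_shape)
}

#' Generate a synthetic volume cohort
#'
#' Produces, for every glioma, co-registered T1Gd and T2 integer volumes on
#' one grid plus a segmentation mask (NCR/NET core, ED shell). Inside the
#' brain, intensities are blocky zones whose characteristic size follows the
#' spec's per-class, per-contrast zone scale; outside the brain they are 0.
#'
#' @param spec a [synthetic_spec()].
#' @return tibble of class `"glioma_cohort"`: one row per (glioma, contrast)
#'   with columns `id`, `grade`, `contrast`, and list-columns `volume`
#'   (integer 3D array) and `mask` (BRATS-labeled integer array, shared
#'   between contrasts of one glioma).
#' @examples
#' coh <- generate_volume_cohort(synthetic_spec(n_lgg = 1, n_hgg = 1,
#'                                              grid_shape = c(12, 12, 12)))
#' @export
generate_volume_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  contrasts <- names(spec$zone_scale[["LGG"]])
  grades <- c(rep("LGG", spec$n_lgg), rep("HGG", spec$n_hgg))
  ids <- sprintf("%s-%03d", tolower(grades), c(seq_len(spec$n_lgg), seq_len(spec$n_hgg)))
  geom <- build_geometry(spec$grid_shape, spec$region_fraction)
  mask <- geom$mask
  withr::with_seed(spec$seed, {
    rows <- purrr::map2(ids, grades, function(gid, gr) {
      vols <- lapply(contrasts, function(ctr) {
        v <- blocky_volume(spec$grid_shape, spec$zone_scale[[gr]][[ctr]],
                           spec$gray_levels, spec$noise_prob)
        v[!geom$brain] <- 0L
        v
      })
      tibble::tibble(id = gid, grade = gr, contrast = contrasts,
                     volume = vols, mask = list(mask))
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("glioma_cohort", class(out))
  out
}

#' Generate a synthetic feature table directly
#'
#' Fast path for testing the statistical stages without imaging: feature
#' values are drawn from class-conditional Gaussians (unit variance, zero
#' baseline mean) with per-feature mean shifts applied to the HGG class.
#'
#' @param spec a [synthetic_spec()] (only class sizes and seed are used).
#' @param effect named numeric vector mapping feature column ids (see
#'   [feature_columns()]) to the HGG-minus-LGG mean shift in standard
#'   deviations; features not named get shift 0.
#' @param sources sources whose 13 feature columns make up the table.
#' @return feature tibble `id, grade, <source>_<feature>...` with
#'   `n_lgg + n_hgg` rows.
#' @examples
#' spec <- synthetic_spec(n_lgg = 5, n_hgg = 5)
#' generate_feature_table(spec, c(T2_NCRNET_z.perc = 3))
#' @export
generate_feature_table <- function(spec, effect = numeric(0),
                                   sources = default_sources()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cols <- feature_columns(sources)
  if (length(effect) > 0) {
    bad <- setdiff(names(effect), cols)
    if (length(bad) > 0) {
      abort(paste0("unknown feature id(s) in `effect`: ",
                   paste(bad, collapse = ", ")))
    }
  }
  shift <- setNames(rep(0, length(cols)), cols)
  shift[names(effect)] <- effect
  n <- spec$n_lgg + spec$n_hgg
  grades <- c(rep("LGG", spec$n_lgg), rep("HGG", spec$n_hgg))
  ids <- sprintf("%s-%03d", tolower(grades),
                 c(seq_len(spec$n_lgg), seq_len(spec$n_hgg)))
  withr::with_seed(child_seed(spec$seed, "features"), {
    vals <- matrix(rnorm(n * length(cols)), nrow = n)
  })
  vals <- vals + outer(as.numeric(grades == "HGG"), shift)
  colnames(vals) <- cols
  dplyr::bind_cols(tibble::tibble(id = ids, grade = grades),
                   tibble::as_tibble(vals))
}

#' Write / read a volume cohort as NIfTI files plus a CSV manifest
#'
#' Each volume is written as `<id>_<contrast>.nii.gz` and each mask as
#' `<id>_seg.nii.gz`; `manifest.csv` lists `id, grade, contrast, volume_path,
#' mask_path`.
#'
#' @param cohort a `"glioma_cohort"` tibble.
#' @param dir output directory (created if needed).
#' @return the manifest path ([write_volume_cohort()]) or the cohort tibble
#'   ([read_volume_cohort()]).
#' @export
write_volume_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort |>
    dplyr::mutate(
      volume_path = file.path(dir, paste0(.data$id, "_", .data$contrast, ".nii.gz")),
      mask_path = file.path(dir, paste0(.data$id, "_seg.nii.gz"))
    )
  purrr::pwalk(list(man$volume, man$mask, man$volume_path, man$mask_path),
               function(v, m, vp, mp) {
                 RNifti::writeNifti(v, vp)
                 if (!file.exists(mp)) RNifti::writeNifti(m, mp)
               })
  manifest <- man |>
    dplyr::select("id", "grade", "contrast", "volume_path", "mask_path")
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' @rdname write_volume_cohort
#' @param manifest path to a `manifest.csv` written by [write_volume_cohort()].
#' @export
read_volume_cohort <- function(manifest) {
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  assert_grades(man$grade)
  out <- man |>
    dplyr::mutate(
      volume = purrr::map(.data$volume_path, function(p) {
        v <- RNifti::readNifti(p)
        array(as.integer(round(v)), dim(v))
      }),
      mask = purrr::map(.data$mask_path, function(p) {
        m <- RNifti::readNifti(p)
        array(as.integer(round(m)), dim(m))
      })
    ) |>
    dplyr::select("id", "grade", "contrast", "volume", "mask")
  class(out) <- c("glioma_cohort", class(out))
  out
}
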