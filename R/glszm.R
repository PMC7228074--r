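#' Gray level size zone matrix (GLSZM) of a segmented region
#'
#' Counts, for every gray level `i >= 1` and zone size `j`, the number of
#' *zones* -- maximal 26-connected (8-connected for 2D input) sets of voxels
#' sharing gray level `i` -- inside one segmented region of a normalized
#' volume. Voxels outside the region, or carrying the reserved value 0
#' ("absence of a value"), are excluded.
#'
#' @param volume integer-valued 2D or 3D array (a normalized volume; levels
#'   `0..255` with 0 = background).
#' @param mask array of the same shape: either logical (TRUE = region) or an
#'   integer label array; in the latter case `region` selects the label.
#' @param region region selector when `mask` is a label array: a region name
#'   from [brats_label_map()] (`"NCRNET"`, `"ED"`, `"ET"`) or an integer
#'   label. Ignored for logical masks.
#' @param label_map named integer vector mapping region names to labels.
#' @param n_bins optional number of equal-width gray-level bins; the default
#'   `NULL` uses the raw integer levels unchanged (the normalization already
#'   quantizes to 1..255).
#'
#' @return An object of class `"glszm"`: a list with
#'   \describe{
#'     \item{counts}{tibble with columns `gray_level`, `zone_size`, `count`
#'       (sparse: only nonzero cells), sorted by level then size.}
#'     \item{n_zones}{total number of zones, `N_s`.}
#'     \item{n_voxels}{number of region voxels with level >= 1, `N_v`.}
#'     \item{max_level}{largest gray level present.}
#'   }
#'   Conservation holds by construction: `sum(zone_size * count) == n_voxels`.
#' @examples
#' vol <- array(c(1, 2, 1, 3), dim = c(2, 2, 1))
#' compute_glszm(vol, array(TRUE, dim(vol)))
#' @export
compute_glszm <- function(volume, mask, region = "NCRNET",
                          label_map = brats_label_map(), n_bins = NULL) {
  if (!is.array(volume)) abort("`volume` must be a 2D or 3D array")
  dims <- dim(volume)
  if (!length(dims) %in% c(2L, 3L)) abort("`volume` must be 2D or 3D")
  if (!identical(dim(mask), dims)) abort("`volume` and `mask` shapes differ")
  v <- as.vector(volume)
  if (any(!is.finite(v)) || any(abs(v - round(v)) > 1e-8)) {
    abort("`volume` must contain integer gray levels (normalize first)")
  }
  v <- as.integer(round(v))

  if (is.logical(mask)) {
    inreg <- as.vector(mask)
  } else {
    lab <- if (is.character(region)) {
      if (!region %in% names(label_map)) {
        abort(paste0("unknown region \"", region, "\""))
      }
      label_map[[region]]
    } else {
      as.integer(region)
    }
    inreg <- as.vector(mask) == lab
  }
  if (!any(inreg)) abort("region is absent or empty in `mask`")

  keep <- inreg & v >= 1L
  if (!any(keep)) abort("region contains no voxels with gray level >= 1")

  if (!is.null(n_bins)) {
    vmax <- max(v[keep])
    vmin <- min(v[keep])
    width <- max((vmax - vmin + 1) / n_bins, .Machine$double.eps)
    v[keep] <- pmin(as.integer(floor((v[keep] - vmin) / width)) + 1L, n_bins)
  }

  zones <- label_zones(v, keep, dims)

  counts <- tibble::tibble(gray_level = zones$level, zone_size = zones$size) |>
    dplyr::count(.data$gray_level, .data$zone_size, name = "count") |>
    dplyr::arrange(.data$gray_level, .data$zone_size)

  out <- structure(
    list(counts = counts,
         n_zones = sum(counts$count),
         n_voxels = sum(keep),
         max_level = max(counts$gray_level)),
    class = "glszm"
  )
  stopifnot(sum(counts$zone_size * counts$count) == out$n_voxels)
  out
}

# frontier BFS over same-level voxels; returns one (level, size) per zone
label_zones <- function(v, keep, dims) {
  if (length(dims) == 2L) dims <- c(dims, 1L)
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]

  levels_out <- integer(0)
  sizes_out <- integer(0)
  member <- keep
  todo <- which(keep)
  # process per gray level so a zone never crosses levels
  for (g in sort(unique(v[todo]))) {
    ingrp <- member & v == g
    pending <- which(ingrp)
    while (length(pending) > 0) {
      seed <- pending[1]
      frontier <- seed
      ingrp[seed] <- FALSE
      size <- 0L
      while (length(frontier) > 0) {
        size <- size + length(frontier)
        i0 <- frontier - 1L
        x <- i0 %% d1 + 1L
        y <- (i0 %/% d1) %% d2 + 1L
        z <- i0 %/% (d1 * d2) + 1L
        nx <- rep(x, each = nrow(off)) + off[, 1]
        ny <- rep(y, each = nrow(off)) + off[, 2]
        nz <- rep(z, each = nrow(off)) + off[, 3]
        ok <- nx >= 1 & nx <= d1 & ny >= 1 & ny <= d2 & nz >= 1 & nz <= d3
        nb <- (nz[ok] - 1L) * d1 * d2 + (ny[ok] - 1L) * d1 + nx[ok]
        nb <- unique(nb[ingrp[nb]])
        ingrp[nb] <- FALSE
        frontier <- nb
      }
      levels_out <- c(levels_out, g)
      sizes_out <- c(sizes_out, size)
      pending <- pending[ingrp[pending]]
    }
  }
  list(level = levels_out, size = sizes_out)
}

#' @export
print.glszm <- function(x, ...) {
  cat("GLSZM:", x$n_zones, "zones over", x$n_voxels, "voxels,",
      "max gray level", x$max_level, "\n")
  print(x$counts, n = 10)
  invisible(x)
}

#' Gray-level and zone-size marginals of a GLSZM
#'
#' @param matrix a [compute_glszm()] result.
#' @return list with tibbles `gray`: (`gray_level`, `g`) where
#'   `g[i] = sum_j s(i,j)`, and `size`: (`zone_size`, `z`) where
#'   `z[j] = sum_i s(i,j)`. Both marginals sum to `n_zones`.
#' @export
zone_marginals <- function(matrix) {
  stopifnot(inherits(matrix, "glszm"))
  gray <- matrix$counts |>
    dplyr::summarise(g = sum(.data$count), .by = "gray_level") |>
    dplyr::arrange(.data$gray_level)
  size <- matrix$counts |>
    dplyr::summarise(z = sum(.data$count), .by = "zone_size") |>
    dplyr::arrange(.data$zone_size)
  list(gray = gray, size = size)
}

#' Write a GLSZM as CSV triplets
#'
#' @param matrix a [compute_glszm()] result.
#' @param path output file; columns `gray_level,zone_size,count`.
#' @return `path`, invisibly.
#' @export
write_glszm <- function(matrix, path) {
  stopifnot(inherits(matrix, "glszm"))
  readr::write_csv(matrix$counts, path)
  invisible(path)
}
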