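# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: zone labeling goes through igraph's generic
# connected components, the rank-sum p-value through exhaustive enumeration,
# and OLS through the explicit normal equations.

# GLSZM via igraph connected components over the 26-neighbor (8 in 2D) graph
oracle_glszm <- function(volume, mask) {
  dims <- dim(volume)
  if (length(dims) == 2) dims <- c(dims, 1L)
  vol <- array(volume, dims)
  msk <- array(mask, dims)
  keep <- which(msk & vol >= 1)
  if (length(keep) == 0) stop("empty region")
  coord <- arrayInd(keep, dims)
  idmap <- array(0L, dims)
  idmap[keep] <- seq_along(keep)
  # edges between kept voxels at Chebyshev distance 1 with equal value:
  # enumerate the 13 positive offsets and pair each voxel with its shifted one
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ]
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1) * dims[1] * dims[2] + (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    a <- which(ok)[idmap[lin] > 0]
    b <- idmap[lin][idmap[lin] > 0]
    same <- vol[keep[a]] == vol[keep[b]]
    edges <- c(edges, rbind(a[same], b[same]))
  }
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  # level of each component = value of any member
  lev <- tapply(vol[keep], comp$membership, function(v) v[1])
  zones <- data.frame(gray_level = as.integer(lev),
                      zone_size = as.integer(comp$csize))
  agg <- aggregate(list(count = rep(1L, nrow(zones))),
                   by = zones[c("gray_level", "zone_size")], FUN = sum)
  agg[order(agg$gray_level, agg$zone_size), ]
}

glszm_equal_oracle <- function(m, oracle) {
  got <- as.data.frame(m$counts)
  rownames(got) <- NULL
  rownames(oracle) <- NULL
  identical(got[c("gray_level", "zone_size", "count")],
            data.frame(gray_level = as.integer(oracle$gray_level),
                       zone_size = as.integer(oracle$zone_size),
                       count = as.integer(oracle$count)))
}

# exact two-sided rank-sum p by enumerating all choose(n_a + n_b, n_a)
# assignments of ranks to group a (tie-free samples only)
oracle_ranksum_exact <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  sets <- utils::combn(n, length(a))
  w_all <- colSums(matrix(seq_len(n)[sets], nrow = length(a)))
  mu <- length(a) * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# OLS through the normal equations
oracle_ols <- function(X, y) {
  Xc <- cbind(1, X)
  drop(solve(t(Xc) %*% Xc, t(Xc) %*% y))
}

# hand-built ranked_features object for consensus tests
make_ranked <- function(features, ps, universe = NULL) {
  universe <- universe %||% features
  p_all <- stats::setNames(rep(0.5, length(universe)), universe)
  p_all[features] <- ps
  structure(tibble::tibble(feature = features, p = ps),
            D = length(features), p_all = p_all,
            class = c("ranked_features", "tbl_df", "tbl", "data.frame"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random small labeled volume + mask pair for property tests
random_volume_case <- function(dim3 = c(6, 6, 6), levels = 3, mask_p = 0.7) {
  vol <- array(sample.int(levels, prod(dim3), replace = TRUE), dim3)
  mask <- array(stats::runif(prod(dim3)) < mask_p, dim3)
  list(volume = vol, mask = mask)
}
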