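mk <- function(values, dims = c(4, 4, 4)) array(values, dims)

test_that("mean intensity excludes background and all tumor labels", {
  vol <- mk(7)
  mask <- mk(0L)
  expect_equal(mean_intensity_excluding_tumor(vol, mask), 7)

  vol2 <- mk(4)
  mask2 <- mk(0L)
  mask2[1:2, 1:2, 1:2] <- 1L # NCR/NET
  vol2[1:2, 1:2, 1:2] <- 10
  expect_equal(mean_intensity_excluding_tumor(vol2, mask2), 4)

  all_tumor <- mk(2L)
  expect_error(mean_intensity_excluding_tumor(vol2, all_tumor), "no non-tumor")
})

test_that("masked mean matches a brute-force oracle on random volumes", {
  withr::with_seed(14, {
    for (rep in 1:10) {
      vol <- array(stats::rexp(512, 1 / 50), c(8, 8, 8))
      vol[sample(512, 50)] <- 0 # background holes
      mask <- array(sample(c(0L, 1L, 2L, 4L), 512, replace = TRUE,
                           prob = c(0.7, 0.1, 0.1, 0.1)), c(8, 8, 8))
      keep <- vol != 0 & !(mask %in% c(1L, 2L, 4L))
      expect_equal(mean_intensity_excluding_tumor(vol, mask),
                   sum(vol[keep]) / sum(keep))
    }
  })
})

ref_cohort <- function(means, grade = "LGG", contrast = "T1Gd", group = "A") {
  tibble::tibble(
    id = sprintf("g%02d", seq_along(means)), grade = grade,
    contrast = contrast, group = group,
    volume = lapply(means, function(m) mk(m) + array(seq(0, 0.9, length.out = 64), c(4, 4, 4))),
    mask = lapply(means, function(m) mk(0L))
  )
}

test_that("reference selection picks the extreme-mean volumes with id tie-break", {
  coh <- ref_cohort(c(20, 10, 30))
  refs <- select_reference_volumes(coh)
  expect_equal(refs$low_id, "g02")
  expect_equal(refs$high_id, "g03")

  tied <- ref_cohort(c(10, 10, 30))
  refs2 <- select_reference_volumes(tied)
  expect_equal(refs2$low_id, "g01") # lexicographic tie-break

  expect_error(select_reference_volumes(ref_cohort(5)), "fewer than 2")
})

test_that("the real database layout yields 40 reference volumes", {
  # 4 contrasts x 2 grades x 3 dataset groups, minus the group with no LGGs
  strata <- expand.grid(contrast = c("T1", "T1Gd", "T2", "FLAIR"),
                        grade = c("LGG", "HGG"),
                        group = c("BRATS2013", "TCIA", "CBICA"),
                        stringsAsFactors = FALSE)
  strata <- strata[!(strata$group == "CBICA" & strata$grade == "LGG"), ]
  coh <- dplyr::bind_rows(lapply(seq_len(nrow(strata)), function(k) {
    means <- c(10, 20) + k
    tb <- ref_cohort(means, grade = strata$grade[k],
                     contrast = strata$contrast[k], group = strata$group[k])
    tb$id <- paste0(strata$group[k], "-", strata$grade[k], "-", tb$id)
    tb
  }))
  refs <- select_reference_volumes(coh)
  expect_equal(nrow(refs), 20)
  expect_equal(nrow(refs) * 2, 40) # two references per stratum
})

test_that("standard scale averages mapped landmarks and pins 1 and 255", {
  vol <- mk(0)
  vol[] <- rep(1:64, each = 1) # 1..64 gradient
  mask <- mk(0L)
  sc1 <- learn_standard_scale(list(vol), list(mask))
  own <- unname(stats::quantile(as.vector(vol), default_landmarks() / 100))
  mapped <- 1 + (own - own[1]) / (own[length(own)] - own[1]) * 254
  expect_equal(sc1$positions, mapped)
  expect_equal(sc1$positions[1], 1)
  expect_equal(sc1$positions[length(sc1$positions)], 255)

  sc2 <- learn_standard_scale(list(vol, vol), list(mask, mask))
  expect_equal(sc2$positions, sc1$positions)

  expect_error(learn_standard_scale(list(mk(3)), list(mask)), "degenerate")
  expect_error(learn_standard_scale(list(vol), list(mask), percentiles = c(5, 5)),
               "strictly increasing")
})

test_that("two toy volumes give hand-computed averaged landmark positions", {
  v1 <- array(1:100, c(10, 10, 1))
  v2 <- array(seq(2, 200, by = 2), c(10, 10, 1))
  mask <- array(0L, c(10, 10, 1))
  pct <- c(1, 50, 99)
  sc <- learn_standard_scale(list(v1, v2), list(mask, mask), percentiles = pct)
  map1 <- function(v) {
    lm <- unname(stats::quantile(as.vector(v), pct / 100))
    1 + (lm - lm[1]) / (lm[3] - lm[1]) * 254
  }
  expect_equal(sc$positions, (map1(v1) + map1(v2)) / 2)
})

test_that("normalization is monotone, integer, 0-preserving and in range", {
  withr::with_seed(8, {
    vol <- array(stats::rlnorm(1000, 4, 0.5), c(10, 10, 10))
    vol[sample(1000, 80)] <- 0
    mask <- array(0L, c(10, 10, 10))
    mask[1:3, 1:3, 1:3] <- 1L
    sc <- learn_standard_scale(list(vol), list(mask))
    out <- normalize_volume(vol, mask, sc)
    expect_true(all(out[vol == 0] == 0))
    expect_true(all(out[vol != 0] >= 1 & out[vol != 0] <= 255))
    expect_true(all(out == round(out)))
    # monotone: normalized order follows raw order among brain voxels
    b <- vol != 0
    ord <- order(vol[b])
    expect_true(all(diff(out[b][ord]) >= 0))
  })
})

test_that("a volume whose landmarks equal the standard positions is unchanged", {
  withr::with_seed(15, {
    vol <- array(stats::runif(1000, 1, 255), c(10, 10, 10))
    mask <- array(0L, c(10, 10, 10))
    own <- unname(stats::quantile(as.vector(vol), default_landmarks() / 100))
    sc <- structure(list(percentiles = default_landmarks(), positions = own,
                         contrast = "T2"), class = "standard_scale")
    out <- normalize_volume(vol, mask, sc)
    inside <- vol >= own[1] & vol <= own[length(own)]
    expect_true(all(abs(out[inside] - vol[inside]) <= 0.5 + 1e-9))
  })
})

test_that("piecewise-linear mapping hits hand-computed interior values", {
  # landmarks {2, 5, 9} -> {50, 128, 200}: value 5 must map to 128
  sc <- structure(list(percentiles = c(1, 50, 99),
                       positions = c(50, 128, 200),
                       contrast = "T1Gd"), class = "standard_scale")
  vol <- array(c(2, 5, 9, rep(c(2, 5, 9), 33)), c(10, 10, 1))
  mask <- array(0L, c(10, 10, 1))
  out <- normalize_volume(vol, mask, sc)
  expect_equal(unique(out[vol == 5]), 128L)
  expect_equal(unique(out[vol == 2]), 50L)
  expect_equal(unique(out[vol == 9]), 200L)
})

test_that("normalized landmark positions reproduce the scale within rounding", {
  withr::with_seed(23, {
    vols <- lapply(1:3, function(i) array(stats::rgamma(1000, 5, 1 / (20 * i)),
                                          c(10, 10, 10)))
    masks <- lapply(1:3, function(i) array(0L, c(10, 10, 10)))
    sc <- learn_standard_scale(vols, masks)
    out <- normalize_volume(vols[[1]], masks[[1]], sc)
    got <- unname(stats::quantile(as.vector(out), default_landmarks() / 100))
    expect_true(all(abs(got - sc$positions) <= 1.5))
  })
})

test_that("cohort normalization drops reference gliomas and normalizes the rest", {
  spec <- synthetic_spec(n_lgg = 3, n_hgg = 3, grid_shape = c(12, 12, 12), seed = 6)
  coh <- generate_volume_cohort(spec)
  # make intensities heterogeneous across gliomas so references are distinct
  coh$volume <- purrr::imap(coh$volume, function(v, i) {
    w <- v * (1 + 0.2 * i)
    w[v == 0] <- 0
    w
  })
  res <- normalize_cohort(coh)
  expect_true(all(!res$cohort$id %in% reference_glioma_ids(res$refs)))
  expect_setequal(names(res$scales), c("T1Gd", "T2"))
  for (v in res$cohort$volume) {
    expect_true(all(v %in% 0:255))
  }
})
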