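test_that("combination enumeration matches the studied design", {
  combos <- enumerate_combinations(default_sources())
  expect_equal(nrow(combos), 15)
  expect_equal(sort(unique(combos$n_features)), c(13L, 26L, 39L, 52L))
  expect_equal(sum(combos$n_features == 13), 4)
  expect_equal(sum(combos$n_features == 26), 6)
  expect_equal(sum(combos$n_features == 39), 4)
  expect_equal(sum(combos$n_features == 52), 1)
  expect_equal(nrow(enumerate_combinations("T1Gd_NCRNET")), 1)
  expect_equal(nrow(enumerate_combinations(c("a", "b"))), 3)
  for (k in 1:4) {
    expect_equal(nrow(enumerate_combinations(letters[seq_len(k)])), 2^k - 1)
  }
  expect_error(enumerate_combinations(c("a", "a")), "distinct")
})

test_that("subset matching is set-wise by default, order-wise on request", {
  cons <- build_consensus(lapply(1:3, function(i)
    make_ranked(c("A", "B", "C"), c(1, 2, 3) / 1000)))
  ranked <- list(
    make_ranked(c("B", "A", "C"), c(1, 2, 3) / 1000),
    make_ranked(c("A", "C", "B"), c(1, 2, 3) / 1000),
    make_ranked(c("A", "B", "C"), c(1, 2, 3) / 1000)
  )
  expect_equal(select_matching_subsets(ranked, cons, 2), c(1L, 3L))
  expect_equal(select_matching_subsets(ranked, cons, 2, mode = "order"), 3L)
  expect_equal(select_matching_subsets(ranked, cons, 3), c(1L, 2L, 3L))
  expect_error(select_matching_subsets(ranked, cons, 4), "1 <= t <= d")
  cons_other <- build_consensus(list(make_ranked(c("C", "B", "A"),
                                                 c(1, 2, 3) / 1000)))
  expect_error(select_matching_subsets(ranked, cons_other, 1),
               "no qualifying subsets")
})

toy_features <- function(n_per_class = 30, seed = 2, p = 3) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- matrix(stats::rnorm(n * p), n)
    colnames(x) <- paste0("f", seq_len(p))
    tibble::tibble(id = sprintf("s%02d", seq_len(n)),
                   grade = rep(c("LGG", "HGG"), each = n_per_class)) |>
      dplyr::bind_cols(tibble::as_tibble(x))
  })
}

toy_subset <- function(tbl) {
  list(LGG = tbl$id[tbl$grade == "LGG"], HGG = tbl$id[tbl$grade == "HGG"])
}

test_that("a perfect +-10 predictor is fit with coefficient 1, intercept 0", {
  tbl <- toy_features()
  tbl$f1 <- ifelse(tbl$grade == "HGG", 10, -10)
  cf <- fit_subset_regression(tbl, toy_subset(tbl), "f1")
  expect_equal(unname(cf["f1"]), 1, tolerance = 1e-10)
  expect_equal(unname(cf["(Intercept)"]), 0, tolerance = 1e-10)
})

test_that("OLS coefficients match the normal-equations oracle to 1e-8", {
  tbl <- toy_features(p = 3)
  cf <- fit_subset_regression(tbl, toy_subset(tbl), c("f1", "f2", "f3"))
  X <- as.matrix(tbl[c("f1", "f2", "f3")])
  y <- ifelse(tbl$grade == "HGG", 10, -10)
  beta <- oracle_ols(X, y)
  expect_equal(unname(cf[c("f1", "f2", "f3")]), unname(beta[2:4]),
               tolerance = 1e-8)
  expect_equal(unname(cf["(Intercept)"]), unname(beta[1]), tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  tbl <- toy_features()
  tbl$f2 <- 2 * tbl$f1
  expect_error(fit_subset_regression(tbl, toy_subset(tbl), c("f1", "f2")),
               "rank-deficient")
  expect_error(fit_subset_regression(tbl, toy_subset(tbl), character(0)),
               "at least one")
})

planted_fixture <- function(seed = 6) {
  spec <- synthetic_spec(n_lgg = 64, n_hgg = 191, seed = seed)
  tbl <- generate_feature_table(spec, c(T1Gd_NCRNET_zsnu = 4, T1Gd_NCRNET_sze = 3),
                                sources = "T1Gd_NCRNET")
  split <- make_split(tbl, n_subsets = 25, seed = seed)
  ranked <- lapply(seq_len(split$n_subsets), function(i)
    rank_subset(tbl, gliotex:::subset_ids(split, i)))
  list(tbl = tbl, split = split, ranked = ranked,
       consensus = build_consensus(ranked))
}

test_that("a unique model built from w = 1 subset equals its own OLS fit", {
  fx <- planted_fixture()
  # restrict to a single subset so the average is over one fit
  m <- build_unique_model(fx$tbl, fx$split, fx$ranked[1],
                          build_consensus(fx$ranked[1]), t = 1)
  expect_equal(m$w, 1)
  cf <- fit_subset_regression(fx$tbl, gliotex:::subset_ids(fx$split, 1),
                              m$variables)
  expect_equal(unname(m$coefficients), unname(cf[m$variables]))
  expect_equal(m$intercept, unname(cf["(Intercept)"]))
})

test_that("averaged coefficients equal the hand-averaged per-subset fits", {
  fx <- planted_fixture()
  t <- min(2, fx$consensus$d)
  idx <- select_matching_subsets(fx$ranked, fx$consensus, t)
  m <- build_unique_model(fx$tbl, fx$split, fx$ranked, fx$consensus, t)
  fits <- sapply(idx, function(i)
    fit_subset_regression(fx$tbl, gliotex:::subset_ids(fx$split, i), m$variables))
  expect_equal(m$w, length(idx))
  expect_equal(unname(m$coefficients), unname(rowMeans(fits)[seq_len(t)]))
  expect_equal(m$intercept, unname(rowMeans(fits)[t + 1]))
})

test_that("unique-model predictions equal the mean of per-subset predictions", {
  fx <- planted_fixture()
  t <- fx$consensus$d
  idx <- select_matching_subsets(fx$ranked, fx$consensus, t)
  m <- build_unique_model(fx$tbl, fx$split, fx$ranked, fx$consensus, t)
  newdata <- withr::with_seed(44, fx$tbl[sample.int(nrow(fx$tbl), 10), ])
  per_subset <- sapply(idx, function(i) {
    cf <- fit_subset_regression(fx$tbl, gliotex:::subset_ids(fx$split, i),
                                m$variables)
    as.matrix(newdata[m$variables]) %*% cf[m$variables] + cf["(Intercept)"]
  })
  expect_equal(predict(m, newdata), unname(rowMeans(per_subset)),
               tolerance = 1e-8)
})

test_that("reduced models enumerate all non-empty variable subsets", {
  fx <- planted_fixture()
  vars <- paste0("T1Gd_NCRNET_", c("zsnu", "sze", "glnu"))
  parent <- gliotex:::new_glioma_model(vars, c(1, 1, 1), 0, w = 1)
  # consensus with 3 features so max(C) up to 3 is selectable
  cons3 <- build_consensus(lapply(fx$ranked, function(r) {
    make_ranked(vars, c(1, 2, 3) / 1000, universe = names(attr(r, "p_all")))
  }))
  ranked3 <- lapply(seq_len(25), function(i)
    make_ranked(vars, c(1, 2, 3) / 1000, universe = names(attr(fx$ranked[[1]], "p_all"))))
  red <- build_reduced_models(parent, fx$tbl, fx$split, ranked3, cons3)
  expect_length(red, 7)
  expect_setequal(names(red), c("1", "2", "3", "1-2", "1-3", "2-3", "1-2-3"))
  # the full-set reduced model is the parent rebuild: same variables
  expect_equal(red[["1-2-3"]]$variables, vars)
  # 5 variables would give 31 candidate combinations
  expect_equal(sum(choose(5, 1:5)), 31)
  expect_error(build_reduced_models(red[["1"]], fx$tbl, fx$split, ranked3, cons3),
               ">= 2 variables")
})

test_that("the full-set reduced model coincides with the unique model", {
  fx <- planted_fixture()
  d <- fx$consensus$d
  expect_gte(d, 2) # two planted features are always significant
  parent <- build_unique_model(fx$tbl, fx$split, fx$ranked, fx$consensus, d)
  red <- build_reduced_models(parent, fx$tbl, fx$split, fx$ranked, fx$consensus)
  full_key <- paste(seq_len(d), collapse = "-")
  expect_equal(red[[full_key]]$coefficients, parent$coefficients)
  expect_equal(red[[full_key]]$intercept, parent$intercept)
  expect_equal(red[[full_key]]$w, parent$w)
})

test_that("model application is the plain linear form with exact arithmetic", {
  pm <- published_model()
  zero <- tibble::tibble(T2_NCRNET_z.perc = 0, T2_NCRNET_zs.var = 0,
                         T1Gd_NCRNET_zsnu = 0)
  expect_equal(predict(pm, zero), -19.5)
  unit <- tibble::tibble(T2_NCRNET_z.perc = 1, T2_NCRNET_zs.var = 0,
                         T1Gd_NCRNET_zsnu = 1)
  expect_equal(predict(pm, unit), 13.693 + 31.842 - 19.5)
  expect_equal(apply_model(pm, unit), predict(pm, unit))
  expect_error(predict(pm, zero[, 1:2]), "missing model variable")
})

test_that("models round-trip through JSON and expose tidy/glance", {
  pm <- published_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(pm, path)
  back <- read_model(path)
  expect_equal(back$coefficients, pm$coefficients)
  expect_equal(back$intercept, pm$intercept)
  td <- tidy(pm)
  expect_equal(td$term, c(pm$variables, "(Intercept)"))
  expect_equal(td$estimate, c(13.693, -0.410, 31.842, -19.500))
  expect_equal(glance(pm)$n_variables, 3)
})
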