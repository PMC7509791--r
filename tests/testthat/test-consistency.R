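test_that("split-half reliability behaves at the degenerate extremes", {
  # builder interface: deterministic per-image "measurements"
  n_obs <- 12
  vals <- matrix(seq_len(n_obs * 8), n_obs, 8,
                 dimnames = list(sprintf("s%02d", 1:n_obs), NULL))
  ids <- sprintf("im%d", 1:8)
  colnames(vals) <- ids
  builder <- function(sub) {
    m <- matrix(rowMeans(vals[, sub, drop = FALSE]), ncol = 1,
                dimnames = list(rownames(vals), "dim"))
    structure(m, class = c("salience_matrix", class(m)), kind = "dwell")
  }
  # interleaved duplicate images: the parity split sees identical halves
  dup <- matrix(0, n_obs, 8)
  dup[, seq(1, 8, 2)] <- matrix(rnorm(n_obs * 4), n_obs)
  dup[, seq(2, 8, 2)] <- dup[, seq(1, 8, 2)]
  colnames(dup) <- ids
  builder_dup <- function(sub) {
    m <- matrix(rowMeans(dup[, sub, drop = FALSE]), ncol = 1,
                dimnames = list(rownames(vals), "dim"))
    structure(m, class = c("salience_matrix", class(m)), kind = "dwell")
  }
  ch <- split_half(builder_dup, image_ids = ids, mode = "parity")
  expect_equal(ch$median_r, 1)

  # identical observers: every split correlation is undefined, reported as such
  const <- function(sub) {
    m <- matrix(0.5, n_obs, 1, dimnames = list(rownames(vals), "dim"))
    structure(m, class = c("salience_matrix", class(m)), kind = "dwell")
  }
  ch0 <- split_half(const, image_ids = ids, n_splits = 5, seed = 1)
  expect_true(is.na(ch0$median_r))
  expect_equal(ch0$n_missing_splits, 5L)

  expect_error(split_half(builder, image_ids = ids[1:3]), "at least 4 images")
  expect_error(split_half(builder, image_ids = ids, n_splits = 0), "n_splits")
})

test_that("split-half is seed-reproducible and Bonferroni-adjusted", {
  sc <- metrics_scores2()
  a <- split_half(sc, n_splits = 25, seed = 99)
  b <- split_half(sc, n_splits = 25, seed = 99)
  expect_identical(attr(a, "r_distribution"), attr(b, "r_distribution"))
  expect_true(all(a$p_adjusted >= a$p_raw - 1e-15))
  expect_true(all(a$p_adjusted <= 1))
  expect_equal(a$p_adjusted, pmin(1, a$p_raw * length(a$dimension)))
})

test_that("builder and fast-path split-half agree", {
  sc <- metrics_scores2()
  dims <- tested_dims("dwell")
  builder <- function(sub) salience_matrix(sc, dims, "dwell", images = sub)
  fast <- split_half(sc, dims = dims, n_splits = 10, seed = 3)
  slow <- split_half(builder, image_ids = sc$image_ids, n_splits = 10, seed = 3)
  expect_equal(attr(fast, "r_distribution"), attr(slow, "r_distribution"))
})

test_that("ranges and max/min ratios match hand arithmetic", {
  rr <- range_and_ratio(c(0.28, 0.53))
  expect_equal(rr$min_pct, 28)
  expect_equal(rr$max_pct, 53)
  expect_equal(round(rr$maxmin_ratio, 2), 1.89)
  expect_equal(range_and_ratio(c(0.2, 0.2, 0.2))$maxmin_ratio, 1)
  expect_equal(range_and_ratio(c(0.10, 0.25))$maxmin_ratio, 2.5)
  expect_warning(rz <- range_and_ratio(c(0, 0.2)), "zero")
  expect_identical(rz$maxmin_ratio, Inf)
  expect_error(range_and_ratio(0.5), "at least 2")
})

test_that("cross-set validity joins observers by id and is symmetric", {
  mk <- function(vals, obs) {
    m <- matrix(vals, ncol = 2, dimnames = list(obs, c("Faces", "Text")))
    structure(m, class = c("salience_matrix", class(m)), kind = "dwell")
  }
  obs <- sprintf("s%02d", 1:20)
  set.seed(1)
  full <- mk(runif(40), obs)
  expect_equal(cross_set_validity(full, full)$r, c(1, 1))

  perm <- full[sample(20), ]
  perm <- structure(perm, class = class(full), kind = "dwell")
  expect_equal(cross_set_validity(full, perm)$r, c(1, 1))

  noisy <- mk(as.numeric(full) + rnorm(40, 0, 0.1), obs)
  expect_equal(cross_set_validity(full, noisy)$r,
               cross_set_validity(noisy, full)$r)
  expect_error(cross_set_validity(full[1:2, ], full[1:2, ]), "3 paired")
})

test_that("matched-variance noise attenuates validity towards 1/sqrt(2)", {
  # closed form: cor(x, x + e) = 1/sqrt(2) when var(e) = var(x)
  set.seed(42)
  n <- 4000
  x <- rnorm(n)
  mk <- function(v) structure(matrix(v, ncol = 1,
                                     dimnames = list(sprintf("s%d", 1:n), "Faces")),
                              class = c("salience_matrix", "matrix", "array"),
                              kind = "dwell")
  cv <- cross_set_validity(mk(x), mk(x + rnorm(n, 0, sd(x))))
  expect_equal(cv$r, 1 / sqrt(2), tolerance = 0.03)
})

test_that("explainable variance ratios follow the r-squared convention", {
  expect_equal(explainable_variance(0.84, 0.84), 1)
  expect_equal(round(explainable_variance(0.6, 0.84), 2), 0.51)
  expect_equal(explainable_variance(0, 0.7), 0)
  expect_equal(explainable_variance(0.6, 0.8, mode = "r"), 0.75)
  expect_warning(explainable_variance(0.9, 0.7), "ceiling")
  expect_error(explainable_variance(0.5, 0), "nonzero")
})

test_that("Spearman-Brown formula matches direct evaluation", {
  expect_equal(spearman_brown(0.2, 350), 350 * 0.2 / (1 + 349 * 0.2))
  expect_equal(round(spearman_brown(0.2, 350), 3), 0.989)
  # inversion is the exact inverse
  for (r in c(0.3, 0.6, 0.95)) {
    expect_equal(spearman_brown(spearman_brown_inverse(r, 123), 123), r)
  }
})

test_that("truncation curves hit identity at the trial end", {
  sc <- metrics_scores2()
  tc <- truncation_consistency(sc, cutoffs_ms = c(1000, 2000, 3000))
  expect_equal(tc$r[tc$cutoff_ms == 3000], rep(1, 5))

  # truncated split-half at the full duration reproduces split_half exactly
  a <- split_half(sc, n_splits = 1, seed = 5, mode = "parity")
  b <- truncated_split_half(sc, cutoffs_ms = 3000, n_splits = 1, seed = 5)
  expect_equal(b$median_r, a$median_r)

  # a cutoff below the earliest usable onset yields missing values, no crash
  tc0 <- truncation_consistency(sc, cutoffs_ms = c(100, 3000))
  expect_true(all(is.na(tc0$r[tc0$cutoff_ms == 100])))
})
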