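# Fixture where a single image carries all the individual-difference signal:
# on "img01" observers split their dwell between a Faces and a Text object in
# observer-specific ratios; on every other image all observers fixate
# identically. The full-set ranking is therefore reproduced by img01 alone.
signal_image_scores <- function(n_obs = 10, n_img = 10) {
  g <- test_geometry()
  objs <- list()
  for (j in seq_len(n_img)) {
    id <- sprintf("img%02d", j)
    objs <- c(objs,
              list(scene_object(id, "f", rect_mask_matrix(60, 40, 5, 14, 5, 14),
                                "Face"),
                   scene_object(id, "t", rect_mask_matrix(60, 40, 30, 39, 5, 14),
                                "Text")))
  }
  catl <- scene_catalog(g, objs, image_ids = sprintf("img%02d", seq_len(n_img)))
  fx <- list()
  for (o in seq_len(n_obs)) {
    obs <- sprintf("s%02d", o)
    w <- o / (n_obs + 1)
    for (j in seq_len(n_img)) {
      id <- sprintf("img%02d", j)
      if (j == 1) {
        fx[[length(fx) + 1L]] <- fix_row(obs, id, 9, 9, 150, 1000 * w)
        fx[[length(fx) + 1L]] <- fix_row(obs, id, 33, 9, 1300, 1000 * (1 - w))
      } else {
        fx[[length(fx) + 1L]] <- fix_row(obs, id, 9, 9, 150, 500)
        fx[[length(fx) + 1L]] <- fix_row(obs, id, 33, 9, 800, 500)
      }
    }
  }
  score_gaze(do.call(rbind, fx), catl)
}

test_that("the image reproducing full-set ranks is selected first", {
  sc <- signal_image_scores()
  sel <- greedy_select(sc, dims = c("Faces", "Text"), target_size = 5)
  expect_equal(sel$ordering[1], "img01")
  expect_equal(sel$init_method, "exhaustive_triples")
  expect_equal(length(sel$objective_trace), 5L)
  # prefixes containing the signal image already correlate perfectly
  expect_gt(sel$objective_trace[3], atanh(0.95))
})

test_that("ties break towards the lowest image id", {
  sc <- signal_image_scores(n_obs = 8, n_img = 6)
  sel <- greedy_select(sc, dims = c("Faces", "Text"), target_size = 6)
  # images 2..6 are exact copies of one another: after img01 the remaining
  # picks must come in ascending id order
  expect_equal(sel$ordering[2:6], sprintf("img%02d", 2:6))
})

test_that("selection rejects inconsistent sizes", {
  sc <- signal_image_scores(n_obs = 6, n_img = 6)
  expect_error(greedy_select(sc, target_size = 2), "min_prefix")
  expect_error(greedy_select(sc, target_size = 7), "exceeds")
})

test_that("validity curves evaluate prefixes against a reference", {
  sc <- metrics_scores2()
  ref <- salience_matrix(sc)
  ordering <- sc$image_ids
  cv <- evaluate_ordering(ordering, sc, ref, sizes = c(10, 20, 30))
  # full set on the same session is the identity
  expect_equal(cv$r[cv$size == 30], rep(1, 5))
  # one row per dimension and size
  expect_equal(nrow(cv), 15L)
  expect_error(evaluate_ordering(c(ordering, "imgXX"), sc, ref),
               "imgXX")
})

test_that("exported subsets are nested prefixes", {
  sc <- signal_image_scores(n_obs = 6, n_img = 8)
  sel <- greedy_select(sc, dims = c("Faces", "Text"), target_size = 8)
  subs <- export_subsets(sel, sizes = c(4, 8))
  expect_identical(subs$set4, subs$set8[1:4])
  expect_error(export_subsets(sel, sizes = 0), "positive")
  expect_error(export_subsets(sel, sizes = 9), "exceeds")
  expect_warning(subs2 <- export_subsets(sel, sizes = c(4, 4)), "duplicate")
  expect_equal(names(subs2), "set4")
})
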