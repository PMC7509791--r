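catalog_with_labels <- function(label_sets) {
  g <- test_geometry()
  objs <- lapply(seq_along(label_sets), function(i)
    scene_object("imgA", sprintf("o%d", i),
                 rect_mask_matrix(60, 40, 2, 5, 2, 5), label_sets[[i]]))
  scene_catalog(g, objs, image_ids = "imgA")
}

labels_of <- function(catalog) lapply(catalog$objects, `[[`, "labels")

test_that("overlap rules strip exactly the prescribed labels", {
  cat0 <- catalog_with_labels(list(
    c("Text", "Smell", "Watchable", "Taste"),
    c("Touched", "Operable", "Gazed"),
    c("Taste", "Motion")))
  out <- labels_of(resolve_overlap(cat0))
  expect_setequal(out[[1]], c("Text", "Taste"))
  expect_setequal(out[[2]], "Touched")
  expect_setequal(out[[3]], c("Taste", "Motion"))
})

test_that("overlap resolution is idempotent and never adds labels", {
  set.seed(42)
  vocab <- osie_raw_labels()
  sets <- replicate(60, sample(vocab, sample(0:6, 1)), simplify = FALSE)
  cat0 <- catalog_with_labels(c(sets, list("Text")))
  once <- resolve_overlap(cat0)
  twice <- resolve_overlap(once)
  expect_identical(labels_of(once), labels_of(twice))
  for (i in seq_along(cat0$objects)) {
    expect_true(all(once$objects[[i]]$labels %in% cat0$objects[[i]]$labels))
    expect_identical(once$objects[[i]]$mask, cat0$objects[[i]]$mask)
  }
})

test_that("face categories merge into a single label", {
  cat0 <- catalog_with_labels(list("Emotion", c("Face", "Emotion"), "Text"))
  out <- labels_of(merge_faces(cat0))
  expect_identical(out[[1]], "Faces")
  expect_identical(out[[2]], "Faces")   # no duplicate
  expect_identical(out[[3]], "Text")
  prepped <- prepare_labels(cat0)
  expect_false(any(c("Face", "Emotion") %in% unlist(labels_of(prepped))))
  expect_false(any(c("Face", "Emotion") %in% prepped$vocabulary))
})

test_that("prevalence audit counts objects per label", {
  cat0 <- catalog_with_labels(list("Face", "Face", "Text", "Taste"))
  cat0 <- prepare_labels(cat0)
  aud <- audit_prevalence(cat0, dims = c("Faces", "Text", "Taste"))
  expect_equal(aud$absolute[aud$label == "Faces"], 2L)
  expect_equal(aud$relative_percent[aud$label == "Faces"], 50)
  expect_equal(sum(aud$relative_percent), 100)

  # an object with two labels counts once per label: totals exceed objects
  cat2 <- prepare_labels(catalog_with_labels(list(c("Face", "Text"), "Taste")))
  aud2 <- audit_prevalence(cat2)
  tally <- sum(lengths(labels_of(cat2)))  # brute-force occurrence count
  expect_equal(sum(aud2$absolute), tally)
  expect_gt(sum(aud2$absolute), length(cat2$objects))

  expect_error(audit_prevalence(cat0, image_subset = character(0)), "empty")
  expect_error(audit_prevalence(cat0, image_subset = "nope"), "unknown")
})
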