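test_that("onset and duration filters follow the exclusion rules", {
  fx <- rbind(fix_row("o1", "imgA", 10, 10, 50, 300),    # central onset
              fix_row("o1", "imgA", 10, 10, 150, 90),    # too short
              fix_row("o1", "imgA", 10, 10, 150, 200),   # retained
              fix_row("o1", "imgA", 10, 10, 40, 80))     # fails both: onset
  out <- filter_fixations(fx)
  expect_equal(nrow(out), 1L)
  expect_equal(out$onset_ms, 150)
  ex <- attr(out, "exclusions")
  expect_equal(ex[["onset"]], 2L)     # reason priority: onset before duration
  expect_equal(ex[["duration"]], 1L)
  expect_equal(attr(out, "reason"), c("onset", "duration", NA, "onset"))
})

test_that("trial truncation drops and clips fixations correctly", {
  fx <- rbind(fix_row("o1", "imgA", 1, 1, 1800, 500),
              fix_row("o1", "imgA", 1, 1, 500, 300),
              fix_row("o1", "imgA", 1, 1, 2100, 400))
  out <- truncate_fixations(fx, 2000)
  expect_equal(nrow(out), 2L)
  expect_equal(out$duration_ms[out$onset_ms == 1800], 200)  # clipped span
  expect_equal(out$duration_ms[out$onset_ms == 500], 300)   # untouched

  # cutoff at/after trial end is the identity
  trial <- rbind(fix_row("o1", "imgA", 1, 1, 100, 800),
                 fix_row("o1", "imgA", 1, 1, 950, 1950))
  expect_identical(truncate_fixations(trial, 3000), trial)
  expect_error(truncate_fixations(trial, 0), "cutoff_ms")
})

test_that("fixations are assigned by containment and radius", {
  cat0 <- prepare_labels(tiny_catalog())
  objs <- cat0$objects[1:3]  # imgA objects
  radius <- dva_to_px(cat0$geometry, 0.5)   # 5 px at 10 px/deg

  # centroid of the Faces mask
  hit <- assign_fixation(list(x_px = 9, y_px = 9), objs, radius)
  expect_true(hit$assigned)
  expect_true("o1" %in% hit$object_ids)
  expect_true("Faces" %in% hit$labels)

  # far from every mask
  miss <- assign_fixation(list(x_px = 55, y_px = 38), objs, radius)
  expect_false(miss$assigned)
  expect_identical(miss$labels, character(0))

  # a point inside the o1/o3 overlap carries the union of labels
  both <- assign_fixation(list(x_px = 13, y_px = 12), objs, radius)
  expect_setequal(both$object_ids, c("o1", "o3"))
  expect_setequal(both$labels, c("Faces", "Taste", "Motion"))

  expect_error(assign_fixation(list(x_px = NaN, y_px = 1), objs, radius),
               "finite")
})

test_that("near-miss assignment matches the per-pixel oracle, union and nearest", {
  g <- test_geometry()
  # two masks flanking a gap; fixation in the middle is within radius of both
  mA <- rect_mask_matrix(60, 40, 10, 14, 10, 20)   # right edge at x=14
  mB <- rect_mask_matrix(60, 40, 22, 26, 10, 20)   # left edge at x=22
  objs <- list(scene_object("imgA", "a", mA, "Text"),
               scene_object("imgA", "b", mB, "Taste"))
  fx <- list(x_px = 18, y_px = 15)
  oracle <- oracle_assign_ids(fx$x_px, fx$y_px, list(mA, mB), radius = 5)
  expect_setequal(oracle, c(1L, 2L))               # oracle confirms both in range
  un <- assign_fixation(fx, objs, radius_px = 5, mode = "union")
  expect_setequal(un$object_ids, c("a", "b"))
  expect_setequal(un$labels, c("Text", "Taste"))
  # equidistant tie: nearest mode keeps both
  expect_setequal(assign_fixation(fx, objs, 5, mode = "nearest")$object_ids,
                  c("a", "b"))
  # off-centre point: nearest mode keeps only the closer object
  near <- assign_fixation(list(x_px = 17, y_px = 15), objs, 5, mode = "nearest")
  expect_identical(near$object_ids, "a")
})

test_that("enlarging the radius never un-assigns a fixation", {
  set.seed(7)
  g <- test_geometry()
  for (i in 1:40) {
    masks <- replicate(3, random_mask_matrix(60, 40), simplify = FALSE)
    objs <- lapply(seq_along(masks), function(k)
      scene_object("imgA", sprintf("o%d", k), masks[[k]], "Face"))
    fx <- list(x_px = runif(1, -5, 64), y_px = runif(1, -5, 44))
    small <- assign_fixation(fx, objs, radius_px = 2)$object_ids
    large <- assign_fixation(fx, objs, radius_px = 6)$object_ids
    expect_true(all(small %in% large))
  }
})

test_that("scoring books every exclusion under one reason", {
  cat0 <- tiny_catalog()
  fx <- rbind(fix_row("o1", "imgA", 9, 9, 150, 300),    # Faces
              fix_row("o1", "imgA", 33, 9, 500, 200),   # Text
              fix_row("o1", "imgA", 55, 35, 800, 200),  # unassignable
              fix_row("o1", "imgA", 9, 9, 50, 200),     # onset
              fix_row("o1", "imgB", 9, 24, 150, 80))    # duration
  sc <- score_gaze(fx, cat0)
  expect_equal(unname(sc$exclusions),
               c(1L, 1L, 1L, 2L))  # onset, duration, unassignable, retained
  tab <- assigned_fixation_table(sc)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$labels, c("Faces", "Text"))
})
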