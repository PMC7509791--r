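# A scored fixture with known dwell structure: observer o1 spends, on imgA,
# 200 ms on a Faces object, 200 ms on a Text object and 100 ms on the
# Faces+Taste+Motion overlap region.
metrics_scores <- function() {
  cat0 <- tiny_catalog()
  fx <- rbind(
    fix_row("o1", "imgA", 7, 7, 150, 200),    # o1 only: Faces
    fix_row("o1", "imgA", 33, 9, 400, 200),   # Text
    fix_row("o1", "imgA", 13, 12, 700, 100),  # o1+o3 overlap: Faces,Taste,Motion
    fix_row("o2", "imgA", 33, 9, 150, 500),   # Text only
    fix_row("o2", "imgB", 9, 24, 150, 250))   # Faces on imgB
  score_gaze(fx, cat0)
}

test_that("dwell proportions are duration-weighted with overlapping labels", {
  sc <- metrics_scores()
  p <- dwell_proportions(sc, "o1", images = "imgA")
  # 500 ms assigned in total; Faces carries 200 + 100, Text 200
  expect_equal(p[["Faces"]], 0.6)
  expect_equal(p[["Text"]], 0.4)
  expect_equal(p[["Taste"]], 0.2)    # overlap fixation counts for each label
  expect_equal(p[["Touched"]], 0)    # label never fixated

  # all fixation time on one label
  expect_equal(dwell_proportions(sc, "o2", images = "imgB")[["Faces"]], 1)

  # proportions are invariant to uniform duration rescaling
  sc2 <- metrics_scores()
  sc2$fix$duration_ms <- sc2$fix$duration_ms * 3.7
  expect_equal(salience_matrix(sc2), salience_matrix(sc))
})

test_that("missing observers stay missing, never zero", {
  sc <- metrics_scores()
  m <- salience_matrix(sc, images = "imgB")
  expect_true(all(is.na(m["o1", ])))   # o1 has no imgB fixations
  expect_equal(m["o2", "Faces"], 1)
  expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
})

test_that("first fixations are the first surviving label-assigned fixation", {
  cat0 <- tiny_catalog()
  fx <- rbind(
    fix_row("o1", "imgA", 9, 9, 50, 300),     # excluded (onset): not first
    fix_row("o1", "imgA", 33, 9, 200, 300),   # first surviving: Text
    fix_row("o1", "imgA", 9, 9, 600, 300),
    fix_row("o1", "imgB", 33, 24, 150, 300),  # literal first: Text+Smell->Text
    fix_row("o1", "imgB", 55, 5, 500, 300))   # unassignable
  sc <- score_gaze(fx, cat0)
  p <- first_fixation_proportions(sc, "o1")
  expect_equal(p[["Text"]], 1)   # both trials' first fixation carries Text
  expect_equal(p[["Faces"]], 0)

  # strict mode drops trials whose literal first fixation was excluded
  m <- salience_matrix(sc, kind = "first_fix", strict_first = TRUE)
  expect_equal(m["o1", "Text"], 1)   # only the imgB trial remains
  comp <- gazesal:::firstfix_components(sc, "Text", strict_first = TRUE)
  expect_equal(sum(comp$denom), 1)
})

test_that("first fixations on overlapping objects count for every label", {
  cat0 <- tiny_catalog()
  fx <- rbind(fix_row("o1", "imgA", 13, 12, 150, 300),
              fix_row("o1", "imgB", 9, 24, 150, 300))
  sc <- score_gaze(fx, cat0)
  p <- first_fixation_proportions(sc, "o1", dims = c("Faces", "Taste", "Motion"))
  # trial 1 first fixation carries Faces+Taste+Motion, trial 2 Faces only
  expect_equal(p[["Faces"]], 1)
  expect_equal(p[["Taste"]], 0.5)
  expect_equal(p[["Motion"]], 0.5)
})

test_that("exploration counts distinct objects, overlaps counting per object", {
  cat0 <- tiny_catalog()
  fx <- rbind(fix_row("o1", "imgA", 9, 9, 150, 200),
              fix_row("o1", "imgA", 9, 9, 400, 200),   # same object again
              fix_row("o1", "imgA", 9, 9, 700, 200),
              fix_row("o2", "imgA", 13, 12, 150, 200)) # overlap: o1 and o3
  sc <- score_gaze(fx, cat0)
  expect_equal(exploration_count(sc, "o1"), 1L)
  expect_equal(exploration_count(sc, "o2"), 2L)
})

test_that("salience matrices are deterministic and compose over subsets", {
  sc <- metrics_scores()
  expect_identical(salience_matrix(sc), salience_matrix(sc))

  # full set equals the duration-weighted combination of disjoint subsets
  full <- salience_matrix(sc)
  a <- gazesal:::gaze_components(sc, tested_dims("dwell"), "dwell")
  mA <- gazesal:::components_matrix(a, "imgA")
  dA <- rowSums(a$denom[, 1, drop = FALSE])
  dB <- rowSums(a$denom[, 2, drop = FALSE])
  comb <- (ifelse(is.na(mA), 0, mA) * dA +
           ifelse(is.na(gazesal:::components_matrix(a, "imgB")), 0,
                  gazesal:::components_matrix(a, "imgB")) * dB) / (dA + dB)
  expect_equal(unclass(full)[, ], comb[, ], ignore_attr = TRUE)

  # a cutoff past the trial end reproduces the full matrix exactly
  expect_equal(unclass(salience_matrix(sc, cutoff_ms = 60000))[, ],
               unclass(full)[, ], ignore_attr = TRUE)
  expect_error(salience_matrix(sc, images = character(0)), "empty")
})
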