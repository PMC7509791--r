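test_that("degree-to-pixel conversion uses the mean pixels-per-degree", {
  g <- display_geometry(1920, 1080, 29.0, 22.2)
  # hand check: mean(1920/29, 1080/22.2) * 0.5
  expect_equal(dva_to_px(g, 0.5), mean(c(1920 / 29, 1080 / 22.2)) * 0.5)
  expect_equal(round(dva_to_px(g, 0.5), 1), 28.7)
  expect_identical(dva_to_px(g, 0), 0)

  gsq <- display_geometry(1000, 1000, 10, 10)
  expect_equal(dva_to_px(gsq, 1), 100)
})

test_that("conversion is linear in the angle", {
  g <- display_geometry(1920, 1080, 29.0, 22.2)
  for (a in c(0.1, 0.5, 2)) for (b in c(0.25, 1.3)) {
    expect_equal(dva_to_px(g, a + b), dva_to_px(g, a) + dva_to_px(g, b))
  }
})

test_that("geometry construction validates its inputs", {
  expect_error(dva_to_px(display_geometry(100, 100, 10, 10), -1), "non-negative")
  expect_error(display_geometry(0, 1080, 29, 22.2), "width_px")
  # anisotropy beyond a factor 2 is rejected; the canonical wide-screen
  # set-up (1.36x) constructs silently
  expect_error(display_geometry(1000, 1000, 10, 25), "implausible")
  expect_silent(display_geometry(1920, 1080, 29.0, 22.2))
})
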