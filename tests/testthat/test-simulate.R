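test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_observers = 8, n_images = 6, seed = 7)
  expect_identical(generate_catalog(cfg, seed = 3), generate_catalog(cfg, seed = 3))
  expect_identical(generate_observers(cfg, seed = 4), generate_observers(cfg, seed = 4))
  catl <- generate_catalog(cfg, seed = 3)
  obs <- generate_observers(cfg, seed = 4)
  expect_identical(simulate_session(obs, catl, cfg, seed = 5),
                   simulate_session(obs, catl, cfg, seed = 5))
  # and the global RNG stream is left untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_catalog(cfg, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("catalog label prevalence follows the configured rates", {
  cfg <- sim_config(n_observers = 2, n_images = 120, seed = 11)
  catl <- generate_catalog(cfg, seed = 11)
  labs <- lapply(catl$objects, `[[`, "labels")
  n <- length(catl$objects)
  p_face <- mean(vapply(labs, function(l) "Face" %in% l, logical(1)))
  p0 <- cfg$label_prevalence[["Face"]]
  # binomial oracle: observed rate within 4 standard errors
  expect_lt(abs(p_face - p0), 4 * sqrt(p0 * (1 - p0) / n) + 0.01)
  # every image carries at least one labelled object
  by_img <- split(lengths(labs), vapply(catl$objects, `[[`, character(1), "image_id"))
  expect_true(all(vapply(by_img, sum, numeric(1)) > 0))

  cfg1 <- sim_config(n_observers = 2, n_images = 10, n_objects_per_image = c(1, 1))
  catl1 <- generate_catalog(cfg1, seed = 2)
  expect_equal(length(catl1$objects), 10L)
  expect_error(sim_config(label_prevalence = c(Face = 0)), "zero")
})

test_that("observer profiles reproduce the configured bias spread", {
  cfg <- sim_config(n_observers = 1000, seed = 5)
  obs <- generate_observers(cfg, seed = 5)
  for (d in cfg$bias_dims) {
    expect_equal(sd(obs[[paste0("bias_", d)]]),
                 cfg$between_observer_bias_sd[[d]], tolerance = 0.1)
  }
  cfg0 <- sim_config(n_observers = 10, between_observer_bias_sd = 0)
  obs0 <- generate_observers(cfg0, seed = 1)
  expect_true(all(vapply(cfg0$bias_dims, function(d)
    sd(obs0[[paste0("bias_", d)]]) == 0, logical(1))))
})

test_that("an extreme bias drives dwell towards that dimension", {
  cfg <- sim_config(n_observers = 6, n_images = 25, seed = 9,
                    within_trial_noise_sd = 0)
  catl <- generate_catalog(cfg, seed = 9)
  obs <- generate_observers(cfg, seed = 10)
  obs$bias_Faces <- 12   # near-degenerate preference
  sc <- score_gaze(simulate_session(obs, catl, cfg, seed = 11), catl)
  # on images that contain a face, essentially all dwell goes to it
  prep <- prepare_labels(catl)
  face_imgs <- unique(vapply(
    Filter(function(o) "Faces" %in% o$labels, prep$objects),
    `[[`, character(1), "image_id"))
  m <- salience_matrix(sc, images = face_imgs)
  expect_true(all(m[, "Faces"] > 0.95))
})

test_that("generated sessions survive io round-trips and assignment", {
  cfg <- sim_config(n_observers = 4, n_images = 8, seed = 21,
                    position_jitter_px = 0, background_weight = 0,
                    label_prevalence = c(Face = 1, Emotion = 0.3, Touched = 0.2,
                                         Gazed = 0.1, Motion = 0.3, Sound = 0.1,
                                         Smell = 0.1, Taste = 0.2, Touch = 0.2,
                                         Text = 0.4, Watchable = 0.1,
                                         Operable = 0.2))
  catl <- generate_catalog(cfg, seed = 21)
  obs <- generate_observers(cfg, seed = 22)
  fx <- simulate_session(obs, catl, cfg, seed = 23)

  path <- withr::local_tempfile(fileext = ".csv")
  write_fixation_table(fx, path)
  expect_equal(read_fixation_table(path), fx, ignore_attr = TRUE,
               tolerance = 1e-12)

  # zero jitter and no background: every retained fixation is assignable
  sc <- score_gaze(fx, catl)
  expect_equal(sc$exclusions[["unassignable"]], 0L)
  # onsets start at or after the default onset filter
  expect_true(all(fx$onset_ms >= 100))
})

test_that("two noise-free sessions give near-perfect cross-session validity", {
  cfg <- sim_config(n_observers = 40, n_images = 250, seed = 31,
                    within_trial_noise_sd = 0, fixations_per_trial = 10)
  catl <- std_catalog(cfg, seed = 31)
  obs <- generate_observers(cfg, seed = 32)
  m1 <- salience_matrix(score_gaze(simulate_session(obs, catl, cfg, "d1", 33), catl))
  m2 <- salience_matrix(score_gaze(simulate_session(obs, catl, cfg, "d2", 34), catl))
  cv <- cross_set_validity(m1, m2)
  expect_true(all(cv$r > 0.8))
  expect_gt(mean(cv$r), 0.9)
})

test_that("unattainable reliability targets are rejected", {
  cfg <- sim_config(n_observers = 10, n_images = 12, seed = 41)
  catl <- generate_catalog(cfg, seed = 41)
  expect_error(
    calibrate_reliability(0.999, cfg, catl, grid_observers = 20, n_splits = 5),
    "unattainable")
  expect_error(calibrate_reliability(1.2, cfg, catl), "strictly")
})
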