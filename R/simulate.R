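# Generative free-viewing simulator with known individual-difference
# structure, plus Spearman-Brown based reliability calibration.
#
# Generative model (per observer i, image j trial):
#   * every labelled object o gets a log-weight
#       base_salience_o + sum_d (bias_id + session_id + trial_ijd) * [d in labels_o]
#     and a constant-weight background target competes with the objects;
#   * each fixation picks a target from the softmax of these weights; the
#     first fixation of a trial has its (bias + noise) term multiplied by
#     `first_fix_bottom_up_weight`;
#   * fixation position = object centroid + isotropic Gaussian jitter
#     (background: uniform over the display);
#   * fixation count ~ Poisson (truncated at 1) scaled by the observer's
#     log-normal exploration rate; dwell ~ Gamma; onsets are sequential with a
#     fixed saccade gap, the first onset >= 100 ms, and the trial is clipped
#     at the trial duration.
#
# This is the simplest process producing stable rank-order individual
# differences with tunable reliability; the analyses only assume the
# between/within variance structure, not a specific gaze model.

#' Simulation configuration
#'
#' Defaults emulate the structure of OSIE-style free-viewing studies: about
#' 100 observers by up to 700 images, 3-second trials, overlapping object
#' labels with Faces most and Touched/Taste least prevalent, stable
#' between-observer biases on the five tested dwell dimensions, within-trial
#' noise, and a bottom-up weighted first fixation. The default display is the
#' canonical 1920x1080 px / 29.0 x 22.2 dva screen scaled down tenfold so that
#' hundreds of pixel masks stay cheap.
#'
#' @param n_observers,n_images dataset size.
#' @param geometry a [display_geometry()].
#' @param n_objects_per_image integer range (min, max).
#' @param label_prevalence named per-dimension Bernoulli rates over the raw
#'   vocabulary.
#' @param emotion_requires_face sample `Emotion` only on `Face` objects
#'   (correlated overlap).
#' @param trial_duration_ms trial length (default 3000).
#' @param fixations_per_trial Poisson mean before exploration-rate scaling.
#' @param dwell_shape,dwell_mean_ms Gamma dwell-duration parameters.
#' @param saccade_gap_ms gap between successive fixations.
#' @param first_onset_range_ms range of the first fixation onset (>= 100 so
#'   generated data survive the default onset filter).
#' @param bias_dims dimensions carrying observer biases (analysis labels).
#' @param between_observer_bias_sd named SDs of the stable log-salience biases.
#' @param within_trial_noise_sd named SDs of per-trial bias noise.
#' @param session_noise_sd named SDs of per-session bias noise.
#' @param first_fix_bottom_up_weight multiplier on the bias term for the first
#'   fixation of each trial (1 = time-stationary biases).
#' @param background_weight softmax weight of the non-object target.
#' @param object_salience_sd SD of per-object base log-salience.
#' @param position_jitter_px SD of fixation position jitter around centroids.
#' @param exploration_rate_sdlog log-normal SD of the per-observer
#'   exploration rate (mean 1).
#' @param seed default seed for generators that are not given one.
#' @return an object of class `sim_config` (a list).
#' @export
sim_config <- function(n_observers = 100L,
                       n_images = 700L,
                       geometry = display_geometry(192L, 108L, 29.0, 22.2),
                       n_objects_per_image = c(5L, 10L),
                       label_prevalence = c(Face = 0.22, Emotion = 0.08,
                                            Touched = 0.06, Gazed = 0.05,
                                            Motion = 0.10, Sound = 0.06,
                                            Smell = 0.06, Taste = 0.06,
                                            Touch = 0.10, Text = 0.12,
                                            Watchable = 0.07, Operable = 0.12),
                       emotion_requires_face = TRUE,
                       trial_duration_ms = 3000,
                       fixations_per_trial = 8,
                       dwell_shape = 4, dwell_mean_ms = 250,
                       saccade_gap_ms = 30,
                       first_onset_range_ms = c(100, 200),
                       bias_dims = tested_dims("dwell"),
                       between_observer_bias_sd = c(Faces = 0.80, Text = 0.70,
                                                    Touched = 0.65, Taste = 0.65,
                                                    Motion = 0.60),
                       within_trial_noise_sd = c(Faces = 0.30, Text = 0.30,
                                                 Touched = 0.30, Taste = 0.30,
                                                 Motion = 0.30),
                       session_noise_sd = c(Faces = 0, Text = 0, Touched = 0,
                                            Taste = 0, Motion = 0),
                       first_fix_bottom_up_weight = 0.8,
                       background_weight = 2.0,
                       object_salience_sd = 0.30,
                       position_jitter_px = 0.8,
                       exploration_rate_sdlog = 0.25,
                       seed = 1L) {
  stopifnot(inherits(geometry, "display_geometry"))
  if (any(label_prevalence < 0 | label_prevalence > 1))
    abort("label_prevalence must lie in [0, 1]")
  if (all(label_prevalence == 0)) abort("all label prevalences are zero")
  as_named <- function(x, what) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, length(bias_dims)),
                                                bias_dims)
    if (!all(bias_dims %in% names(x)))
      abort(sprintf("%s must be named for every bias dimension", what))
    if (any(x[bias_dims] < 0)) abort(sprintf("%s must be >= 0", what))
    x[bias_dims]
  }
  cfg <- list(n_observers = as.integer(n_observers),
              n_images = as.integer(n_images),
              geometry = geometry,
              n_objects_per_image = as.integer(n_objects_per_image),
              label_prevalence = label_prevalence,
              emotion_requires_face = isTRUE(emotion_requires_face),
              trial_duration_ms = trial_duration_ms,
              fixations_per_trial = fixations_per_trial,
              dwell_shape = dwell_shape, dwell_mean_ms = dwell_mean_ms,
              saccade_gap_ms = saccade_gap_ms,
              first_onset_range_ms = first_onset_range_ms,
              bias_dims = bias_dims,
              between_observer_bias_sd = as_named(between_observer_bias_sd,
                                                  "between_observer_bias_sd"),
              within_trial_noise_sd = as_named(within_trial_noise_sd,
                                               "within_trial_noise_sd"),
              session_noise_sd = as_named(session_noise_sd, "session_noise_sd"),
              first_fix_bottom_up_weight = first_fix_bottom_up_weight,
              background_weight = background_weight,
              object_salience_sd = object_salience_sd,
              position_jitter_px = position_jitter_px,
              exploration_rate_sdlog = exploration_rate_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulation presets
#'
#' * `"default"`: the standard conditions of [sim_config()].
#' * `"low-reliability"`: quadrupled within-trial noise.
#' * `"two-session"`: session noise enabled (SD 0.3 per dimension).
#' * `"stationary"`: time-stationary biases (no first-fixation reweighting).
#'
#' @param preset preset name.
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
sim_preset <- function(preset = c("default", "low-reliability", "two-session",
                                  "stationary"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "default" = list(),
    "low-reliability" = list(within_trial_noise_sd = 1.2),
    "two-session" = list(session_noise_sd = 0.3),
    "stationary" = list(first_fix_bottom_up_weight = 1))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# centroid of a mask (mean true-pixel coordinates, 0-based)
mask_centroid <- function(mask) {
  idx <- which(mask$sub, arr.ind = TRUE)
  c(x = mask$x0 + mean(idx[, 2L]) - 1, y = mask$y0 + mean(idx[, 1L]) - 1)
}

#' Generate a synthetic scene catalog
#'
#' Rectangular and elliptic object masks (possibly overlapping) with label
#' sets sampled per-dimension from `cfg$label_prevalence` over the raw
#' vocabulary; at least one labelled object per image is guaranteed. The
#' overlap-resolution rules are exercised downstream because raw labels are
#' sampled before preparation. Per-object base log-salience is attached as
#' attribute `"base_salience"` (simulation metadata, not catalog data).
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return a raw [scene_catalog()].
#' @export
generate_catalog <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- cfg$geometry
  vocab <- names(cfg$label_prevalence)
  with_seed(seed, {
    image_ids <- sprintf("img%04d", seq_len(cfg$n_images))
    objects <- list()
    salience <- numeric(0)
    for (j in seq_len(cfg$n_images)) {
      K <- sample(cfg$n_objects_per_image[1]:cfg$n_objects_per_image[2], 1L)
      labm <- matrix(stats::runif(K * length(vocab)) <
                       rep(cfg$label_prevalence, each = K),
                     K, length(vocab), dimnames = list(NULL, vocab))
      if (cfg$emotion_requires_face && all(c("Face", "Emotion") %in% vocab)) {
        pe <- min(1, cfg$label_prevalence[["Emotion"]] /
                    max(cfg$label_prevalence[["Face"]], 1e-9))
        labm[, "Emotion"] <- labm[, "Face"] & (stats::runif(K) < pe)
      }
      if (!any(labm)) {  # guarantee a labelled object
        d <- sample(vocab, 1L, prob = cfg$label_prevalence)
        labm[sample.int(K, 1L), d] <- TRUE
      }
      for (k in seq_len(K)) {
        hx <- stats::runif(1, 0.03, 0.10) * g$width_px
        hy <- stats::runif(1, 0.04, 0.13) * g$height_px
        cx <- stats::runif(1, hx + 1, g$width_px - hx - 2)
        cy <- stats::runif(1, hy + 1, g$height_px - hy - 2)
        m <- if (stats::runif(1) < 0.5)
          rasterize_rect(g$width_px, g$height_px, cx, cy, hx, hy)
        else
          rasterize_ellipse(g$width_px, g$height_px, cx, cy, hx, hy)
        objects[[length(objects) + 1L]] <-
          scene_object(image_ids[j], sprintf("obj%02d", k), pixel_mask(m),
                       vocab[labm[k, ]], vocabulary = vocab)
        salience <- c(salience, stats::rnorm(1, 0, cfg$object_salience_sd))
      }
    }
    cat <- scene_catalog(g, objects, image_ids = image_ids, vocabulary = vocab)
    attr(cat, "base_salience") <- salience
    cat
  })
}

#' Generate observer profiles
#'
#' Per-dimension biases are drawn independently from
#' `Normal(0, between_observer_bias_sd[d])`; the exploration rate is
#' log-normal with mean 1.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param n_observers number of observers (default `cfg$n_observers`).
#' @param id_prefix prefix for observer ids.
#' @return data.frame with `observer_id`, one `bias_<dim>` column per
#'   dimension, and `exploration_rate`.
#' @export
generate_observers <- function(cfg, seed = cfg$seed,
                               n_observers = cfg$n_observers,
                               id_prefix = "obs") {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    out <- data.frame(observer_id = sprintf("%s%04d", id_prefix,
                                            seq_len(n_observers)),
                      stringsAsFactors = FALSE)
    for (d in cfg$bias_dims)
      out[[paste0("bias_", d)]] <-
        stats::rnorm(n_observers, 0, cfg$between_observer_bias_sd[[d]])
    sdl <- cfg$exploration_rate_sdlog
    out$exploration_rate <- stats::rlnorm(n_observers, -sdl^2 / 2, sdl)
    out
  })
}

#' Simulate a free-viewing session
#'
#' Generates a fixation table for every observer by image trial under the
#' generative model described in the package vignette. Two sessions simulated
#' from the same profiles and catalog share the stable biases but draw fresh
#' session and trial noise.
#'
#' @param observers a [generate_observers()] data.frame.
#' @param catalog a [scene_catalog()] (raw or prepared).
#' @param cfg a [sim_config()].
#' @param session_id label attached to the output.
#' @param seed RNG seed.
#' @return a fixation data.frame (canonical columns) with attribute
#'   `"session_id"`.
#' @export
simulate_session <- function(observers, catalog, cfg, session_id = "day1",
                             seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), inherits(catalog, "scene_catalog"))
  prep <- prepare_labels(catalog)
  dims <- cfg$bias_dims
  bad <- setdiff(dims, prep$vocabulary)
  if (length(bad))
    abort(sprintf("bias dimensions missing from the catalog vocabulary: %s",
                  paste(bad, collapse = ", ")))
  n_obs <- nrow(observers)
  bias <- as.matrix(observers[paste0("bias_", dims)])  # n_obs x D
  explor <- observers$exploration_rate
  g <- cfg$geometry

  labm <- catalog_label_matrix(prep)[, dims, drop = FALSE]
  base_sal <- attr(catalog, "base_salience") %||% rep(0, length(prep$objects))
  cents <- vapply(prep$objects, function(o) mask_centroid(o$mask), numeric(2))
  obj_by_img <- split(seq_along(prep$objects),
                      factor(vapply(prep$objects, `[[`, character(1), "image_id"),
                             levels = prep$image_ids))

  with_seed(seed, {
    sess_noise <- matrix(stats::rnorm(n_obs * length(dims)), n_obs) *
      rep(cfg$session_noise_sd[dims], each = n_obs)

    obs_l <- list(); img_l <- list(); tgt_l <- list(); first_l <- list()
    for (j in seq_along(prep$image_ids)) {
      oidx <- obj_by_img[[j]]
      K <- length(oidx)
      trial_noise <- matrix(stats::rnorm(n_obs * length(dims)), n_obs) *
        rep(cfg$within_trial_noise_sd[dims], each = n_obs)
      eff <- bias + sess_noise + trial_noise            # n_obs x D
      logit <- eff %*% t(labm[oidx, , drop = FALSE])    # n_obs x K
      base <- rep(base_sal[oidx], each = n_obs)
      W <- cbind(exp(base + logit), cfg$background_weight)
      W1 <- cbind(exp(base + cfg$first_fix_bottom_up_weight * logit),
                  cfg$background_weight)
      nfix <- pmax(1L, stats::rpois(n_obs, cfg$fixations_per_trial * explor))

      # first fixations: one categorical draw per observer from W1
      cw1 <- W1
      for (k in 2:ncol(cw1)) cw1[, k] <- cw1[, k] + cw1[, k - 1L]
      u1 <- stats::runif(n_obs) * cw1[, ncol(cw1)]
      t1 <- rowSums(cw1 < u1) + 1L

      # subsequent fixations from W, expanded per fixation
      n2 <- nfix - 1L
      rows <- rep.int(seq_len(n_obs), n2)
      if (length(rows)) {
        cw <- W
        for (k in 2:ncol(cw)) cw[, k] <- cw[, k] + cw[, k - 1L]
        ce <- cw[rows, , drop = FALSE]
        u <- stats::runif(length(rows)) * ce[, ncol(ce)]
        t2 <- rowSums(ce < u) + 1L
      } else t2 <- integer(0)

      # interleave: per observer, first fixation then the rest (trial-ordered)
      ord <- order(c(seq_len(n_obs), rows), c(rep(1L, n_obs), rep(2L, length(rows))))
      tgt <- c(t1, t2)[ord]
      obs_v <- c(seq_len(n_obs), rows)[ord]
      first_v <- c(rep(TRUE, n_obs), rep(FALSE, length(rows)))[ord]
      tgt_obj <- ifelse(tgt <= K, oidx[tgt], 0L)  # 0 = background

      obs_l[[j]] <- obs_v; img_l[[j]] <- rep.int(j, length(obs_v))
      tgt_l[[j]] <- tgt_obj; first_l[[j]] <- first_v
    }

    obs_v <- unlist(obs_l); img_v <- unlist(img_l)
    tgt_v <- unlist(tgt_l); first_v <- unlist(first_l)
    N <- length(obs_v)

    # positions
    x <- numeric(N); y <- numeric(N)
    on_obj <- tgt_v > 0L
    x[on_obj] <- cents[1L, tgt_v[on_obj]] +
      stats::rnorm(sum(on_obj), 0, cfg$position_jitter_px)
    y[on_obj] <- cents[2L, tgt_v[on_obj]] +
      stats::rnorm(sum(on_obj), 0, cfg$position_jitter_px)
    x[!on_obj] <- stats::runif(sum(!on_obj), 0, g$width_px - 1)
    y[!on_obj] <- stats::runif(sum(!on_obj), 0, g$height_px - 1)

    # durations and sequential onsets, clipped at the trial duration
    dur <- stats::rgamma(N, shape = cfg$dwell_shape,
                         scale = cfg$dwell_mean_ms / cfg$dwell_shape)
    o1 <- stats::runif(N, cfg$first_onset_range_ms[1], cfg$first_onset_range_ms[2])
    step <- dur + cfg$saccade_gap_ms
    prev <- c(0, step[-N]); prev[first_v] <- 0
    cum <- cumsum(prev)
    first_pos <- which(first_v)
    base_cum <- rep.int(cum[first_pos], diff(c(first_pos, N + 1L)))
    first_onset <- rep.int(o1[first_pos], diff(c(first_pos, N + 1L)))
    onset <- first_onset + (cum - base_cum)
    keep <- onset < cfg$trial_duration_ms
    dur <- pmin(dur, cfg$trial_duration_ms - onset)

    out <- data.frame(
      observer_id = observers$observer_id[obs_v[keep]],
      image_id = prep$image_ids[img_v[keep]],
      x_px = x[keep], y_px = y[keep],
      onset_ms = onset[keep], duration_ms = dur[keep],
      stringsAsFactors = FALSE)
    attr(out, "session_id") <- session_id
    out
  })
}
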