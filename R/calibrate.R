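# Reliability calibration for the synthetic generator.
#
# Split-half reliability of a k-image aggregate follows the Spearman-Brown
# relation r = k L / (1 + (k - 1) L) in the per-image reliability L, because
# images are exchangeable draws from the generator. Calibration therefore
# works on measured reliabilities: the target r at the study's half-set size
# is mapped through the Spearman-Brown inversion to the equivalent target at
# a smaller calibration grid, and the trial-noise SD is root-found per
# dimension against grid reliabilities measured by running the simulator
# through the *actual* scoring pipeline. Every grid evaluation reuses the
# same derived seeds (common random numbers), which makes the measured
# reliability a smooth, monotone function of the noise SD and lets a
# bracket-plus-secant search converge in a handful of evaluations.

# catalog restricted to an image subset (simulation metadata preserved)
subset_catalog <- function(catalog, image_ids) {
  keep <- vapply(catalog$objects, function(o) o$image_id %in% image_ids,
                 logical(1))
  out <- catalog
  out$objects <- catalog$objects[keep]
  out$image_ids <- as.character(image_ids)
  sal <- attr(catalog, "base_salience")
  if (!is.null(sal)) attr(out, "base_salience") <- sal[keep]
  out
}

# evenly spaced image subsample (representative of the catalog population)
spread_subset <- function(ids, n) {
  ids[unique(round(seq(1, length(ids), length.out = min(n, length(ids)))))]
}

# median split-half r per dimension on a calibration grid; common random
# numbers across calls with the same seed
grid_split_half <- function(cfg, catalog, dims, sigma_w, n_obs, n_images,
                            n_splits, seed) {
  cfg_run <- cfg
  cfg_run$within_trial_noise_sd[dims] <- sigma_w
  sub <- subset_catalog(catalog, spread_subset(catalog$image_ids, n_images))
  obs <- generate_observers(cfg_run, seed = derive_seed(seed, "cal-obs"),
                            n_observers = n_obs, id_prefix = "cal")
  fx <- simulate_session(obs, sub, cfg_run, session_id = "cal",
                         seed = derive_seed(seed, "cal-sess"))
  sc <- score_gaze(fx, sub)
  ch <- split_half(sc, dims = dims, kind = "dwell", n_splits = n_splits,
                   seed = derive_seed(seed, "cal-split"))
  stats::setNames(ch$median_r, ch$dimension)
}

# cross-session validity r per dimension with two grid sessions
grid_cross_session <- function(cfg, catalog, dims, sigma_s, n_obs, n_images,
                               seed) {
  cfg_run <- cfg
  cfg_run$session_noise_sd[dims] <- sigma_s
  sub <- subset_catalog(catalog, spread_subset(catalog$image_ids, n_images))
  obs <- generate_observers(cfg_run, seed = derive_seed(seed, "cal-obs"),
                            n_observers = n_obs, id_prefix = "cal")
  m <- lapply(c("s1", "s2"), function(s) {
    fx <- simulate_session(obs, sub, cfg_run, session_id = s,
                           seed = derive_seed(seed, paste0("cal-", s)))
    salience_matrix(score_gaze(fx, sub), dims, "dwell")
  })
  cv <- cross_set_validity(m[[1]], m[[2]])
  stats::setNames(cv$r, cv$dimension)
}

# monotone-decreasing interpolation: smallest sigma whose r reaches target,
# linear in r over log1p(sigma) between the bracketing evaluations
interp_sigma <- function(s, r, target) {
  o <- order(s)
  s <- s[o]; r <- r[o]
  below <- which(r < target)
  if (!length(below)) return(max(s) * 2 + 1)   # extend the bracket
  hi <- min(below)
  if (hi == 1L) return(s[1])
  lo <- hi - 1L
  w <- (r[lo] - target) / max(r[lo] - r[hi], 1e-9)
  expm1(log1p(s[lo]) + w * (log1p(s[hi]) - log1p(s[lo])))
}

root_find_sigma <- function(target, eval_fun, ladder, tol, max_iter) {
  dims <- names(target)
  r0 <- eval_fun(stats::setNames(rep(0, length(dims)), dims))
  short <- r0 < target - pmax(0.04, 2 * tol)
  if (any(short))
    abort(sprintf(
      "target reliability unattainable for %s: the zero-noise ceiling is %s",
      paste(dims[short], collapse = ", "),
      paste(sprintf("%.3f", r0[short]), collapse = ", ")))
  at_ceiling <- r0 < target
  if (any(at_ceiling)) {
    warning(sprintf(
      "target within measurement margin of the zero-noise ceiling for %s; using zero noise",
      paste(dims[at_ceiling], collapse = ", ")), call. = FALSE)
    target[at_ceiling] <- r0[at_ceiling] - 1e-6
  }
  pts <- lapply(dims, function(d) list(s = 0, r = r0[[d]]))
  names(pts) <- dims
  for (sig in ladder) {
    bracketed <- vapply(seq_along(dims), function(i)
      any(pts[[i]]$r < target[i]), logical(1))
    if (all(bracketed)) break
    rr <- eval_fun(stats::setNames(rep(sig, length(dims)), dims))
    for (i in seq_along(dims)) {
      pts[[i]]$s <- c(pts[[i]]$s, sig)
      pts[[i]]$r <- c(pts[[i]]$r, rr[[i]])
    }
  }
  sigma <- vapply(seq_along(dims), function(i)
    interp_sigma(pts[[i]]$s, pts[[i]]$r, target[i]), numeric(1))
  r_cur <- r0
  for (it in seq_len(max_iter)) {
    r_cur <- eval_fun(stats::setNames(sigma, dims))
    for (i in seq_along(dims)) {
      pts[[i]]$s <- c(pts[[i]]$s, sigma[i])
      pts[[i]]$r <- c(pts[[i]]$r, r_cur[[i]])
    }
    if (all(abs(r_cur - target) < tol)) break
    sigma <- vapply(seq_along(dims), function(i)
      interp_sigma(pts[[i]]$s, pts[[i]]$r, target[i]), numeric(1))
  }
  list(sigma = stats::setNames(sigma, dims),
       r_grid = r_cur, r_zero = r0)
}

#' Calibrate trial noise for a target split-half reliability
#'
#' Solves the per-dimension within-trial noise SD so that the simulated
#' study's median split-half correlation at half-set size `k_half` matches
#' `target_r`. The target is converted to the calibration-grid scale through
#' the Spearman-Brown inversion (per-image reliability `lambda`), and the
#' noise SD is root-found against reliabilities measured on simulated
#' calibration grids scored by the real pipeline. Targets above the
#' zero-noise ceiling of the generator raise an error.
#'
#' @param target_r target split-half correlation(s) in (0, 1); scalar or a
#'   vector named by dimension.
#' @param cfg a [sim_config()].
#' @param catalog catalog the study will use (default: `generate_catalog(cfg)`).
#' @param k_half images per half in the target study (default
#'   `cfg$n_images / 2`).
#' @param grid_observers,grid_images calibration grid size (`grid_images`
#'   defaults to the full study image set: reliability targets then need no
#'   set-size extrapolation).
#' @param n_splits splits per grid reliability measurement.
#' @param tol convergence tolerance on the grid-scale reliability.
#' @param max_iter maximum secant refinements.
#' @param seed RNG seed (grids use common random numbers derived from it).
#' @return `cfg` with `within_trial_noise_sd` replaced; attribute
#'   `"calibration"` holds per-dimension diagnostics (target, per-image
#'   `lambda_star`, solved sigma, grid reliabilities).
#' @export
calibrate_reliability <- function(target_r, cfg, catalog = NULL, k_half = NULL,
                                  grid_observers = 120L, grid_images = NULL,
                                  n_splits = 40L, tol = 0.015, max_iter = 8L,
                                  seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(target_r <= 0 | target_r >= 1))
    abort("target_r must lie strictly in (0, 1)")
  if (is.null(catalog)) catalog <- generate_catalog(cfg)
  dims <- cfg$bias_dims
  target <- if (is.null(names(target_r)))
    stats::setNames(rep_len(target_r, length(dims)), dims)
  else {
    if (!all(dims %in% names(target_r)))
      abort("named target_r must cover every bias dimension")
    target_r[dims]
  }
  k_half <- k_half %||% (cfg$n_images / 2)
  # default grid = the study's own image set, so the target needs no
  # set-size extrapolation (Spearman-Brown scaling is exact only for
  # homogeneous items; per-image information is heterogeneous here)
  grid_images <- grid_images %||% length(catalog$image_ids)
  k_grid <- length(spread_subset(catalog$image_ids, grid_images))
  lambda_star <- spearman_brown_inverse(target, k_half)
  if (any(lambda_star <= 0 | lambda_star >= 1))
    abort("target reliability is not attainable at this set size")
  target_grid <- spearman_brown(lambda_star, k_grid %/% 2L)

  fit <- root_find_sigma(
    target_grid,
    function(sig) grid_split_half(cfg, catalog, dims, sig, grid_observers,
                                  k_grid, n_splits, seed),
    ladder = c(0.5, 1, 2, 4, 8, 16), tol = tol, max_iter = max_iter)

  out <- cfg
  out$within_trial_noise_sd[dims] <- fit$sigma
  attr(out, "calibration") <- data.frame(
    dimension = dims,
    target_r = as.numeric(target),
    lambda_star = as.numeric(lambda_star),
    target_grid_r = as.numeric(target_grid),
    sigma_w = as.numeric(fit$sigma),
    grid_r = as.numeric(fit$r_grid[dims]),
    grid_r_zero_noise = as.numeric(fit$r_zero[dims]),
    predicted_study_r = as.numeric(
      spearman_brown(spearman_brown_inverse(fit$r_grid[dims], k_grid %/% 2L),
                     k_half)),
    row.names = NULL)
  out
}

#' Solve session noise for a target cross-session correlation
#'
#' Chooses per-dimension session-noise SDs so that the validity correlation
#' between full-set estimates from two simulated sessions of `k_images`
#' images equals `target_r`. Measurement noise attenuates the correlation
#' even without session noise, so the root-find runs on cross-session
#' correlations measured on two-session calibration grids at the full
#' `k_images` (no set-size extrapolation); targets above that measurement
#' ceiling raise an error.
#'
#' @inheritParams calibrate_reliability
#' @param k_images images per session (default `cfg$n_images`); the grid uses
#'   the same number.
#' @return `cfg` with `session_noise_sd` set; attribute `"calibration"` holds
#'   diagnostics.
#' @export
solve_session_noise <- function(target_r, cfg, catalog = NULL,
                                k_images = cfg$n_images,
                                grid_observers = 250L, tol = 0.01,
                                max_iter = 8L, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(target_r <= 0 | target_r >= 1))
    abort("target_r must lie strictly in (0, 1)")
  if (is.null(catalog)) catalog <- generate_catalog(cfg)
  dims <- cfg$bias_dims
  target <- if (is.null(names(target_r)))
    stats::setNames(rep_len(target_r, length(dims)), dims) else target_r[dims]

  fit <- root_find_sigma(
    target,
    function(sig) grid_cross_session(cfg, catalog, dims, sig, grid_observers,
                                     k_images, seed),
    ladder = c(0.25, 0.5, 1, 2, 4), tol = tol, max_iter = max_iter)

  out <- cfg
  out$session_noise_sd[dims] <- fit$sigma
  attr(out, "calibration") <- data.frame(
    dimension = dims, target_r = as.numeric(target),
    sigma_s = as.numeric(fit$sigma),
    grid_r = as.numeric(fit$r_grid[dims]),
    grid_r_zero_noise = as.numeric(fit$r_zero[dims]),
    row.names = NULL)
  out
}
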