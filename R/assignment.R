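# Fixation filtering, object assignment and trial truncation.

#' Fixation filter parameters
#'
#' Defaults follow standard free-viewing practice: central onset fixations
#' (onset time < 100 ms) and fixations shorter than 100 ms are excluded, and
#' fixations are assigned to objects on or within 0.5 degrees visual angle.
#'
#' @param min_onset_ms minimum fixation onset relative to image onset (ms).
#' @param min_duration_ms minimum fixation duration (ms).
#' @param assign_radius_dva assignment radius in degrees of visual angle.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(min_onset_ms = 100, min_duration_ms = 100,
                          assign_radius_dva = 0.5) {
  check_number(min_onset_ms, "min_onset_ms", lower = 0)
  check_number(min_duration_ms, "min_duration_ms", lower = 0)
  check_number(assign_radius_dva, "assign_radius_dva", lower = 0)
  structure(list(min_onset_ms = min_onset_ms,
                 min_duration_ms = min_duration_ms,
                 assign_radius_dva = assign_radius_dva),
            class = "filter_params")
}

#' Filter fixations by onset and duration
#'
#' Retains fixations with `onset_ms >= min_onset_ms` and
#' `duration_ms >= min_duration_ms`, preserving input order. Every dropped
#' fixation is booked under a single reason with priority onset < duration.
#'
#' @param fixations fixation data.frame (canonical columns).
#' @param params a [filter_params()].
#' @return the retained fixations; attribute `"exclusions"` holds counts by
#'   reason and attribute `"reason"` the per-row reason vector for the input
#'   (`NA` for retained rows).
#' @export
filter_fixations <- function(fixations, params = filter_params()) {
  validate_fixations(fixations)
  reason <- rep(NA_character_, nrow(fixations))
  reason[fixations$onset_ms < params$min_onset_ms] <- "onset"
  reason[is.na(reason) &
           fixations$duration_ms < params$min_duration_ms] <- "duration"
  out <- fixations[is.na(reason), , drop = FALSE]
  attr(out, "exclusions") <- c(onset = sum(reason == "onset", na.rm = TRUE),
                               duration = sum(reason == "duration", na.rm = TRUE))
  attr(out, "reason") <- reason
  out
}

#' Truncate a trial to a viewing-time cutoff
#'
#' Fixations starting at or after `cutoff_ms` are dropped; a fixation spanning
#' the cutoff keeps the partial dwell `cutoff_ms - onset_ms`; earlier
#' fixations are unchanged. Order (and hence first-fixation identity) is
#' preserved: truncation only drops or clips, never re-orders.
#'
#' @param fixations fixation data.frame.
#' @param cutoff_ms positive cutoff relative to image onset (ms).
#' @return the truncated fixation data.frame (`duration_ms` holds the
#'   effective, possibly clipped, duration).
#' @export
truncate_fixations <- function(fixations, cutoff_ms) {
  check_number(cutoff_ms, "cutoff_ms", lower = 1e-9)
  validate_fixations(fixations)
  keep <- fixations$onset_ms < cutoff_ms
  out <- fixations[keep, , drop = FALSE]
  out$duration_ms <- pmin(out$duration_ms, cutoff_ms - out$onset_ms)
  out
}

#' Assign one fixation to scene objects
#'
#' A fixation inside at least one mask is assigned to all containing objects.
#' Otherwise, if its Euclidean distance to the nearest mask pixel is at most
#' `radius_px`, it is assigned to all objects within the radius (`mode =
#' "union"`, the default) or only to the nearest object(s) (`mode =
#' "nearest"`). The fixation's labels are the union over the assigned
#' objects' labels; objects with empty label sets confer assignment but
#' contribute no labels, so a fixation whose label union is empty counts as
#' unassignable downstream.
#'
#' @param fix one fixation (a list or one-row data.frame with `x_px`, `y_px`).
#' @param objects list of [scene_object()]s sharing the fixation's pixel frame.
#' @param radius_px assignment radius in pixels (e.g. `dva_to_px(geom, 0.5)`).
#' @param mode `"union"` or `"nearest"` for near-miss ties.
#' @return list with `assigned` (logical), `object_ids`, `labels` and
#'   `distance_px` (0 when contained, `NA` when unassigned).
#' @export
assign_fixation <- function(fix, objects, radius_px, mode = c("union", "nearest")) {
  mode <- match.arg(mode)
  x <- fix$x_px; y <- fix$y_px
  if (!is.finite(x) || !is.finite(y))
    abort("fixation coordinates must be finite")
  check_number(radius_px, "radius_px", lower = 0)
  inside <- vapply(objects, function(o) mask_contains(o$mask, x, y), logical(1))
  if (any(inside)) {
    idx <- which(inside); dist <- 0
  } else {
    d <- vapply(objects, function(o) mask_min_dist(o$mask, x, y), numeric(1))
    within <- which(d <= radius_px)
    if (!length(within))
      return(list(assigned = FALSE, object_ids = character(),
                  labels = character(), distance_px = NA_real_))
    idx <- if (mode == "union") within else within[d[within] == min(d[within])]
    dist <- min(d[within])
  }
  list(assigned = TRUE,
       object_ids = vapply(objects[idx], `[[`, character(1), "object_id"),
       labels = sort(unique(unlist(lapply(objects[idx], `[[`, "labels")))),
       distance_px = dist)
}

#' Score a fixation dataset against a scene catalog
#'
#' Runs the full per-fixation pipeline: onset/duration filtering, object
#' assignment (containment or within-radius), label lookup and exclusion
#' bookkeeping. Raw catalogs are label-prepared first (face merge + overlap
#' resolution). The result caches everything the metric and reliability
#' analyses need, including per-fixation label membership and the expanded
#' fixation-object hit table used for visual-exploration counts.
#'
#' @param fixations fixation data.frame (canonical columns).
#' @param catalog a [scene_catalog()].
#' @param params a [filter_params()].
#' @param mode near-miss assignment mode, see [assign_fixation()].
#' @return an object of class `gaze_scores`.
#' @export
score_gaze <- function(fixations, catalog, params = filter_params(),
                       mode = c("union", "nearest")) {
  mode <- match.arg(mode)
  validate_fixations(fixations)
  stopifnot(inherits(catalog, "scene_catalog"))
  if (!isTRUE(catalog$prepared)) catalog <- prepare_labels(catalog)
  radius_px <- dva_to_px(catalog$geometry, params$assign_radius_dva)
  vocab <- catalog$vocabulary

  observers <- sort(unique(fixations$observer_id))
  obs <- match(fixations$observer_id, observers)
  img <- match(fixations$image_id, catalog$image_ids)
  if (anyNA(img))
    abort(sprintf("fixations reference images absent from the catalog: %s",
                  paste(unique(fixations$image_id[is.na(img)])[1:5], collapse = ", ")))

  # literal first fixation of each trial (pre-filter), for strict_first mode
  trial <- (img - 1L) * length(observers) + obs
  ord <- order(trial, fixations$onset_ms)
  trial_first <- logical(nrow(fixations))
  trial_first[ord[!duplicated(trial[ord])]] <- TRUE

  reason <- rep(NA_character_, nrow(fixations))
  reason[fixations$onset_ms < params$min_onset_ms] <- "onset"
  reason[is.na(reason) &
           fixations$duration_ms < params$min_duration_ms] <- "duration"
  retained <- which(is.na(reason))

  by_img <- catalog_objects_by_image(catalog)
  labmat_cat <- catalog_label_matrix(catalog)
  obj_of <- vapply(catalog$objects, `[[`, character(1), "image_id")
  obj_index_by_img <- split(seq_along(catalog$objects),
                            factor(obj_of, levels = catalog$image_ids))

  n_ret <- length(retained)
  fix_lab <- matrix(FALSE, n_ret, length(vocab), dimnames = list(NULL, vocab))
  assigned <- logical(n_ret)
  hit_fix <- integer(0); hit_obj <- integer(0)  # indices into retained / objects

  ximg <- img[retained]
  for (j in seq_along(catalog$image_ids)) {
    rows <- which(ximg == j)            # positions within `retained`
    if (!length(rows)) next
    oidx <- obj_index_by_img[[j]]
    if (!length(oidx)) next
    fx <- fixations$x_px[retained[rows]]
    fy <- fixations$y_px[retained[rows]]
    K <- length(oidx)
    inside <- matrix(FALSE, length(rows), K)
    for (k in seq_len(K))
      inside[, k] <- mask_contains(catalog$objects[[oidx[k]]]$mask, fx, fy)
    hit <- inside
    far <- which(rowSums(inside) == 0L)
    if (length(far)) {
      dmat <- matrix(Inf, length(far), K)
      for (k in seq_len(K))
        dmat[, k] <- mask_min_dist(catalog$objects[[oidx[k]]]$mask,
                                   fx[far], fy[far])
      within <- dmat <= radius_px
      if (mode == "nearest" && any(within)) {
        dmin <- apply(dmat, 1L, min)
        within <- within & (dmat == dmin)
      }
      hit[far, ] <- within
    }
    hh <- which(hit, arr.ind = TRUE)
    if (nrow(hh)) {
      hit_fix <- c(hit_fix, rows[hh[, 1L]])
      hit_obj <- c(hit_obj, oidx[hh[, 2L]])
      assigned[rows] <- rowSums(hit) > 0L
      # label union per fixation
      for (k in seq_len(K)) {
        lk <- labmat_cat[oidx[k], ]
        if (any(lk)) {
          rk <- rows[hit[, k]]
          if (length(rk))
            fix_lab[rk, lk] <- TRUE
        }
      }
    }
  }

  has_label <- rowSums(fix_lab) > 0L
  reason[retained[!has_label]] <- "unassignable"

  keep <- which(has_label)
  fix <- data.frame(obs = obs[retained[keep]],
                    img = img[retained[keep]],
                    onset_ms = fixations$onset_ms[retained[keep]],
                    duration_ms = fixations$duration_ms[retained[keep]],
                    trial_first = trial_first[retained[keep]])
  structure(list(
    observers = observers,
    image_ids = catalog$image_ids,
    vocabulary = vocab,
    fix = fix,
    labmat = fix_lab[keep, , drop = FALSE],
    hits = data.frame(obs = obs[retained[hit_fix]],
                      img = img[retained[hit_fix]],
                      obj = hit_obj,
                      onset_ms = fixations$onset_ms[retained[hit_fix]]),
    exclusions = c(onset = sum(reason == "onset", na.rm = TRUE),
                   duration = sum(reason == "duration", na.rm = TRUE),
                   unassignable = sum(reason == "unassignable", na.rm = TRUE),
                   retained = length(keep)),
    n_input = nrow(fixations),
    params = params, mode = mode, radius_px = radius_px,
    geometry = catalog$geometry),
    class = "gaze_scores")
}

#' @export
print.gaze_scores <- function(x, ...) {
  ex <- x$exclusions
  cat(sprintf("<gaze_scores> %d observers x %d images; %d fixations in\n",
              length(x$observers), length(x$image_ids), x$n_input))
  cat(sprintf("  retained (label-assigned): %d | excluded: onset %d, duration %d, unassignable %d\n",
              ex[["retained"]], ex[["onset"]], ex[["duration"]],
              ex[["unassignable"]]))
  cat(sprintf("  assignment: %s mode, radius %.1f px\n", x$mode, x$radius_px))
  invisible(x)
}

#' Export assigned fixations as a tidy table
#'
#' @param scores a [score_gaze()] result.
#' @return data.frame with observer, image, onset, duration and
#'   semicolon-joined labels per retained fixation.
#' @export
assigned_fixation_table <- function(scores) {
  stopifnot(inherits(scores, "gaze_scores"))
  labs <- apply(scores$labmat, 1L, function(r)
    paste(scores$vocabulary[r], collapse = ";"))
  data.frame(observer_id = scores$observers[scores$fix$obs],
              image_id = scores$image_ids[scores$fix$img],
              onset_ms = scores$fix$onset_ms,
              effective_duration_ms = scores$fix$duration_ms,
              labels = labs,
              stringsAsFactors = FALSE)
}
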