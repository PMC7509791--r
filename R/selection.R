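# Greedy forward selection of stimulus subsets that preserve the predictive
# validity of individual-difference estimates, and validity-curve evaluation.

# objective: mean Fisher-z (|r| capped, see fisher_z) of per-dimension
# correlations between prefix-based and full-set-based estimates; or the
# minimum r across dimensions. A dimension with an undefined correlation
# (no variance or no data in the prefix) carries zero validity — dropping it
# from the mean would reward prefixes that miss a dimension entirely.
selection_objective <- function(est, full, objective = "mean_z", z_cap = 0.99) {
  r <- vapply(seq_len(ncol(full)), function(d)
    safe_cor(est[, d], full[, d]), numeric(1))
  if (all(is.na(r))) return(NA_real_)
  r[is.na(r)] <- 0
  switch(objective,
         mean_z = mean(fisher_z(r, cap = z_cap)),
         min_r = min(r),
         abort(sprintf("unknown objective: %s", objective)))
}

#' Greedy forward selection of an image ordering
#'
#' Orders images so that each prefix maximises the congruence of
#' individual-difference estimates based on the prefix with estimates based on
#' the full image set (computed on the same training data, mirroring a
#' selection run on an existing dataset). At each step the unchosen image
#' maximising the objective of the extended prefix is added; ties are broken
#' towards the lexicographically lowest image id.
#'
#' The default objective is the unweighted mean, over dimensions, of
#' Fisher-z-transformed Pearson correlations (with |r| capped at `z_cap`
#' before the transform, since z diverges as prefixes approach the full set);
#' `objective = "min_r"` maximises the weakest dimension instead.
#'
#' Below `min_prefix` images a correlation objective is unstable. When the
#' image set has at most `exhaustive_limit` images the first `min_prefix`
#' images are seeded by exhaustive search over all triples; otherwise the seed
#' is greedy from the single image with the highest objective (heuristic,
#' recorded in the result's `init_method`).
#'
#' @param scores a [score_gaze()] result (training data covering the full set).
#' @param dims dimensions optimised; default the tested dwell dimensions.
#' @param kind measure kind used by the objective (default `"dwell"`).
#' @param target_size length of the ordering to produce.
#' @param objective `"mean_z"` or `"min_r"`.
#' @param min_prefix smallest prefix scored by the objective (default 3).
#' @param exhaustive_limit maximum set size for exhaustive triple seeding.
#' @param z_cap cap on |r| before the Fisher transform.
#' @param cutoff_ms optional truncation applied to the training data.
#' @return an object of class `selection_result` with `ordering` (image ids),
#'   `objective_trace` (objective at each prefix size) and metadata.
#' @export
greedy_select <- function(scores, dims = NULL, kind = "dwell",
                          target_size = NULL, objective = "mean_z",
                          min_prefix = 3L, exhaustive_limit = 50L,
                          z_cap = 0.99, cutoff_ms = NULL) {
  stopifnot(inherits(scores, "gaze_scores"))
  comp <- gaze_components(scores, dims, kind, cutoff_ms)
  ids <- comp$image_ids
  n <- length(ids)
  if (is.null(target_size)) target_size <- n
  if (target_size < min_prefix)
    abort(sprintf("target_size (%d) must be at least min_prefix (%d)",
                  target_size, min_prefix))
  if (target_size > n) abort("target_size exceeds the image set")
  dims <- names(comp$numer)
  full <- components_matrix(comp, ids)[, dims, drop = FALSE]

  num <- lapply(comp$numer, identity)  # n_obs x n_img
  den <- comp$denom
  is_expl <- comp$kind == "exploration"
  prefix_est <- function(cols) {
    d <- rowSums(den[, cols, drop = FALSE])
    e <- vapply(num, function(m) rowSums(m[, cols, drop = FALSE]),
                numeric(comp$n_obs))
    if (!is_expl) { e <- e / d; e[d == 0, ] <- NA_real_ }
    e
  }
  obj_of <- function(cols)
    selection_objective(prefix_est(cols), full, objective, z_cap)
  # incremental evaluation: objective of prefix + one candidate image, from
  # running numerator/denominator sums (keeps the greedy loop linear)
  obj_add <- function(run_num, run_den, j) {
    d <- run_den + den[, j]
    e <- vapply(seq_along(num), function(i) run_num[, i] + num[[i]][, j],
                numeric(comp$n_obs))
    if (!is_expl) { e <- e / d; e[d == 0, ] <- NA_real_ }
    selection_objective(e, full, objective, z_cap)
  }

  # candidate order = lexicographic image id, so which.max breaks ties low
  cand_order <- order(ids)

  chosen <- integer(0)
  trace <- numeric(0)
  init_method <- NA_character_

  if (n <= exhaustive_limit && min_prefix == 3L) {
    init_method <- "exhaustive_triples"
    trip <- utils::combn(cand_order, 3L)
    vals <- apply(trip, 2L, obj_of)
    best <- trip[, which.max(vals)]
    # order within the triple by single-image objective, ties by id
    single <- vapply(best, function(j) obj_of(j), numeric(1))
    best <- best[order(-single, ids[best])]
    chosen <- best
    trace <- c(obj_of(chosen[1]), obj_of(chosen[1:2]), vals[which.max(vals)])
  } else {
    init_method <- "best_single_then_greedy"
    single <- vapply(cand_order, function(j) obj_of(j), numeric(1))
    chosen <- cand_order[which.max(single)]
    trace <- max(single, na.rm = TRUE)
  }

  run_num <- vapply(num, function(m) rowSums(m[, chosen, drop = FALSE]),
                    numeric(comp$n_obs))
  run_den <- rowSums(den[, chosen, drop = FALSE])
  while (length(chosen) < target_size) {
    rest <- setdiff(cand_order, chosen)
    vals <- vapply(rest, function(j) obj_add(run_num, run_den, j), numeric(1))
    pick <- rest[which.max(vals)]
    chosen <- c(chosen, pick)
    trace <- c(trace, max(vals, na.rm = TRUE))
    run_num <- run_num + vapply(num, function(m) m[, pick], numeric(comp$n_obs))
    run_den <- run_den + den[, pick]
  }

  structure(list(ordering = ids[chosen],
                 objective_trace = trace,
                 objective = objective, dims = dims, kind = comp$kind,
                 init_method = init_method, z_cap = z_cap,
                 n_images_total = n),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d images, objective %s over {%s}\n",
              length(x$ordering), x$n_images_total, x$objective,
              paste(x$dims, collapse = ", ")))
  cat(sprintf("  init: %s | final objective: %.3f\n",
              x$init_method, x$objective_trace[length(x$objective_trace)]))
  cat("  first images:", paste(utils::head(x$ordering, 10), collapse = ", "), "\n")
  invisible(x)
}

#' Validity curve of an image ordering
#'
#' For each prefix size, correlates (per dimension, across observers) the
#' estimates computed from the first `s` images of `ordering` on an
#' independent evaluation dataset with a full-set reference matrix from
#' another session, and marks crossings of the validity threshold.
#'
#' @param ordering character vector of image ids (a [greedy_select()]
#'   ordering, or any ordering to evaluate).
#' @param eval_scores a [score_gaze()] result for the evaluation session; must
#'   contain every image of the ordering.
#' @param full_reference a `salience_matrix` from the reference session.
#' @param sizes prefix sizes to evaluate.
#' @param kind measure kind for the evaluation estimates (defaults to the
#'   reference matrix's kind).
#' @param threshold validity threshold (default 0.7).
#' @param cutoff_ms optional truncation of the evaluation data.
#' @return data.frame of class `validity_curve`: `dimension`, `size`, `r`,
#'   `above_threshold`.
#' @export
evaluate_ordering <- function(ordering, eval_scores, full_reference,
                              sizes = NULL, kind = NULL, threshold = 0.7,
                              cutoff_ms = NULL) {
  stopifnot(inherits(eval_scores, "gaze_scores"),
            inherits(full_reference, "salience_matrix"))
  ordering <- as.character(ordering)
  missing_img <- setdiff(ordering, eval_scores$image_ids)
  if (length(missing_img))
    abort(sprintf("ordering image(s) absent from the evaluation data: %s",
                  paste(missing_img, collapse = ", ")))
  kind <- kind %||% attr(full_reference, "kind")
  dims <- colnames(full_reference)
  if (is.null(sizes)) sizes <- seq(min(10L, length(ordering)), length(ordering))
  if (any(sizes < 1L) || any(sizes > length(ordering)))
    abort("sizes must lie within the ordering length")
  comp <- gaze_components(eval_scores,
                          dims = if (kind == "exploration") NULL else dims,
                          kind = kind, cutoff_ms = cutoff_ms)
  obs <- intersect(rownames(full_reference), comp$observers)
  out <- lapply(sizes, function(s) {
    m <- components_matrix(comp, ordering[seq_len(s)])
    r <- vapply(dims, function(d)
      safe_cor(m[obs, d], full_reference[obs, d]), numeric(1))
    data.frame(dimension = dims, size = s, r = r, row.names = NULL)
  })
  res <- do.call(rbind, out)
  res$above_threshold <- !is.na(res$r) & res$r >= threshold
  class(res) <- c("validity_curve", "data.frame")
  attr(res, "threshold") <- threshold
  attr(res, "kind") <- kind
  res
}

#' @export
plot.validity_curve <- function(x, ...) {
  dims <- unique(x$dimension)
  cols <- grDevices::hcl.colors(max(3, length(dims)), "Dark 2")[seq_along(dims)]
  graphics::plot(range(x$size), c(0, 1), type = "n", xlab = "set size",
                 ylab = "validity r", main = "Subset validity", ...)
  for (i in seq_along(dims)) {
    xi <- x[x$dimension == dims[i], ]
    graphics::lines(xi$size, xi$r, col = cols[i], lwd = 2)
  }
  graphics::abline(h = attr(x, "threshold") %||% 0.7, lty = 2, col = "red")
  graphics::legend("bottomright", legend = dims, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Export nested stimulus subsets from a selection result
#'
#' Prefixes of the greedy ordering are nested by construction, so the exported
#' subsets satisfy e.g. `set40` being contained in `set100`.
#'
#' @param result a [greedy_select()] result.
#' @param sizes subset sizes (duplicates are collapsed with a warning).
#' @return named list of image-id vectors (`set<k>`).
#' @export
export_subsets <- function(result, sizes = c(40, 100, 200)) {
  stopifnot(inherits(result, "selection_result"))
  if (any(sizes < 1))
    abort("subset sizes must be positive")
  if (any(sizes > length(result$ordering)))
    abort(sprintf("subset size %d exceeds the ordering length (%d)",
                  max(sizes), length(result$ordering)))
  if (anyDuplicated(sizes)) {
    warning("duplicate subset sizes collapsed", call. = FALSE)
    sizes <- unique(sizes)
  }
  out <- lapply(sizes, function(s) result$ordering[seq_len(s)])
  names(out) <- paste0("set", sizes)
  out
}
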