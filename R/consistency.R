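# Reliability and validity analyses: split-half consistency over random image
# splits, descriptive ranges and max/min ratios, cross-set validity,
# truncation curves, and explainable variance.

#' Spearman-Brown step-up formula
#'
#' Reliability of an aggregate of `k` parallel items given single-item
#' reliability `lambda`: `k * lambda / (1 + (k - 1) * lambda)`.
#'
#' @param lambda single-item reliability in `[0, 1]`.
#' @param k number of aggregated items.
#' @return predicted aggregate reliability.
#' @export
spearman_brown <- function(lambda, k) {
  k * lambda / (1 + (k - 1) * lambda)
}

# inverse: single-item reliability achieving aggregate reliability r at k items
spearman_brown_inverse <- function(r, k) {
  r / (k - r * (k - 1))
}

#' Split-half consistency over random image splits
#'
#' Partitions the image set into two halves (uniformly at random per split;
#' for an odd count the halves differ by one image), computes the salience
#' matrix on each half, and Pearson-correlates the two half-estimates per
#' dimension across observers. Reports the full distribution over splits, the
#' median r and a two-sided p for the median (t transform, df = observers - 2)
#' Bonferroni-multiplied by the number of tested dimensions and capped at 1.
#'
#' `mode = "parity"` instead uses the single deterministic odd/even-numbered
#' image split.
#'
#' @param x a [score_gaze()] result, or a builder `function(image_ids)`
#'   returning a salience matrix (used with `image_ids`).
#' @param dims dimensions to test; the Bonferroni factor is `length(dims)`.
#' @param kind `"dwell"`, `"first_fix"` or `"exploration"`.
#' @param n_splits number of random splits (ignored for `"parity"`).
#' @param seed RNG seed for the splits.
#' @param mode `"random"` or `"parity"` (odd/even image numbers).
#' @param images image subset (default: all).
#' @param cutoff_ms optional truncation cutoff (ms).
#' @param image_ids image ids when `x` is a builder function.
#' @param strict_first see [salience_matrix()].
#' @return an object of class `consistency_result`: a data.frame with one row
#'   per dimension (`median_r`, `p_raw`, `p_adjusted`, `n_splits`,
#'   `n_observers`, `n_missing_splits`) and attribute `r_distribution`
#'   (splits x dimensions matrix).
#' @export
split_half <- function(x, dims = NULL, kind = "dwell", n_splits = 1000,
                       seed = 1L, mode = c("random", "parity"),
                       images = NULL, cutoff_ms = NULL, image_ids = NULL,
                       strict_first = FALSE) {
  mode <- match.arg(mode)
  if (n_splits < 1) abort("n_splits must be >= 1")
  if (is.function(x)) {
    if (is.null(image_ids)) abort("image_ids is required when x is a builder function")
    builder <- x
    ids <- as.character(image_ids)
    probe <- builder(ids)
    dims <- dims %||% colnames(probe)
    n_obs <- nrow(probe)
    half_fun <- function(half_ids) builder(half_ids)[, dims, drop = FALSE]
  } else {
    stopifnot(inherits(x, "gaze_scores"))
    if (identical(kind, "exploration")) dims <- "exploration"
    comp <- gaze_components(x, dims, kind, cutoff_ms, strict_first)
    dims <- names(comp$numer)
    ids <- if (is.null(images)) x$image_ids else as.character(images)
    n_obs <- comp$n_obs
    half_fun <- function(half_ids)
      components_matrix(comp, half_ids)[, dims, drop = FALSE]
  }
  n_img <- length(ids)
  if (n_img < 4L) abort("need at least 4 images for split-half analysis")
  if (n_obs < 3L) abort("need at least 3 observers")

  splits <- if (mode == "parity") {
    list(seq_len(n_img) %% 2L == 1L)
  } else {
    with_seed(seed, lapply(seq_len(n_splits), function(i) {
      h <- sample.int(n_img, n_img %/% 2L)
      seq_len(n_img) %in% h
    }))
  }
  rmat <- matrix(NA_real_, length(splits), length(dims),
                 dimnames = list(NULL, dims))
  for (s in seq_along(splits)) {
    a <- half_fun(ids[splits[[s]]])
    b <- half_fun(ids[!splits[[s]]])
    for (d in seq_along(dims)) rmat[s, d] <- safe_cor(a[, d], b[, d])
  }
  med <- apply(rmat, 2L, stats::median, na.rm = TRUE)
  p_raw <- vapply(med, cor_p_value, numeric(1), n = n_obs)
  res <- data.frame(dimension = dims,
                    median_r = med,
                    p_raw = p_raw,
                    p_adjusted = pmin(1, p_raw * length(dims)),
                    n_splits = length(splits),
                    n_observers = n_obs,
                    n_missing_splits = colSums(is.na(rmat)),
                    row.names = NULL)
  structure(res, class = c("consistency_result", "data.frame"),
            r_distribution = rmat, mode = mode, kind = kind,
            cutoff_ms = cutoff_ms, seed = seed)
}

#' @export
print.consistency_result <- function(x, digits = 3, ...) {
  cat(sprintf("<consistency_result> %s, %s split(s)%s\n",
              attr(x, "kind") %||% "?",
              x$n_splits[1],
              if (!is.null(attr(x, "cutoff_ms")))
                sprintf(", cutoff %g ms", attr(x, "cutoff_ms")) else ""))
  df <- as.data.frame(x)
  df$median_r <- round(df$median_r, digits)
  df$p_adjusted <- signif(df$p_adjusted, 2)
  print.data.frame(df[c("dimension", "median_r", "p_adjusted",
                        "n_splits", "n_observers")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.consistency_result <- function(x, ...) {
  rmat <- attr(x, "r_distribution")
  graphics::boxplot(as.data.frame(rmat), ylab = "split-half r",
                    main = "Split-half consistency", las = 2, ...)
  graphics::points(seq_len(ncol(rmat)), x$median_r, pch = 19, col = "red")
  invisible(x)
}

#' Range and max/min ratio of individual estimates
#'
#' Descriptive spread of per-observer proportions for one dimension, reported
#' in percent, with the maximum/minimum ratio (the orientation printed in
#' test-shortening studies: all ratios >= 1). A minimum of zero yields an
#' infinite ratio with a warning.
#'
#' @param values per-observer proportions (or counts).
#' @param as_percent multiply proportions by 100 before reporting.
#' @return list with `min_pct`, `max_pct`, `maxmin_ratio`, `n`.
#' @export
range_and_ratio <- function(values, as_percent = TRUE) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) abort("need at least 2 observers")
  scl <- if (as_percent) 100 else 1
  mn <- min(values) * scl; mx <- max(values) * scl
  ratio <- if (mn > 0) mx / mn else {
    warning("minimum is zero; max/min ratio is infinite", call. = FALSE)
    Inf
  }
  list(min_pct = mn, max_pct = mx, maxmin_ratio = ratio, n = length(values))
}

#' Cross-set validity correlation
#'
#' Pearson correlation, per dimension, between two salience matrices (for
#' example a subset estimate from one session against the full-set estimate
#' from another). Observers are joined by id; missing values are deleted
#' pairwise; the comparison is symmetric in its arguments.
#'
#' @param full,subset `salience_matrix` objects sharing dimensions.
#' @param threshold validity threshold to flag (default 0.7).
#' @return data.frame with `dimension`, `r`, `p`, `n`, `reaches_threshold`.
#' @export
cross_set_validity <- function(full, subset, threshold = 0.7) {
  dims <- intersect(colnames(full), colnames(subset))
  if (!length(dims)) abort("no shared dimensions")
  obs <- intersect(rownames(full), rownames(subset))
  if (length(obs) < 3L) abort("need at least 3 paired observers")
  f <- full[obs, dims, drop = FALSE]
  s <- subset[obs, dims, drop = FALSE]
  r <- vapply(dims, function(d) safe_cor(f[, d], s[, d]), numeric(1))
  n <- vapply(dims, function(d)
    sum(is.finite(f[, d]) & is.finite(s[, d])), numeric(1))
  data.frame(dimension = dims, r = r,
             p = mapply(cor_p_value, r, n),
             n = as.integer(n),
             reaches_threshold = !is.na(r) & r >= threshold,
             row.names = NULL)
}

#' Consistency of truncated estimates with the full trial duration
#'
#' For each truncation cutoff, correlates (per dimension, across observers)
#' the salience estimates computed from trials clipped at the cutoff with the
#' estimates from the full trial duration.
#'
#' @param scores a [score_gaze()] result.
#' @param dims dimensions (default: tested dwell dimensions).
#' @param cutoffs_ms ascending truncation cutoffs in ms.
#' @param kind measure kind.
#' @param images optional image subset.
#' @return data.frame of class `truncation_curve` with `cutoff_ms`,
#'   `dimension`, `r`, `n`.
#' @export
truncation_consistency <- function(scores, dims = NULL,
                                   cutoffs_ms = seq(100, 3000, by = 100),
                                   kind = "dwell", images = NULL) {
  stopifnot(inherits(scores, "gaze_scores"))
  if (is.unsorted(cutoffs_ms)) abort("cutoffs_ms must be ascending")
  full <- salience_matrix(scores, dims, kind, images = images)
  dims_used <- colnames(full)
  out <- lapply(cutoffs_ms, function(cut) {
    m <- salience_matrix(scores, dims, kind, images = images, cutoff_ms = cut)
    data.frame(cutoff_ms = cut, dimension = dims_used,
               r = vapply(dims_used, function(d)
                 safe_cor(full[, d], m[, d]), numeric(1)),
               n = vapply(dims_used, function(d)
                 sum(is.finite(full[, d]) & is.finite(m[, d])), numeric(1)),
               row.names = NULL)
  })
  res <- do.call(rbind, out)
  if (all(is.na(res$r[res$cutoff_ms == cutoffs_ms[1]])))
    attr(res, "flagged") <- "all values missing at the smallest cutoff"
  class(res) <- c("truncation_curve", "data.frame")
  res
}

#' Split-half consistency at each truncation cutoff
#'
#' Runs [split_half()] on trial data clipped at each cutoff. The default
#' split mode is the deterministic odd/even image split (`"parity"`).
#'
#' @inheritParams truncation_consistency
#' @param n_splits,seed,mode passed to [split_half()].
#' @return data.frame: one [split_half()] summary row per cutoff x dimension.
#' @export
truncated_split_half <- function(scores, dims = NULL,
                                 cutoffs_ms = seq(100, 3000, by = 100),
                                 kind = "dwell", n_splits = 1000, seed = 1L,
                                 mode = "parity", images = NULL) {
  stopifnot(inherits(scores, "gaze_scores"))
  out <- lapply(cutoffs_ms, function(cut) {
    ch <- split_half(scores, dims = dims, kind = kind, n_splits = n_splits,
                     seed = seed, mode = mode, images = images,
                     cutoff_ms = cut)
    cbind(cutoff_ms = cut, as.data.frame(ch))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Proportion of explainable variance
#'
#' Share of the noise-ceiling-limited (explainable) variance that a subset
#' estimate captures. On the default `"r2"` scale this is
#' `r_subset^2 / r_ceiling^2`; `mode = "r"` returns the plain ratio of
#' correlations. Values above 1 (subset beats the ceiling estimate, possible
#' by sampling error) are returned with a warning.
#'
#' @param r_subset validity correlation of the subset estimate.
#' @param r_ceiling noise-ceiling correlation (e.g. full-set retest r).
#' @param mode `"r2"` or `"r"`.
#' @return proportion (>= 0).
#' @export
explainable_variance <- function(r_subset, r_ceiling, mode = c("r2", "r")) {
  mode <- match.arg(mode)
  if (!is.numeric(r_ceiling) || any(r_ceiling == 0))
    abort("r_ceiling must be nonzero")
  out <- if (mode == "r2") r_subset^2 / r_ceiling^2 else r_subset / r_ceiling
  if (any(out > 1, na.rm = TRUE))
    warning("subset correlation exceeds the noise ceiling (ratio > 1)",
            call. = FALSE)
  pmax(out, 0)
}
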