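# Per-observer salience estimates: dwell-time proportions, first-fixation
# proportions, and visual-exploration counts.
#
# Internally everything is reduced to per-(observer, image) numerators and
# denominators ("components"): a salience matrix over any image subset or
# truncation cutoff is then a column-sum ratio, which makes 1000-split
# reliability analyses cheap.

# ---- component builders ---------------------------------------------------

# effective durations under a cutoff; drops fixations starting at/after it
truncate_fix_frame <- function(fix, cutoff_ms) {
  if (is.null(cutoff_ms) || !is.finite(cutoff_ms)) return(fix)
  keep <- fix$onset_ms < cutoff_ms
  fix <- fix[keep, , drop = FALSE]
  fix$duration_ms <- pmin(fix$duration_ms, cutoff_ms - fix$onset_ms)
  fix
}

# dwell: numer[[d]] and denom are n_obs x n_img matrices of summed durations
dwell_components <- function(scores, dims, cutoff_ms = NULL) {
  n_obs <- length(scores$observers); n_img <- length(scores$image_ids)
  keep <- if (is.null(cutoff_ms)) rep(TRUE, nrow(scores$fix))
          else scores$fix$onset_ms < cutoff_ms
  fix <- scores$fix[keep, , drop = FALSE]
  dur <- fix$duration_ms
  if (!is.null(cutoff_ms)) dur <- pmin(dur, cutoff_ms - fix$onset_ms)
  lab <- scores$labmat[keep, , drop = FALSE]
  cell <- (fix$img - 1L) * n_obs + fix$obs
  denom <- matrix(0, n_obs, n_img)
  if (length(cell)) {
    agg <- rowsum(dur, cell)
    denom[as.integer(rownames(agg))] <- agg
  }
  numer <- lapply(dims, function(d) {
    m <- matrix(0, n_obs, n_img)
    w <- dur * lab[, d]
    nz <- w > 0
    if (any(nz)) {
      agg <- rowsum(w[nz], cell[nz])
      m[as.integer(rownames(agg))] <- agg
    }
    m
  })
  names(numer) <- dims
  list(numer = numer, denom = denom, n_obs = n_obs, n_img = n_img,
       observers = scores$observers, image_ids = scores$image_ids,
       kind = "dwell", cutoff_ms = cutoff_ms)
}

# first fixation: numer binary per trial/dim, denom 1 where a valid first
# fixation exists. strict = drop trials whose literal first fixation was
# excluded by the filters.
firstfix_components <- function(scores, dims, cutoff_ms = NULL,
                                strict_first = FALSE) {
  n_obs <- length(scores$observers); n_img <- length(scores$image_ids)
  keep <- if (is.null(cutoff_ms)) rep(TRUE, nrow(scores$fix))
          else scores$fix$onset_ms < cutoff_ms
  fix <- scores$fix[keep, , drop = FALSE]
  lab <- scores$labmat[keep, , drop = FALSE]
  cell <- (fix$img - 1L) * n_obs + fix$obs
  ord <- order(cell, fix$onset_ms)
  first <- ord[!duplicated(cell[ord])]
  if (strict_first) first <- first[fix$trial_first[first]]
  denom <- matrix(0, n_obs, n_img)
  denom[cell[first]] <- 1
  numer <- lapply(dims, function(d) {
    m <- matrix(0, n_obs, n_img)
    m[cell[first]] <- as.numeric(lab[first, d])
    m
  })
  names(numer) <- dims
  list(numer = numer, denom = denom, n_obs = n_obs, n_img = n_img,
       observers = scores$observers, image_ids = scores$image_ids,
       kind = "first_fix", cutoff_ms = cutoff_ms)
}

# exploration: counts of distinct objects fixated per (observer, image);
# additive over images because objects belong to single images.
exploration_components <- function(scores, cutoff_ms = NULL) {
  n_obs <- length(scores$observers); n_img <- length(scores$image_ids)
  h <- scores$hits
  if (!is.null(cutoff_ms)) h <- h[h$onset_ms < cutoff_ms, , drop = FALSE]
  key <- paste(h$obs, h$obj)   # obj indices are image-specific
  h <- h[!duplicated(key), , drop = FALSE]
  denom <- matrix(0, n_obs, n_img)
  cnt <- matrix(0, n_obs, n_img)
  if (nrow(h)) {
    cell <- (h$img - 1L) * n_obs + h$obs
    agg <- rowsum(rep(1, nrow(h)), cell)
    cnt[as.integer(rownames(agg))] <- agg
  }
  denom[] <- 1  # counts, not proportions
  list(numer = list(exploration = cnt), denom = denom,
       n_obs = n_obs, n_img = n_img,
       observers = scores$observers, image_ids = scores$image_ids,
       kind = "exploration", cutoff_ms = cutoff_ms)
}

gaze_components <- function(scores, dims = NULL,
                            kind = c("dwell", "first_fix", "exploration"),
                            cutoff_ms = NULL, strict_first = FALSE) {
  stopifnot(inherits(scores, "gaze_scores"))
  kind <- match.arg(kind)
  if (is.null(dims)) dims <- tested_dims(if (kind == "first_fix") "first_fix" else "dwell")
  if (kind != "exploration") {
    bad <- setdiff(dims, scores$vocabulary)
    if (length(bad))
      abort(sprintf("dimension(s) not in the catalog label vocabulary: %s (available: %s)",
                    paste(bad, collapse = ", "),
                    paste(scores$vocabulary, collapse = ", ")))
  }
  switch(kind,
         dwell = dwell_components(scores, dims, cutoff_ms),
         first_fix = firstfix_components(scores, dims, cutoff_ms, strict_first),
         exploration = exploration_components(scores, cutoff_ms))
}

# matrix over an image subset from components; NA where denominator is 0
components_matrix <- function(comp, images = NULL) {
  cols <- if (is.null(images)) seq_len(comp$n_img)
          else match(images, comp$image_ids)
  if (anyNA(cols)) abort("unknown image id in subset")
  if (!length(cols)) abort("image subset is empty")
  den <- rowSums(comp$denom[, cols, drop = FALSE])
  vals <- vapply(comp$numer, function(m)
    rowSums(m[, cols, drop = FALSE]), numeric(comp$n_obs))
  if (comp$n_obs == 1L) vals <- matrix(vals, nrow = 1L,
                                       dimnames = list(NULL, names(comp$numer)))
  if (comp$kind != "exploration") {
    vals <- vals / den
    vals[den == 0, ] <- NA_real_
  }
  rownames(vals) <- comp$observers
  structure(vals, class = c("salience_matrix", class(vals)),
            kind = comp$kind,
            image_set = comp$image_ids[cols],
            cutoff_ms = comp$cutoff_ms)
}

# ---- public surface -------------------------------------------------------

#' Per-observer salience matrix
#'
#' Builds the observer-by-dimension matrix of fixation proportions for a given
#' measure, image subset and optional trial truncation.
#'
#' * `kind = "dwell"`: proportion of cumulative dwell time on objects carrying
#'   each label, out of all label-assigned dwell time. Labels overlap, so row
#'   sums may exceed 1; each cell is in `[0, 1]`.
#' * `kind = "first_fix"`: proportion of trials whose first retained,
#'   label-assigned fixation carries each label, out of trials with a valid
#'   first fixation.
#' * `kind = "exploration"`: number of distinct objects fixated (a count).
#'
#' Observers with no valid data on the subset get `NA` (missing is never
#' imputed as zero).
#'
#' @param scores a [score_gaze()] result.
#' @param dims labels to score; defaults to the tested dimensions for `kind`.
#' @param kind `"dwell"`, `"first_fix"` or `"exploration"`.
#' @param images image-id subset; default full set.
#' @param cutoff_ms optional truncation cutoff (ms); fixations are clipped as
#'   in [truncate_fixations()].
#' @param strict_first for `"first_fix"`: drop trials whose literal first
#'   fixation was removed by the onset/duration filters instead of falling
#'   back to the next surviving fixation.
#' @return a numeric matrix of class `salience_matrix` with observers as row
#'   names and attributes `kind`, `image_set`, `cutoff_ms`.
#' @export
salience_matrix <- function(scores, dims = NULL,
                            kind = c("dwell", "first_fix", "exploration"),
                            images = NULL, cutoff_ms = NULL,
                            strict_first = FALSE) {
  kind <- match.arg(kind)
  comp <- gaze_components(scores, dims, kind, cutoff_ms, strict_first)
  components_matrix(comp, images)
}

#' @export
print.salience_matrix <- function(x, ...) {
  cat(sprintf("<salience_matrix> %s: %d observers x %d dimension(s)%s\n",
              attr(x, "kind"), nrow(x), ncol(x),
              if (!is.null(attr(x, "cutoff_ms")))
                sprintf(", truncated at %g ms", attr(x, "cutoff_ms")) else ""))
  cat(sprintf("  images: %d | per-dimension mean: %s\n",
              length(attr(x, "image_set")),
              paste(sprintf("%s=%.3f", colnames(x),
                            colMeans(x, na.rm = TRUE)), collapse = ", ")))
  invisible(x)
}

#' Dwell-time proportions for one observer
#'
#' @param scores a [score_gaze()] result.
#' @param observer observer id.
#' @param dims labels; defaults to the tested dwell dimensions.
#' @param images,cutoff_ms as in [salience_matrix()].
#' @return named numeric vector of proportions (`NA` when the observer has no
#'   assigned fixations on the subset).
#' @export
dwell_proportions <- function(scores, observer, dims = tested_dims("dwell"),
                              images = NULL, cutoff_ms = NULL) {
  m <- salience_matrix(scores, dims, "dwell", images, cutoff_ms)
  if (!observer %in% rownames(m)) abort(sprintf("unknown observer: %s", observer))
  m[observer, ]
}

#' First-fixation proportions for one observer
#'
#' @inheritParams dwell_proportions
#' @param strict_first see [salience_matrix()].
#' @export
first_fixation_proportions <- function(scores, observer,
                                       dims = tested_dims("first_fix"),
                                       images = NULL, cutoff_ms = NULL,
                                       strict_first = FALSE) {
  m <- salience_matrix(scores, dims, "first_fix", images, cutoff_ms,
                       strict_first = strict_first)
  if (!observer %in% rownames(m)) abort(sprintf("unknown observer: %s", observer))
  m[observer, ]
}

#' Visual exploration count for one observer
#'
#' Number of distinct objects (image, object pairs) that received at least one
#' retained, object-assigned fixation.
#'
#' @inheritParams dwell_proportions
#' @return integer count.
#' @export
exploration_count <- function(scores, observer, images = NULL,
                              cutoff_ms = NULL) {
  m <- salience_matrix(scores, kind = "exploration", images = images,
                       cutoff_ms = cutoff_ms)
  if (!observer %in% rownames(m)) abort(sprintf("unknown observer: %s", observer))
  as.integer(m[observer, 1L])
}

#' Write a salience matrix with a metadata sidecar
#'
#' Writes the matrix as CSV (observers x dimensions) and a JSON sidecar with
#' the measure kind, image set, cutoff and a provenance hash.
#'
#' @param x a `salience_matrix`.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_salience_matrix <- function(x, path) {
  stopifnot(inherits(x, "salience_matrix"))
  df <- data.frame(observer_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(kind = attr(x, "kind"),
               image_set = attr(x, "image_set"),
               cutoff_ms = attr(x, "cutoff_ms"),
               hash = stable_hash(list(attr(x, "kind"), attr(x, "image_set"),
                                       attr(x, "cutoff_ms"))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
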