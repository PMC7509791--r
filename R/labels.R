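# Label preparation: overlap-resolution rules and the Faces merge.

#' Resolve label overlap between semantic dimensions
#'
#' Applies the fixed overlap-reduction rules to every object in a catalog:
#' objects carrying `Text` lose `Smell` and `Watchable`; objects carrying
#' `Touched` lose `Operable` and `Gazed`. The two rule groups are independent,
#' so application order is irrelevant; they are applied in a fixed order
#' (Text rules, then Touched rules) for deterministic audit logs. The
#' operation is idempotent, never adds a label, and never touches masks.
#'
#' @param catalog a [scene_catalog()].
#' @return the catalog with modified label sets.
#' @export
resolve_overlap <- function(catalog) {
  stopifnot(inherits(catalog, "scene_catalog"))
  catalog$objects <- lapply(catalog$objects, function(o) {
    o$labels <- resolve_overlap_labels(o$labels)
    o
  })
  catalog
}

# rule core on one label set (exported logic used by tests / enumeration)
resolve_overlap_labels <- function(labels) {
  if ("Text" %in% labels) labels <- setdiff(labels, c("Smell", "Watchable"))
  if ("Touched" %in% labels) labels <- setdiff(labels, c("Operable", "Gazed"))
  labels
}

#' Merge neutral and emotional face labels
#'
#' Replaces the raw face categories (by default `Face` and `Emotion`) with the
#' single analysis label `Faces`, reflecting the high covariance of fixation
#' tendencies towards both. The catalog's vocabulary is updated accordingly.
#'
#' @param catalog a [scene_catalog()].
#' @param face_labels raw label names to merge (configurable to absorb naming
#'   differences in deposited data).
#' @param into the merged label name.
#' @return the catalog with merged labels.
#' @export
merge_faces <- function(catalog, face_labels = c("Face", "Emotion"),
                        into = "Faces") {
  stopifnot(inherits(catalog, "scene_catalog"))
  catalog$objects <- lapply(catalog$objects, function(o) {
    if (any(face_labels %in% o$labels))
      o$labels <- unique(c(into, setdiff(o$labels, face_labels)))
    o
  })
  if (any(face_labels %in% catalog$vocabulary))
    catalog$vocabulary <- unique(c(into, setdiff(catalog$vocabulary, face_labels)))
  catalog
}

#' Prepare a raw catalog for analysis
#'
#' Convenience composition of [merge_faces()] and [resolve_overlap()]; marks
#' the catalog as analysis-ready.
#'
#' @inheritParams resolve_overlap
#' @inheritParams merge_faces
#' @return the prepared catalog.
#' @export
prepare_labels <- function(catalog, face_labels = c("Face", "Emotion"),
                           into = "Faces") {
  if (isTRUE(catalog$prepared)) return(catalog)
  catalog <- merge_faces(catalog, face_labels = face_labels, into = into)
  catalog <- resolve_overlap(catalog)
  catalog$prepared <- TRUE
  catalog
}

#' Audit label prevalence across an image subset
#'
#' Counts, for every label in the vocabulary, the number of objects carrying
#' it among the images of `image_subset` (absolute prevalence) and the share
#' of all label occurrences in the subset (relative prevalence, in percent).
#' The relative denominator is the total number of label occurrences, so
#' percentages sum to 100 across labels; an object carrying two labels counts
#' once per label. Set `dims` to restrict the occurrence denominator to a
#' subset of dimensions.
#'
#' @param catalog a [scene_catalog()].
#' @param image_subset image ids; defaults to the full catalog.
#' @param dims labels to report; defaults to the full vocabulary.
#' @return data.frame with columns `label`, `absolute`, `relative_percent`,
#'   `n_images`, `n_objects`.
#' @export
audit_prevalence <- function(catalog, image_subset = catalog$image_ids,
                             dims = catalog$vocabulary) {
  stopifnot(inherits(catalog, "scene_catalog"))
  image_subset <- as.character(image_subset)
  if (!length(image_subset)) abort("image_subset is empty")
  bad <- setdiff(image_subset, catalog$image_ids)
  if (length(bad))
    abort(sprintf("image_subset contains unknown images: %s",
                  paste(bad, collapse = ", ")))
  keep <- vapply(catalog$objects, function(o) o$image_id %in% image_subset,
                 logical(1))
  labs <- unlist(lapply(catalog$objects[keep], `[[`, "labels"))
  labs <- labs[labs %in% dims]
  total <- length(labs)
  absolute <- vapply(dims, function(d) sum(labs == d), numeric(1))
  data.frame(label = dims,
             absolute = as.integer(absolute),
             relative_percent = if (total > 0) 100 * absolute / total
                                else rep(NA_real_, length(dims)),
             n_images = length(image_subset),
             n_objects = sum(keep),
             row.names = NULL)
}
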