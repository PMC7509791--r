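# Scene catalogs: per-image labelled objects with binary pixel masks.

#' Semantic label vocabularies
#'
#' `osie_raw_labels()` returns the twelve raw semantic attributes of
#' OSIE-style object annotations. `osie_analysis_labels()` returns the label
#' space after the face merge (neutral + emotional faces combined into
#' `Faces`). `tested_dims()` returns the dimensions analysed for cumulative
#' dwell time (`"dwell"`: Faces, Text, Touched, Taste, Motion) or first
#' fixations (`"first_fix"`: Faces, Text, Touched).
#'
#' @return character vector of label names.
#' @export
osie_raw_labels <- function() {
  c("Face", "Emotion", "Touched", "Gazed", "Motion", "Sound",
    "Smell", "Taste", "Touch", "Text", "Watchable", "Operable")
}

#' @rdname osie_raw_labels
#' @export
osie_analysis_labels <- function() {
  c("Faces", setdiff(osie_raw_labels(), c("Face", "Emotion")))
}

#' @rdname osie_raw_labels
#' @param kind `"dwell"` or `"first_fix"`.
#' @export
tested_dims <- function(kind = c("dwell", "first_fix")) {
  kind <- match.arg(kind)
  if (kind == "dwell") c("Faces", "Text", "Touched", "Taste", "Motion")
  else c("Faces", "Text", "Touched")
}

#' Create a scene object
#'
#' One annotated object in one image: a binary pixel mask plus a set of
#' semantic labels.
#'
#' @param image_id,object_id character identifiers.
#' @param mask a [pixel_mask()] or a logical matrix.
#' @param labels character vector, a subset of `vocabulary`.
#' @param vocabulary allowed label names.
#' @return an object of class `scene_object`.
#' @export
scene_object <- function(image_id, object_id, mask, labels = character(),
                         vocabulary = osie_raw_labels()) {
  if (!inherits(mask, "pixel_mask")) mask <- pixel_mask(mask)
  labels <- unique(as.character(labels))
  bad <- setdiff(labels, vocabulary)
  if (length(bad))
    abort(sprintf("labels outside the declared vocabulary: %s",
                  paste(bad, collapse = ", ")))
  structure(list(image_id = as.character(image_id),
                 object_id = as.character(object_id),
                 mask = mask, labels = labels),
            class = "scene_object")
}

#' Create a scene catalog
#'
#' @param geometry a [display_geometry()]; all masks must match its pixel
#'   resolution (no silent rescaling is performed).
#' @param objects list of [scene_object()]s.
#' @param image_ids ordered image identifiers; defaults to the order of first
#'   appearance in `objects`.
#' @param vocabulary the label vocabulary in force.
#' @return an object of class `scene_catalog`.
#' @export
scene_catalog <- function(geometry, objects,
                          image_ids = NULL,
                          vocabulary = osie_raw_labels()) {
  stopifnot(inherits(geometry, "display_geometry"))
  obj_img <- vapply(objects, function(o) o$image_id, character(1))
  if (is.null(image_ids)) image_ids <- unique(obj_img)
  missing_img <- setdiff(obj_img, image_ids)
  if (length(missing_img))
    abort(sprintf("objects reference image ids absent from image_ids: %s",
                  paste(unique(missing_img), collapse = ", ")))
  for (o in objects) {
    if (o$mask$width != geometry$width_px || o$mask$height != geometry$height_px)
      abort(sprintf(
        "mask for %s/%s is %dx%d px but the geometry is %dx%d px (masks are never rescaled)",
        o$image_id, o$object_id, o$mask$width, o$mask$height,
        geometry$width_px, geometry$height_px))
  }
  ids <- paste(obj_img, vapply(objects, function(o) o$object_id, character(1)))
  if (anyDuplicated(ids))
    abort("object_ids must be unique within an image")
  structure(list(geometry = geometry, objects = objects,
                 image_ids = as.character(image_ids),
                 vocabulary = vocabulary, prepared = FALSE),
            class = "scene_catalog")
}

#' @export
print.scene_catalog <- function(x, ...) {
  cat(sprintf("<scene_catalog> %d images, %d objects, %s labels%s\n",
              length(x$image_ids), length(x$objects),
              length(x$vocabulary),
              if (isTRUE(x$prepared)) " (analysis-ready)" else " (raw)"))
  tab <- sort(table(unlist(lapply(x$objects, `[[`, "labels"))), decreasing = TRUE)
  if (length(tab))
    cat("  label counts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# objects of one image, as a list
catalog_objects_by_image <- function(catalog) {
  split(catalog$objects,
        factor(vapply(catalog$objects, `[[`, character(1), "image_id"),
               levels = catalog$image_ids))
}

# label membership matrix: objects x vocabulary
catalog_label_matrix <- function(catalog) {
  vocab <- catalog$vocabulary
  m <- matrix(FALSE, length(catalog$objects), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(catalog$objects)) {
    m[i, match(catalog$objects[[i]]$labels, vocab)] <- TRUE
  }
  m
}
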