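# Reading and writing fixation tables and scene catalogs.
#
# House formats:
#   * fixation tables: delimited text (CSV/TSV) with a header naming at least
#     observer_id, image_id, x_px, y_px, onset_ms, duration_ms (column names
#     remappable via `columns`). Onsets are relative to image onset; importers
#     of tracker-native timestamps must pre-subtract the trial onset.
#   * scene catalogs: a directory with geometry.yaml (width_px, height_px,
#     width_dva, height_dva), labels.csv (image_id, object_id, one 0/1 column
#     per label) and one grayscale PNG per object named
#     <image_id>__<object_id>.png (nonzero = object pixel).
#     Users of OSIE-style .mat mask deposits should export each object mask to
#     that PNG layout and the label table to labels.csv (conversion itself is
#     out of scope here).

fixation_fields <- c("observer_id", "image_id", "x_px", "y_px",
                     "onset_ms", "duration_ms")

#' Read a fixation table
#'
#' @param path delimited text file with a header.
#' @param columns named character vector mapping the canonical field names
#'   (`observer_id`, `image_id`, `x_px`, `y_px`, `onset_ms`, `duration_ms`)
#'   to the column names used in the file.
#' @param sep field separator; `","` for CSV, `"\t"` for TSV.
#' @return data.frame of fixations with canonical column names.
#' @export
read_fixation_table <- function(path,
                                columns = stats::setNames(fixation_fields,
                                                          fixation_fields),
                                sep = ",") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L) abort(sprintf("fixation table is empty: %s", path))
  miss <- setdiff(fixation_fields, names(columns))
  if (length(miss))
    abort(sprintf("column mapping lacks entries for: %s",
                  paste(miss, collapse = ", ")))
  for (f in fixation_fields) {
    if (!(columns[[f]] %in% names(raw)))
      abort(sprintf("missing required column `%s` (mapped to field `%s`) in %s",
                    columns[[f]], f, path))
  }
  out <- data.frame(
    observer_id = as.character(raw[[columns[["observer_id"]]]]),
    image_id = as.character(raw[[columns[["image_id"]]]]),
    stringsAsFactors = FALSE)
  for (f in c("x_px", "y_px", "onset_ms", "duration_ms")) {
    v <- suppressWarnings(as.numeric(raw[[columns[[f]]]]))
    bad <- which(is.na(v) & !(trimws(raw[[columns[[f]]]]) %in% c("NA", "")))
    if (length(bad))
      abort(sprintf("could not parse `%s` as numeric at row %d of %s (value \"%s\")",
                    columns[[f]], bad[1], path, raw[[columns[[f]]]][bad[1]]))
    if (anyNA(v))
      abort(sprintf("missing value in column `%s` at row %d of %s",
                    columns[[f]], which(is.na(v))[1], path))
    out[[f]] <- v
  }
  validate_fixations(out)
  out
}

validate_fixations <- function(fx) {
  stopifnot(is.data.frame(fx))
  miss <- setdiff(fixation_fields, names(fx))
  if (length(miss))
    abort(sprintf("fixation table lacks columns: %s", paste(miss, collapse = ", ")))
  if (any(!is.finite(fx$onset_ms)) || any(fx$onset_ms < 0))
    abort("onset_ms must be finite and >= 0 (relative to image onset)")
  if (any(!is.finite(fx$duration_ms)) || any(fx$duration_ms <= 0))
    abort("duration_ms must be finite and > 0")
  invisible(fx)
}

#' Write a fixation table
#'
#' Round-trip counterpart of [read_fixation_table()].
#'
#' @param fixations data.frame with the canonical fixation columns.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(fixations, path, sep = ",") {
  validate_fixations(fixations)
  utils::write.table(fixations[fixation_fields], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scene catalog from a directory
#'
#' Expects `geometry.yaml`, `labels.csv` and one grayscale PNG mask per object
#' (see the package README for the layout). Masks must match the geometry's
#' resolution exactly; all-zero masks and masks referenced in `labels.csv` but
#' absent on disk are errors.
#'
#' @param dir catalog directory.
#' @param vocabulary allowed label names; label columns outside it are an
#'   error.
#' @return a [scene_catalog()].
#' @export
read_scene_catalog <- function(dir, vocabulary = osie_raw_labels()) {
  geom_path <- file.path(dir, "geometry.yaml")
  lab_path <- file.path(dir, "labels.csv")
  for (p in c(geom_path, lab_path))
    if (!file.exists(p)) abort(sprintf("catalog file missing: %s", p))
  g <- yaml::read_yaml(geom_path)
  geometry <- display_geometry(g$width_px, g$height_px, g$width_dva, g$height_dva)
  lab <- utils::read.csv(lab_path, check.names = FALSE,
                         colClasses = c(image_id = "character",
                                        object_id = "character"))
  if (!all(c("image_id", "object_id") %in% names(lab)))
    abort("labels.csv must have image_id and object_id columns")
  label_cols <- setdiff(names(lab), c("image_id", "object_id"))
  bad <- setdiff(label_cols, vocabulary)
  if (length(bad))
    abort(sprintf("label columns outside the declared vocabulary: %s",
                  paste(bad, collapse = ", ")))
  objects <- vector("list", nrow(lab))
  for (i in seq_len(nrow(lab))) {
    f <- file.path(dir, sprintf("%s__%s.png", lab$image_id[i], lab$object_id[i]))
    if (!file.exists(f))
      abort(sprintf("mask file referenced in labels.csv but absent: %s", f))
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    if (!any(img > 0))
      abort(sprintf("mask is all zeros (no object pixels): %s", f))
    labs <- label_cols[as.logical(unlist(lab[i, label_cols]))]
    objects[[i]] <- scene_object(lab$image_id[i], lab$object_id[i],
                                 pixel_mask(img > 0), labs,
                                 vocabulary = vocabulary)
  }
  scene_catalog(geometry, objects, image_ids = unique(lab$image_id),
                vocabulary = vocabulary)
}

#' Write a scene catalog to a directory
#'
#' Emits the layout read by [read_scene_catalog()].
#'
#' @param catalog a [scene_catalog()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_catalog <- function(catalog, dir) {
  stopifnot(inherits(catalog, "scene_catalog"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- catalog$geometry
  yaml::write_yaml(list(width_px = g$width_px, height_px = g$height_px,
                        width_dva = g$width_dva, height_dva = g$height_dva),
                   file.path(dir, "geometry.yaml"))
  vocab <- catalog$vocabulary
  lab <- data.frame(
    image_id = vapply(catalog$objects, `[[`, character(1), "image_id"),
    object_id = vapply(catalog$objects, `[[`, character(1), "object_id"),
    stringsAsFactors = FALSE)
  lm <- catalog_label_matrix(catalog)
  for (v in vocab) lab[[v]] <- as.integer(lm[, v])
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  for (o in catalog$objects) {
    png::writePNG(as.matrix(o$mask) * 1,
                  file.path(dir, sprintf("%s__%s.png", o$image_id, o$object_id)))
  }
  invisible(dir)
}
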