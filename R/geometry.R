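#' Display geometry
#'
#' Describes the stimulus display: its pixel resolution and its extent in
#' degrees of visual angle (dva). Used to convert angular thresholds (such as
#' the 0.5 dva fixation-assignment radius) into pixels.
#'
#' Wide-screen set-ups are often anisotropic (horizontal and vertical
#' pixels-per-degree differ); a warning is raised above a 50% discrepancy and
#' an error beyond a factor of two, which would indicate implausible numbers.
#'
#' @param width_px,height_px display resolution in pixels.
#' @param width_dva,height_dva display extent in degrees of visual angle.
#' @return an object of class `display_geometry`.
#' @examples
#' geom <- display_geometry(1920, 1080, 29.0, 22.2)
#' dva_to_px(geom, 0.5)
#' @export
display_geometry <- function(width_px, height_px, width_dva, height_dva) {
  check_number(width_px, "width_px", lower = 1)
  check_number(height_px, "height_px", lower = 1)
  check_number(width_dva, "width_dva", lower = 1e-9)
  check_number(height_dva, "height_dva", lower = 1e-9)
  ppd_h <- width_px / width_dva
  ppd_v <- height_px / height_dva
  ratio <- max(ppd_h, ppd_v) / min(ppd_h, ppd_v)
  if (ratio > 2)
    abort(sprintf(
      "horizontal and vertical pixels-per-degree differ by a factor %.2f (> 2); geometry looks implausible",
      ratio))
  if (ratio > 1.5)
    warning(sprintf("pixels-per-degree are strongly anisotropic (%.1f vs %.1f px/deg)",
                    ppd_h, ppd_v), call. = FALSE)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         width_dva = width_dva, height_dva = height_dva),
    class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("<display_geometry> %d x %d px, %.1f x %.1f dva (%.1f px/deg mean)\n",
              x$width_px, x$height_px, x$width_dva, x$height_dva,
              mean(c(x$width_px / x$width_dva, x$height_px / x$height_dva))))
  invisible(x)
}

#' Convert degrees of visual angle to pixels
#'
#' Uses the mean of the horizontal and vertical pixels-per-degree, giving a
#' symmetric treatment of radial thresholds on anisotropic displays.
#'
#' @param geometry a [display_geometry()].
#' @param dva non-negative angle in degrees of visual angle.
#' @return distance in pixels.
#' @export
dva_to_px <- function(geometry, dva) {
  stopifnot(inherits(geometry, "display_geometry"))
  if (!is.numeric(dva) || any(!is.finite(dva)) || any(dva < 0))
    abort("`dva` must be non-negative and finite")
  ppd <- mean(c(geometry$width_px / geometry$width_dva,
                geometry$height_px / geometry$height_dva))
  dva * ppd
}
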