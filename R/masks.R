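# Binary pixel masks.
#
# Coordinate convention used throughout the package: pixel (x, y) is 0-based,
# origin at the top-left, x growing rightwards (columns) and y downwards
# (rows); the centre of pixel (x, y) sits at continuous coordinates (x, y).
# A real-valued position is "inside" a mask when the nearest pixel
# (round(x), round(y)) is a true mask pixel.
#
# Masks are stored compactly: the logical submatrix restricted to the tight
# bounding box, plus the coordinates of the boundary pixels (true pixels with
# a false 4-neighbour, or on the image edge). For any point whose containing
# pixel is false, the nearest true pixel is a boundary pixel: if the nearest
# pixel had all four true in-bounds neighbours, the neighbour towards the
# point would be strictly closer (or tied on the pixel edge). Distances to a
# mask are therefore computed exactly from boundary pixels alone, and agree
# with a brute-force scan over every true pixel.

#' Create a pixel mask
#'
#' @param m logical (or 0/1 numeric) matrix; rows are pixel rows from the top,
#'   columns pixel columns from the left. Must contain at least one true pixel.
#' @return an object of class `pixel_mask`.
#' @export
pixel_mask <- function(m) {
  if (!is.matrix(m)) abort("mask must be a matrix")
  m <- m != 0
  if (!any(m)) abort("mask has no true pixels")
  rr <- range(which(rowSums(m) > 0))
  cc <- range(which(colSums(m) > 0))
  sub <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  # boundary: pad with FALSE; true pixel with any false 4-neighbour
  nr <- nrow(sub); nc <- ncol(sub)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- sub
  core <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  nb <- pad[1:nr, 2:(nc + 1L), drop = FALSE] &
        pad[3:(nr + 2L), 2:(nc + 1L), drop = FALSE] &
        pad[2:(nr + 1L), 1:nc, drop = FALSE] &
        pad[2:(nr + 1L), 3:(nc + 2L), drop = FALSE]
  bidx <- which(core & !nb, arr.ind = TRUE)
  boundary <- cbind(x = cc[1] - 2L + bidx[, 2L],   # 0-based image coords
                    y = rr[1] - 2L + bidx[, 1L])
  structure(
    list(height = nrow(m), width = ncol(m),
         x0 = cc[1] - 1L, y0 = rr[1] - 1L,  # 0-based bbox offset
         sub = sub, boundary = boundary, n_pixels = sum(m)),
    class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d x %d px, %d true pixels, bbox (%d,%d)+%dx%d\n",
              x$width, x$height, x$n_pixels, x$x0, x$y0,
              ncol(x$sub), nrow(x$sub)))
  invisible(x)
}

#' @export
as.matrix.pixel_mask <- function(x, ...) {
  m <- matrix(FALSE, x$height, x$width)
  m[x$y0 + seq_len(nrow(x$sub)), x$x0 + seq_len(ncol(x$sub))] <- x$sub
  m
}

# Vectorised containment test for 0-based real coordinates.
mask_contains <- function(mask, x, y) {
  px <- round(x); py <- round(y)
  r <- py - mask$y0 + 1; c <- px - mask$x0 + 1
  ok <- is.finite(px) & is.finite(py) &
    r >= 1 & r <= nrow(mask$sub) & c >= 1 & c <= ncol(mask$sub)
  out <- logical(length(x))
  if (any(ok)) out[ok] <- mask$sub[cbind(r[ok], c[ok])]
  out
}

# Minimum Euclidean distance from points to the mask (0 if contained).
# Exact: equals the minimum over all true pixel centres.
mask_min_dist <- function(mask, x, y) {
  out <- numeric(length(x))
  inside <- mask_contains(mask, x, y)
  todo <- which(!inside)
  if (length(todo)) {
    bx <- mask$boundary[, 1L]; by <- mask$boundary[, 2L]
    for (i in todo) {
      out[i] <- sqrt(min((x[i] - bx)^2 + (y[i] - by)^2))
    }
  }
  out
}

# Rasterisers used by the synthetic catalog generator ----------------------

rasterize_rect <- function(width, height, cx, cy, hx, hy) {
  xs <- 0:(width - 1); ys <- 0:(height - 1)
  m <- outer(abs(ys - cy) <= hy, abs(xs - cx) <= hx, `&`)
  m
}

rasterize_ellipse <- function(width, height, cx, cy, rx, ry) {
  xs <- 0:(width - 1); ys <- 0:(height - 1)
  m <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`) <= 1
  m
}
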