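#' Continuous polygon area by the shoelace formula
#'
#' `|sum(x_i * y_{i+1} - x_{i+1} * y_i)| / 2` over the implicitly closed
#' vertex list; independent of orientation. Serves as the analytic
#' reference against which pixel-count areas are validated.
#'
#' @param polygon n x 2 numeric matrix of (x, y) vertices, n >= 3.
#' @return area in px^2.
#' @export
shoelace_area <- function(polygon) {
  if (!is.matrix(polygon) || ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("degenerate polygon: shoelace_area needs an n x 2 matrix, n >= 3")
  }
  x <- polygon[, 1L]; y <- polygon[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Rasterize a ventricle polygon to a pixel mask
#'
#' Pixel membership follows the even-odd rule evaluated at pixel
#' centers (integer coordinates, 0-based, x rightward / y downward);
#' pixels whose center lies exactly on a polygon edge are included.
#' Whole pixels are counted -- no anti-aliasing or partial-pixel
#' weighting -- because downstream blood-area measurements are pixel
#' counts.
#'
#' @param polygon n x 2 numeric matrix of (x, y) vertices of a simple
#'   polygon lying within the image.
#' @param image_shape `c(height, width)` of the target raster.
#' @param frame_index optional 0-based frame index carried in the
#'   result.
#' @return an object of class `RoiMask`: list with `mask` (logical
#'   height x width matrix), `frame_index`, and `area_px` (count of
#'   `TRUE` pixels).
#' @export
rasterize_polygon <- function(polygon, image_shape, frame_index = NA_integer_) {
  image_shape <- as.integer(image_shape)
  validate_polygon(polygon, image_shape, what = "ROI polygon")
  h <- image_shape[1L]; w <- image_shape[2L]
  mask <- matrix(FALSE, nrow = h, ncol = w)

  xs <- polygon[, 1L]; ys <- polygon[, 2L]
  x0 <- max(0L, floor(min(xs))); x1 <- min(w - 1L, ceiling(max(xs)))
  y0 <- max(0L, floor(min(ys))); y1 <- min(h - 1L, ceiling(max(ys)))
  if (x0 > x1 || y0 > y1) stop("polygon covers no pixel centers")

  px <- rep(x0:x1, times = y1 - y0 + 1L)
  py <- rep(y0:y1, each = x1 - x0 + 1L)
  inside <- points_in_polygon(px, py, polygon)
  if (!any(inside)) stop("polygon covers no pixel centers")
  mask[cbind(py + 1L, px + 1L)] <- inside
  structure(list(mask = mask,
                 frame_index = as.integer(frame_index),
                 area_px = sum(inside)),
            class = "RoiMask")
}

# Vectorized even-odd test with boundary inclusion. Crossing number of
# a horizontal ray toward +x, counted per edge with the half-open rule
# (y1 > py) != (y2 > py); points lying on any edge are included
# explicitly.
points_in_polygon <- function(px, py, polygon, eps = 1e-9) {
  n <- nrow(polygon)
  xs <- polygon[, 1L]; ys <- polygon[, 2L]
  xn <- c(xs[-1L], xs[1L]); yn <- c(ys[-1L], ys[1L])
  crossings <- integer(length(px))
  on_edge <- logical(length(px))
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xn[k]; y2 <- yn[k]
    if (y1 != y2) {
      straddles <- (y1 > py) != (y2 > py)
      if (any(straddles)) {
        xint <- x1 + (py[straddles] - y1) * (x2 - x1) / (y2 - y1)
        hit <- straddles
        hit[straddles] <- px[straddles] < xint
        crossings <- crossings + hit
      }
    }
    # exact on-segment test: collinear and within the segment's span
    d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    span <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    col <- abs(d) <= eps * max(1, span) &
      px >= min(x1, x2) - eps & px <= max(x1, x2) + eps &
      py >= min(y1, y2) - eps & py <= max(y1, y2) + eps
    on_edge <- on_edge | col
  }
  (crossings %% 2L == 1L) | on_edge
}

#' @export
print.RoiMask <- function(x, ...) {
  cat("RoiMask: ", x$area_px, " px on a ",
      nrow(x$mask), "x", ncol(x$mask), " frame", sep = "")
  if (!is.na(x$frame_index)) cat(" (frame ", x$frame_index, ")", sep = "")
  cat("\n")
  invisible(x)
}
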