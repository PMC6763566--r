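#' Construct a set of ventricle ROI polygons
#'
#' A `RoiSet` stores the manually segmented ventricle outline for
#' individual frames of an image series. Coordinates are 0-based pixel
#' coordinates with x increasing rightward (columns) and y downward
#' (rows); integer coordinates denote pixel centers. Polygons are
#' implicitly closed (last vertex connects back to the first) and must
#' be simple.
#'
#' @param entries named list mapping frame index (as character, 0-based)
#'   to an n x 2 numeric matrix of (x, y) vertices, n >= 3.
#' @param image_shape optional `c(height, width)` of the image the ROI
#'   was drawn on; when given, vertices must lie within
#'   `[0, width-1] x [0, height-1]`.
#' @return an object of class `RoiSet`.
#' @export
roi_set <- function(entries, image_shape = NULL) {
  if (!is.list(entries) || length(entries) == 0L) {
    stop("a RoiSet needs at least one polygon")
  }
  if (is.null(names(entries)) || anyNA(suppressWarnings(as.integer(names(entries))))) {
    stop("entries must be named by 0-based frame index")
  }
  if (!is.null(image_shape)) {
    image_shape <- as.integer(image_shape)
    stopifnot(length(image_shape) == 2L, all(image_shape >= 1L))
  }
  for (key in names(entries)) {
    poly <- entries[[key]]
    validate_polygon(poly, image_shape,
                     what = paste0("frame ", key, " polygon"))
  }
  structure(list(entries = entries, image_shape = image_shape),
            class = "RoiSet")
}

#' Validate a ventricle outline polygon
#'
#' Checks the three structural invariants the pipeline relies on: at
#' least 3 vertices, all vertices within image bounds (when a shape is
#' known), and simplicity (no two non-adjacent edges touch or cross).
#'
#' @param poly n x 2 numeric matrix of (x, y) vertices.
#' @param image_shape optional `c(height, width)` bounds.
#' @param what label used in error messages.
#' @return `poly`, invisibly, when valid; otherwise an error.
#' @export
validate_polygon <- function(poly, image_shape = NULL, what = "polygon") {
  if (!is.matrix(poly) || ncol(poly) != 2L || !is.numeric(poly) || anyNA(poly)) {
    stop(what, " must be a numeric n x 2 matrix of (x, y) vertices")
  }
  if (nrow(poly) < 3L) {
    stop("degenerate polygon: ", what, " has ", nrow(poly),
         " vertices, need at least 3")
  }
  if (!is.null(image_shape)) {
    h <- image_shape[1L]; w <- image_shape[2L]
    bad <- which(poly[, 1L] < 0 | poly[, 1L] > w - 1 |
                 poly[, 2L] < 0 | poly[, 2L] > h - 1)
    if (length(bad) > 0L) {
      stop("out-of-bounds vertex in ", what, ": vertex ", bad[1L] - 1L,
           " at (", poly[bad[1L], 1L], ", ", poly[bad[1L], 2L],
           ") outside ", h, "x", w, " image")
    }
  }
  if (!polygon_is_simple(poly)) {
    stop("invalid polygon: ", what, " is self-intersecting")
  }
  invisible(poly)
}

# Simplicity test: no pair of non-adjacent closed-polygon edges shares a
# point. Adjacent edges legitimately share their common endpoint.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  p1 <- poly
  p2 <- poly[c(2:n, 1L), , drop = FALSE]
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_touch(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

on_segment_box <- function(p, a, b, eps) {
  p[1] >= min(a[1], b[1]) - eps && p[1] <= max(a[1], b[1]) + eps &&
  p[2] >= min(a[2], b[2]) - eps && p[2] <= max(a[2], b[2]) + eps
}

# TRUE if closed segments [a1,a2] and [b1,b2] share any point
segments_touch <- function(a1, a2, b1, b2, eps = 1e-9) {
  d1 <- cross2(b1, b2, a1)
  d2 <- cross2(b1, b2, a2)
  d3 <- cross2(a1, a2, b1)
  d4 <- cross2(a1, a2, b2)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  if (abs(d1) <= eps && on_segment_box(a1, b1, b2, eps)) return(TRUE)
  if (abs(d2) <= eps && on_segment_box(a2, b1, b2, eps)) return(TRUE)
  if (abs(d3) <= eps && on_segment_box(b1, a1, a2, eps)) return(TRUE)
  if (abs(d4) <= eps && on_segment_box(b2, a1, a2, eps)) return(TRUE)
  FALSE
}

#' @export
print.RoiSet <- function(x, ...) {
  cat("RoiSet: ", length(x$entries), " polygon(s) on frame(s) ",
      paste(names(x$entries), collapse = ", "), "\n", sep = "")
  if (!is.null(x$image_shape)) {
    cat("  image shape: ", x$image_shape[1L], "x", x$image_shape[2L],
        "\n", sep = "")
  }
  invisible(x)
}

#' Retrieve the polygon for one frame
#' @param roi a [roi_set()].
#' @param frame_index 0-based frame index.
#' @return n x 2 vertex matrix, or `NULL` when the frame has no ROI.
#' @export
roi_polygon <- function(roi, frame_index) {
  roi$entries[[as.character(as.integer(frame_index))]]
}

#' Read a ventricle ROI sidecar file
#'
#' The sidecar dialect (`hcsa-roi v1`) is a plain text file whose first
#' line starts with `#hcsa-roi v1` (optionally followed by
#' `height=H width=W`), then one comma-separated record per vertex:
#' `frame_index, vertex_index, x, y`. A frame's vertices appear on
#' consecutive lines with vertex_index running 0, 1, 2, ... in outline
#' order.
#'
#' @param path sidecar file path.
#' @return a [roi_set()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("cannot read ROI sidecar: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], "#hcsa-roi v1")) {
    stop("not an hcsa-roi v1 sidecar (bad header): ", path)
  }
  image_shape <- NULL
  hm <- regmatches(lines[1L],
                   regexec("height=([0-9]+) +width=([0-9]+)", lines[1L]))[[1L]]
  if (length(hm) == 3L) image_shape <- as.integer(hm[2:3])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body)) & !startsWith(trimws(body), "#")]
  if (length(body) == 0L) stop("ROI sidecar has no vertex records: ", path)
  rec <- utils::read.csv(text = body, header = FALSE,
                         col.names = c("frame_index", "vertex_index", "x", "y"))
  if (anyNA(rec)) stop("malformed vertex record in ", path)
  entries <- list()
  runs <- rle(rec$frame_index)
  if (anyDuplicated(runs$values)) {
    stop("ROI sidecar ", path, ": a frame's vertices must be consecutive")
  }
  pos <- cumsum(c(0L, runs$lengths))
  for (k in seq_along(runs$values)) {
    rows <- (pos[k] + 1L):pos[k + 1L]
    sub <- rec[rows, , drop = FALSE]
    if (!identical(as.integer(sub$vertex_index), seq_len(nrow(sub)) - 1L)) {
      stop("ROI sidecar ", path, ": vertex_index for frame ", runs$values[k],
           " must run 0..", nrow(sub) - 1L, " in order")
    }
    entries[[as.character(runs$values[k])]] <-
      cbind(x = sub$x, y = sub$y)
  }
  roi_set(entries, image_shape = image_shape)
}

#' Write a ventricle ROI sidecar file
#'
#' Inverse of [read_roi()]; `read_roi(write_roi(roi, path))` restores
#' the vertex lists exactly.
#'
#' @param roi a [roi_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "RoiSet"))
  header <- "#hcsa-roi v1"
  if (!is.null(roi$image_shape)) {
    header <- sprintf("#hcsa-roi v1 height=%d width=%d",
                      roi$image_shape[1L], roi$image_shape[2L])
  }
  out <- header
  keys <- names(roi$entries)[order(as.integer(names(roi$entries)))]
  for (key in keys) {
    poly <- roi$entries[[key]]
    out <- c(out, sprintf("%s,%d,%.17g,%.17g", key, seq_len(nrow(poly)) - 1L,
                          poly[, 1L], poly[, 2L]))
  }
  writeLines(out, path)
  invisible(path)
}
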