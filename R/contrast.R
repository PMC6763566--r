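#' Compute per-frame hemoglobin contrast images
#'
#' Hemoglobin absorbs short visible wavelengths (green/blue) far more
#' strongly than red, so blood darkens the strongly absorbed channel
#' relative to the weakly absorbed one. In `channel_difference` mode the
#' contrast is the weak-absorption channel minus the strong-absorption
#' channel, min-max normalized over the whole series to `[0, 1]`, so
#' higher values mean more hemoglobin and values are comparable across
#' frames. `single_channel_inverted` mode (for grayscale phantoms)
#' inverts the series-normalized single channel instead.
#'
#' @param series an [image_series()].
#' @param config a [run_config()]; `channel_weak`/`channel_strong` name
#'   the channel roles in `channel_difference` mode.
#' @return an object of class `ContrastStack`: list with `frames` (one
#'   scalar raster per input frame), `normalization` (the series
#'   min/max used), and `mode`.
#' @export
compute_hb_contrast <- function(series, config = run_config()) {
  stopifnot(inherits(series, "ImageSeries"), inherits(config, "RunConfig"))
  d <- dim(series$frames[[1L]])
  n_chan <- if (length(d) == 3L) d[3L] else 1L
  if (config$contrast_mode == "channel_difference") {
    if (n_chan < 2L) {
      stop("configuration error: channel_difference mode needs a ",
           "multi-channel series, got ", n_chan, " channel(s)")
    }
    iw <- resolve_channel(config$channel_weak, series$channel_names,
                          "channel_weak")
    is_ <- resolve_channel(config$channel_strong, series$channel_names,
                           "channel_strong")
    raw <- lapply(series$frames,
                  function(f) channel_slice(f, iw) - channel_slice(f, is_))
  } else {
    ch <- if (n_chan == 1L) NULL
          else resolve_channel(config$channel_strong, series$channel_names,
                               "channel_strong")
    raw <- lapply(series$frames,
                  function(f) if (is.null(ch)) f else channel_slice(f, ch))
  }
  lo <- min(vapply(raw, min, numeric(1)))
  hi <- max(vapply(raw, max, numeric(1)))
  if (hi <= lo) {
    stop("degenerate contrast: series has zero dynamic range (min == max)")
  }
  norm <- lapply(raw, function(f) (f - lo) / (hi - lo))
  if (config$contrast_mode == "single_channel_inverted") {
    norm <- lapply(norm, function(f) 1 - f)
  }
  structure(list(frames = norm,
                 normalization = c(low = lo, high = hi),
                 mode = config$contrast_mode),
            class = "ContrastStack")
}

# extract one channel as a matrix, keeping 1-px-wide shapes intact
channel_slice <- function(f, ch) {
  out <- f[, , ch, drop = FALSE]
  dim(out) <- dim(f)[1:2]
  out
}

resolve_channel <- function(role, channel_names, what) {
  if (is.null(role) || is.na(role)) {
    stop("configuration error: ", what, " is not set")
  }
  idx <- match(role, channel_names)
  if (is.na(idx)) {
    idx <- suppressWarnings(as.integer(role))
    if (is.na(idx) || idx < 1L || idx > length(channel_names)) {
      stop("configuration error: ", what, " '", role,
           "' matches no channel (available: ",
           paste(channel_names, collapse = ", "), ")")
    }
  }
  idx
}

#' @export
print.ContrastStack <- function(x, ...) {
  cat("ContrastStack: ", length(x$frames), " frames, mode ", x$mode,
      ", source range [", format(x$normalization[1L]), ", ",
      format(x$normalization[2L]), "]\n", sep = "")
  invisible(x)
}

#' Count hemoglobin-classified pixels (Hb blush) inside a ventricle ROI
#'
#' The Hb blush of a frame is the number of ROI pixels whose contrast
#' exceeds the threshold; it is the pixel-count surrogate for the blood
#' area visible in that frame.
#'
#' @param contrast_frame scalar contrast raster (one frame of a
#'   [compute_hb_contrast()] stack).
#' @param roi_mask a [rasterize_polygon()] mask of the same shape.
#' @param threshold an [otsu_threshold()] result (or a bare numeric
#'   threshold value).
#' @return an object of class `BlushMeasurement`: list with
#'   `frame_index`, `blush_px`, `roi_area_px`.
#' @export
measure_blush <- function(contrast_frame, roi_mask, threshold) {
  stopifnot(inherits(roi_mask, "RoiMask"))
  if (!identical(dim(contrast_frame), dim(roi_mask$mask))) {
    stop("shape mismatch: contrast frame is ",
         paste(dim(contrast_frame), collapse = "x"), " but ROI mask is ",
         paste(dim(roi_mask$mask), collapse = "x"))
  }
  thr <- if (inherits(threshold, "ThresholdResult")) threshold$threshold
         else as.numeric(threshold)
  vals <- contrast_frame[roi_mask$mask]
  structure(list(frame_index = roi_mask$frame_index,
                 blush_px = sum(vals > thr),
                 roi_area_px = roi_mask$area_px),
            class = "BlushMeasurement")
}
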