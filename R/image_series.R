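#' Construct an image series
#'
#' An `ImageSeries` is an ordered stack of equally shaped frames from a
#' time-lapse acquisition of a beating heart. Frames are numeric matrices
#' (grayscale, height x width) or arrays (height x width x channels) in
#' raw detector units; no intensity rescaling is ever applied. 14-bit
#' acquisitions are carried unchanged in 16-bit containers and
#' `bit_depth` records the container.
#'
#' @param frames list of frames, each a numeric matrix or 3-d array; all
#'   frames must share one shape.
#' @param bit_depth integer container bit depth (8-16). Integer-valued
#'   frames must lie within `[0, 2^bit_depth - 1]`.
#' @param interframe_interval_s time between consecutive frames in
#'   seconds (default 0.2, the standard still-series interval).
#' @param channel_names ordered channel labels. Defaults to `"gray"` for
#'   single-channel frames and `c("red", "green", "blue")` for
#'   three-channel frames.
#' @param source_id free-text provenance label.
#'
#' @return an object of class `ImageSeries`: a list with fields
#'   `frames`, `bit_depth`, `interframe_interval_s`, `channel_names`,
#'   `source_id`.
#' @export
image_series <- function(frames, bit_depth,
                         interframe_interval_s = 0.2,
                         channel_names = NULL,
                         source_id = "") {
  if (!is.list(frames) || length(frames) < 2L) {
    stop("insufficient frames: an image series needs at least 2 frames, got ",
         length(frames))
  }
  ref_dim <- dim_of_frame(frames[[1L]])
  for (i in seq_along(frames)) {
    d <- dim_of_frame(frames[[i]])
    if (!identical(d, ref_dim)) {
      stop("shape mismatch: frame ", i - 1L, " has shape ",
           paste(d, collapse = "x"), " but frame 0 has ",
           paste(ref_dim, collapse = "x"))
    }
    if (!is.numeric(frames[[i]]) || anyNA(frames[[i]])) {
      stop("frame ", i - 1L, " contains non-numeric or missing values")
    }
  }
  bit_depth <- as.integer(bit_depth)
  if (length(bit_depth) != 1L || is.na(bit_depth) ||
      bit_depth < 1L || bit_depth > 16L) {
    stop("bit_depth must be a single integer between 1 and 16")
  }
  maxval <- 2^bit_depth - 1
  rng <- range(vapply(frames, range, numeric(2)))
  integerish <- all(vapply(frames, function(f) all(f == floor(f)), logical(1)))
  if (integerish && (rng[1] < 0 || rng[2] > maxval)) {
    stop("intensities [", rng[1], ", ", rng[2],
         "] exceed the ", bit_depth, "-bit container range [0, ", maxval, "]")
  }
  if (!is.numeric(interframe_interval_s) || length(interframe_interval_s) != 1L ||
      interframe_interval_s <= 0) {
    stop("interframe_interval_s must be a single positive number")
  }
  n_chan <- if (length(ref_dim) == 3L) ref_dim[3L] else 1L
  if (is.null(channel_names)) {
    channel_names <- if (n_chan == 1L) "gray"
                     else if (n_chan == 3L) c("red", "green", "blue")
                     else paste0("ch", seq_len(n_chan))
  }
  if (length(channel_names) != n_chan) {
    stop("channel_names has length ", length(channel_names),
         " but frames have ", n_chan, " channel(s)")
  }
  structure(
    list(frames = frames,
         bit_depth = bit_depth,
         interframe_interval_s = interframe_interval_s,
         channel_names = as.character(channel_names),
         source_id = as.character(source_id)),
    class = "ImageSeries")
}

dim_of_frame <- function(f) {
  d <- dim(f)
  if (is.null(d)) stop("frames must be matrices or arrays")
  if (!length(d) %in% c(2L, 3L)) {
    stop("frames must be 2-d (gray) or 3-d (multichannel), got ",
         length(d), " dimensions")
  }
  as.integer(d)
}

#' @export
print.ImageSeries <- function(x, ...) {
  d <- dim_of_frame(x$frames[[1L]])
  cat("ImageSeries: ", length(x$frames), " frames of ",
      paste(d, collapse = "x"), ", ", x$bit_depth, "-bit, ",
      x$interframe_interval_s, " s interval\n", sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  if (nzchar(x$source_id)) cat("  source: ", x$source_id, "\n", sep = "")
  invisible(x)
}

#' Number of frames in an image series
#' @param series an `ImageSeries`.
#' @return integer frame count.
#' @export
n_frames <- function(series) length(series$frames)

#' Read a time-lapse image series from PNG or TIFF files
#'
#' Accepts either a multi-page TIFF stack, a single directory of
#' numbered single-frame PNG/TIFF files, or an explicit character vector
#' of frame files. Files are ordered by the trailing number in their
#' base name (zero-padded suffixes sort identically either way); pages
#' of a multi-page TIFF keep their page order. Pixel values are restored
#' to raw integer detector units; no rescaling is applied.
#'
#' @param path_spec a multi-page TIFF path, a directory containing the
#'   frame files, or a character vector of frame file paths.
#' @param interframe_interval_s seconds between frames, recorded in the
#'   result (default 0.2).
#' @param source_id optional provenance label; defaults to `path_spec`.
#'
#' @return an [image_series()] object.
#' @export
read_image_series <- function(path_spec, interframe_interval_s = 0.2,
                              source_id = NULL) {
  if (length(path_spec) == 1L && dir.exists(path_spec)) {
    files <- list.files(path_spec, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) {
      stop("no PNG/TIFF frames found in directory: ", path_spec)
    }
    files <- order_by_suffix(files)
  } else if (length(path_spec) == 1L && grepl("\\.(tif|tiff)$", path_spec,
                                              ignore.case = TRUE)) {
    return(read_tiff_stack(path_spec, interframe_interval_s,
                           source_id %||% path_spec))
  } else {
    files <- path_spec
  }
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    stop("cannot read frame file: ", missing[1L])
  }
  if (length(files) < 2L) {
    stop("insufficient frames: found ", length(files),
         " frame file(s), need at least 2")
  }
  frames <- vector("list", length(files))
  depths <- integer(length(files))
  for (i in seq_along(files)) {
    fr <- read_one_frame(files[i])
    frames[[i]] <- fr$pixels
    depths[i] <- fr$bit_depth
    if (i > 1L && !identical(dim_of_frame(frames[[i]]),
                             dim_of_frame(frames[[1L]]))) {
      stop("shape mismatch in frame file ", files[i], ": ",
           paste(dim_of_frame(frames[[i]]), collapse = "x"),
           " vs ", paste(dim_of_frame(frames[[1L]]), collapse = "x"),
           " in ", files[1L])
    }
  }
  if (length(unique(depths)) > 1L) {
    stop("mixed bit depths across frame files: ",
         paste(sort(unique(depths)), collapse = ", "))
  }
  image_series(frames, bit_depth = depths[1L],
               interframe_interval_s = interframe_interval_s,
               source_id = source_id %||%
                 paste0(dirname(files[1L]), " (", length(files), " files)"))
}

read_one_frame <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("cannot read PNG ", path, ": ",
                                             conditionMessage(e)))
    depth <- attr(img, "info")$bit.depth
    list(pixels = round(unclass_strip(img) * (2^depth - 1)),
         bit_depth = as.integer(depth))
  } else {
    img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) stop("cannot read TIFF ", path, ": ",
                                             conditionMessage(e)))
    depth <- attr(img, "bits.per.sample")
    list(pixels = round(unclass_strip(img) * (2^depth - 1)),
         bit_depth = as.integer(depth))
  }
}

read_tiff_stack <- function(path, interframe_interval_s, source_id) {
  if (!file.exists(path)) stop("cannot read TIFF stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    stop("insufficient frames: TIFF stack ", path, " has ",
         length(pages), " page(s), need at least 2")
  }
  depths <- vapply(pages, function(p) as.integer(attr(p, "bits.per.sample")),
                   integer(1))
  if (length(unique(depths)) > 1L) {
    stop("mixed bit depths across pages of ", path)
  }
  frames <- lapply(pages, function(p) round(unclass_strip(p) * (2^depths[1L] - 1)))
  for (i in seq_along(frames)) {
    if (!identical(dim_of_frame(frames[[i]]), dim_of_frame(frames[[1L]]))) {
      stop("shape mismatch at page ", i - 1L, " of ", path)
    }
  }
  image_series(frames, bit_depth = depths[1L],
               interframe_interval_s = interframe_interval_s,
               source_id = source_id)
}

# drop reader-attached attributes but keep dim
unclass_strip <- function(x) {
  d <- dim(x)
  attributes(x) <- NULL
  dim(x) <- d
  x
}

order_by_suffix <- function(files) {
  base <- sub("\\.[A-Za-z]+$", "", basename(files))
  num <- suppressWarnings(as.numeric(sub(".*?([0-9]+)$", "\\1", base)))
  if (anyNA(num)) files[order(base)] else files[order(num, base)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image series to disk
#'
#' Writes either a single multi-page TIFF (when `path` ends in
#' `.tif`/`.tiff`) or one numbered file per frame into a directory.
#' TIFF output preserves 8- and 16-bit data bit-exactly. PNG output is
#' limited to 8-bit series (the PNG writer available to R emits 8-bit
#' files only); writing a deeper series to PNG is an error rather than a
#' silent truncation.
#'
#' @param series an [image_series()] object.
#' @param path output TIFF stack path, or a directory for per-frame
#'   files.
#' @param format per-frame file format when `path` is a directory:
#'   `"tiff"` (default) or `"png"` (8-bit series only).
#' @return `path`, invisibly.
#' @export
write_image_series <- function(series, path, format = c("tiff", "png")) {
  stopifnot(inherits(series, "ImageSeries"))
  format <- match.arg(format)
  container_bits <- if (series$bit_depth > 8L) 16L else 8L
  maxval <- 2^container_bits - 1
  scaled <- lapply(series$frames, function(f) f / maxval)
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(scaled, path, bits.per.sample = container_bits)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  width <- max(4L, nchar(as.character(length(scaled) - 1L)))
  for (i in seq_along(scaled)) {
    stem <- sprintf("frame_%0*d", width, i - 1L)
    if (format == "tiff") {
      tiff::writeTIFF(scaled[[i]], file.path(path, paste0(stem, ".tif")),
                      bits.per.sample = container_bits)
    } else {
      if (container_bits != 8L) {
        stop("PNG output supports 8-bit series only; ",
             "use TIFF for ", series$bit_depth, "-bit data")
      }
      png::writePNG(scaled[[i]], file.path(path, paste0(stem, ".png")))
    }
  }
  invisible(path)
}
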