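#' Analysis run configuration
#'
#' Bundles every tunable of the quantification pipeline. Defaults match
#' a colour acquisition in which hemoglobin absorbs the green channel
#' strongly and the red channel weakly, a 256-bin Otsu histogram pooled
#' over the two selected frames, and automatic end-diastole/end-systole
#' selection.
#'
#' @param channel_weak channel name (or 1-based index as character) of
#'   the weakly Hb-absorbing channel; default `"red"`.
#' @param channel_strong strongly Hb-absorbing channel; default
#'   `"green"`.
#' @param contrast_mode `"channel_difference"` (weak minus strong,
#'   two-channel HCSA) or `"single_channel_inverted"` (inverted
#'   grayscale, for single-channel phantoms).
#' @param otsu_bins number of equal-width histogram bins for the Otsu
#'   threshold; default 256.
#' @param otsu_pooling `"pooled_over_selected_frames"` (one threshold
#'   shared by the ED and ES frame, the default) or `"per_frame"`.
#' @param phase_selection `"auto"` (extremes of the Hb-blush trace) or
#'   `"manual"`.
#' @param ed_frame,es_frame 0-based frame indices, required when
#'   `phase_selection = "manual"`.
#' @param smoothing_window odd moving-average window (frames) applied to
#'   the blush trace before picking extremes; default 1 (no smoothing).
#' @param alpha two-sided significance level for group comparisons;
#'   default 0.05.
#' @return an object of class `RunConfig`.
#' @export
run_config <- function(channel_weak = "red",
                       channel_strong = "green",
                       contrast_mode = c("channel_difference",
                                         "single_channel_inverted"),
                       otsu_bins = 256L,
                       otsu_pooling = c("pooled_over_selected_frames",
                                        "per_frame"),
                       phase_selection = c("auto", "manual"),
                       ed_frame = NA_integer_,
                       es_frame = NA_integer_,
                       smoothing_window = 1L,
                       alpha = 0.05) {
  contrast_mode <- match.arg(contrast_mode)
  otsu_pooling <- match.arg(otsu_pooling)
  phase_selection <- match.arg(phase_selection)
  otsu_bins <- as.integer(otsu_bins)
  smoothing_window <- as.integer(smoothing_window)
  if (is.na(otsu_bins) || otsu_bins < 2L) stop("otsu_bins must be >= 2")
  if (is.na(smoothing_window) || smoothing_window < 1L ||
      smoothing_window %% 2L == 0L) {
    stop("smoothing_window must be an odd integer >= 1")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  ed_frame <- as.integer(ed_frame)
  es_frame <- as.integer(es_frame)
  if (phase_selection == "manual") {
    if (is.na(ed_frame) || is.na(es_frame)) {
      stop("manual phase selection requires ed_frame and es_frame")
    }
    if (ed_frame == es_frame) stop("ed_frame and es_frame must differ")
    if (ed_frame < 0L || es_frame < 0L) stop("frame indices are 0-based, >= 0")
  }
  structure(
    list(channel_weak = channel_weak, channel_strong = channel_strong,
         contrast_mode = contrast_mode, otsu_bins = otsu_bins,
         otsu_pooling = otsu_pooling, phase_selection = phase_selection,
         ed_frame = ed_frame, es_frame = es_frame,
         smoothing_window = smoothing_window, alpha = alpha),
    class = "RunConfig")
}

config_keys <- c("channel_weak", "channel_strong", "contrast_mode",
                 "otsu_bins", "otsu_pooling", "phase_selection",
                 "ed_frame", "es_frame", "smoothing_window", "alpha")

#' Read a run configuration from a key=value file
#'
#' The file is flat text, one `key=value` pair per line; blank lines and
#' lines starting `#` are ignored. Unknown keys are an error so that a
#' misspelled option never silently falls back to its default.
#'
#' @param path configuration file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad) > 0L) stop("malformed config line: ", lines[bad[1L]])
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  unknown <- setdiff(keys, config_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(keys)) stop("duplicate config key: ",
                                keys[duplicated(keys)][1L])
  args <- as.list(vals)
  names(args) <- keys
  for (k in intersect(keys, c("otsu_bins", "ed_frame", "es_frame",
                              "smoothing_window"))) {
    args[[k]] <- as.integer(args[[k]])
  }
  if ("alpha" %in% keys) args$alpha <- as.numeric(args$alpha)
  do.call(run_config, args)
}

#' Write a run configuration to a key=value file
#' @param config a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  vals <- vapply(config_keys, function(k) {
    v <- config[[k]]
    if (is.na(v)) "NA" else as.character(v)
  }, character(1))
  writeLines(paste0(config_keys, "=", vals), path)
  invisible(path)
}
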