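#' Select end-diastolic and end-systolic frames from a blush trace
#'
#' End-diastole (maximal filling) is taken as the frame with the
#' largest hemoglobin blush and end-systole (maximal contraction) as
#' the frame with the smallest, optionally after a centered
#' moving-average smoothing of the trace (window truncated at the
#' edges). Ties are broken toward the earliest frame. A constant trace
#' carries no pulsatility signal and is an error, not a silent pick.
#'
#' @param blush_trace numeric vector of per-frame blush pixel counts
#'   (index 1 of the vector is frame 0).
#' @param config a [run_config()]; uses `smoothing_window`,
#'   `phase_selection`, and in manual mode `ed_frame`/`es_frame`.
#' @return an object of class `PhaseSelection`: list with 0-based
#'   `ed_frame`, `es_frame`, `mode`, and the (smoothed) `blush_trace`
#'   used.
#' @export
select_phases <- function(blush_trace, config = run_config()) {
  stopifnot(inherits(config, "RunConfig"))
  n <- length(blush_trace)
  if (n < 2L) stop("blush trace needs at least 2 frames")
  if (config$phase_selection == "manual") {
    ed <- config$ed_frame; es <- config$es_frame
    if (ed >= n || es >= n) {
      stop("manual frame index out of range: series has frames 0..", n - 1L)
    }
    return(structure(list(ed_frame = ed, es_frame = es, mode = "manual",
                          blush_trace = blush_trace),
                     class = "PhaseSelection"))
  }
  w <- config$smoothing_window
  if (w > n) stop("smoothing_window (", w, ") exceeds trace length (", n, ")")
  sm <- moving_average(blush_trace, w)
  if (max(sm) <= min(sm)) {
    stop("no pulsatility: blush trace is constant, cannot select ED/ES frames")
  }
  structure(list(ed_frame = which.max(sm) - 1L,
                 es_frame = which.min(sm) - 1L,
                 mode = "auto",
                 blush_trace = sm),
            class = "PhaseSelection")
}

# centered moving average, window truncated at the series edges
moving_average <- function(x, w) {
  if (w == 1L) return(as.numeric(x))
  half <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' @export
print.PhaseSelection <- function(x, ...) {
  cat("PhaseSelection (", x$mode, "): ED frame ", x$ed_frame,
      ", ES frame ", x$es_frame, "\n", sep = "")
  invisible(x)
}

#' Compute the eight ventricular function metrics
#'
#' From the segmented ventricle area and the Hb blush (blood pixel
#' count) at end-diastole and end-systole:
#' \itemize{
#'   \item `tEDA`, `tESA` -- total ventricular area (px^2) at ED / ES;
#'   \item `delta_pct_tA = 100 * (tEDA - tESA) / tEDA` -- percent area
#'     change during contraction;
#'   \item `EDBA`, `ESBA` -- blood (blush) area at ED / ES;
#'   \item `SA = EDBA - ESBA` -- stroke area;
#'   \item `EF = 100 * SA / EDBA` -- ejection fraction;
#'   \item `MMI = tESA - ESBA` -- myocardial mass index: at peak
#'     contraction most blood has been ejected, so the segmented area
#'     minus the residual blood area approximates myocardial tissue.
#' }
#' Negative stroke area (paradoxical filling) is reported, flagged via
#' the `paradoxical` field, and never clamped. Areas are in px^2; any
#' physical calibration is applied at output, not here.
#'
#' @param ed,es numeric vectors `c(roi_area_px, blush_px)` for the ED
#'   and ES frame.
#' @param phases a [select_phases()] result (provides the frame
#'   indices), or `NULL` when only the areas matter.
#' @param embryo_id,group labels carried into results tables.
#' @return an object of class `VentricleMetrics`.
#' @export
ventricle_metrics <- function(ed, es, phases = NULL,
                              embryo_id = NA_character_,
                              group = NA_character_) {
  stopifnot(length(ed) == 2L, length(es) == 2L)
  tEDA <- as.numeric(ed[[1L]]); EDBA <- as.numeric(ed[[2L]])
  tESA <- as.numeric(es[[1L]]); ESBA <- as.numeric(es[[2L]])
  if (any(c(tEDA, tESA, EDBA, ESBA) < 0)) stop("areas must be >= 0")
  if (EDBA > tEDA || ESBA > tESA) {
    stop("blush area exceeds ROI area (ED: ", EDBA, "/", tEDA,
         ", ES: ", ESBA, "/", tESA, ")")
  }
  if (tEDA <= 0) stop("undefined area change: tEDA is 0")
  if (EDBA <= 0) stop("undefined ejection fraction: EDBA is 0")
  SA <- EDBA - ESBA
  structure(
    list(tEDA = tEDA, tESA = tESA,
         delta_pct_tA = 100 * (tEDA - tESA) / tEDA,
         EDBA = EDBA, ESBA = ESBA,
         SA = SA, EF = 100 * SA / EDBA,
         MMI = tESA - ESBA,
         ed_frame = if (is.null(phases)) NA_integer_ else phases$ed_frame,
         es_frame = if (is.null(phases)) NA_integer_ else phases$es_frame,
         paradoxical = SA < 0,
         embryo_id = as.character(embryo_id),
         group = as.character(group)),
    class = "VentricleMetrics")
}

#' Scale pixel-based metrics to physical units
#'
#' Applies a micrometers-per-pixel calibration to every area metric
#' (multiplying by `um_per_px^2`). Percentages (`EF`, `delta_pct_tA`)
#' and frame indices are dimensionless and unchanged.
#'
#' @param metrics a [ventricle_metrics()].
#' @param um_per_px positive scale factor.
#' @return a new `VentricleMetrics` with areas in um^2.
#' @export
scale_metrics <- function(metrics, um_per_px) {
  stopifnot(inherits(metrics, "VentricleMetrics"), um_per_px > 0)
  s2 <- um_per_px^2
  for (f in c("tEDA", "tESA", "EDBA", "ESBA", "SA", "MMI")) {
    metrics[[f]] <- metrics[[f]] * s2
  }
  metrics
}

#' @export
print.VentricleMetrics <- function(x, ...) {
  cat("VentricleMetrics",
      if (!is.na(x$embryo_id)) paste0(" [", x$embryo_id,
                                      if (!is.na(x$group)) paste0("/", x$group),
                                      "]"),
      ":\n", sep = "")
  cat(sprintf("  tEDA %.1f  tESA %.1f  d%%tA %.2f%%\n",
              x$tEDA, x$tESA, x$delta_pct_tA))
  cat(sprintf("  EDBA %.1f  ESBA %.1f  SA %.1f  EF %.2f%%  MMI %.1f\n",
              x$EDBA, x$ESBA, x$SA, x$EF, x$MMI))
  if (!is.na(x$ed_frame)) {
    cat("  ED frame ", x$ed_frame, ", ES frame ", x$es_frame, "\n", sep = "")
  }
  if (isTRUE(x$paradoxical)) cat("  ! paradoxical filling (SA < 0)\n")
  invisible(x)
}

#' Flatten ventricle metrics to a one-row data frame
#' @param x a [ventricle_metrics()].
#' @param row.names,optional,... ignored (data frame method signature).
#' @return one-row data frame with the standard metrics table columns.
#' @export
as.data.frame.VentricleMetrics <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(embryo_id = x$embryo_id, group = x$group,
             tEDA = x$tEDA, tESA = x$tESA, delta_pct_tA = x$delta_pct_tA,
             EDBA = x$EDBA, ESBA = x$ESBA, SA = x$SA, EF = x$EF,
             MMI = x$MMI, ed_frame = x$ed_frame, es_frame = x$es_frame,
             stringsAsFactors = FALSE)
}
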