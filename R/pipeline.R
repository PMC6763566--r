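#' Run the full quantification pipeline on an in-memory series
#'
#' Stages: hemoglobin contrast, end-diastole/end-systole selection,
#' Otsu thresholding of ROI contrast values, Hb blush measurement, and
#' the eight ventricular metrics.
#'
#' In automatic phase selection the per-frame blush trace is computed
#' inside the union of all supplied ROI outlines with a provisional
#' Otsu threshold pooled over every frame; the trace maximum is
#' end-diastole and the minimum end-systole. The selected frames must
#' each carry their own ROI outline (the ventricle is segmented
#' separately at ED and ES because the total areas differ). The final
#' threshold is then computed per the configured pooling: by default
#' the ED- and ES-frame ROI values are pooled into one histogram so
#' that one shared threshold is applied to both frames and the
#' `EDBA - ESBA` difference reflects blood area, not threshold drift.
#'
#' @param series an [image_series()].
#' @param rois a [roi_set()] with outlines at least on the selected ED
#'   and ES frames.
#' @param config a [run_config()].
#' @param embryo_id,group labels carried into the metrics.
#' @return list with `metrics` ([ventricle_metrics()]), `phases`,
#'   `threshold` (named list, one entry per frame role), `blush`
#'   (ED/ES [measure_blush()] results), `blush_trace` (auto mode only),
#'   and `log` (per-stage character lines).
#' @export
quantify_series <- function(series, rois, config = run_config(),
                            embryo_id = NA_character_,
                            group = NA_character_) {
  stopifnot(inherits(series, "ImageSeries"), inherits(rois, "RoiSet"),
            inherits(config, "RunConfig"))
  log <- character()
  shape <- dim_of_frame(series$frames[[1L]])[1:2]
  nf <- n_frames(series)
  for (key in names(rois$entries)) {
    if (as.integer(key) < 0L || as.integer(key) >= nf) {
      stop("ROI references frame ", key, " but series has frames 0..", nf - 1L)
    }
  }

  contrast <- compute_hb_contrast(series, config)
  log <- c(log, sprintf("contrast: mode=%s source_range=[%g, %g]",
                        contrast$mode, contrast$normalization[1L],
                        contrast$normalization[2L]))

  blush_trace <- NULL
  if (config$phase_selection == "auto") {
    union_mask <- NULL
    for (key in names(rois$entries)) {
      m <- rasterize_polygon(rois$entries[[key]], shape,
                             frame_index = as.integer(key))
      union_mask <- if (is.null(union_mask)) m$mask else union_mask | m$mask
    }
    pooled_vals <- unlist(lapply(contrast$frames, function(f) f[union_mask]))
    provisional <- otsu_threshold(pooled_vals, config$otsu_bins)
    blush_trace <- vapply(contrast$frames,
                          function(f) sum(f[union_mask] > provisional$threshold),
                          numeric(1))
    log <- c(log, sprintf("trace: provisional_threshold=%g union_roi_px=%d",
                          provisional$threshold, sum(union_mask)))
  }
  phases <- select_phases(blush_trace %||% rep(0, nf), config)
  log <- c(log, sprintf("phases: mode=%s ed_frame=%d es_frame=%d",
                        phases$mode, phases$ed_frame, phases$es_frame))

  poly_ed <- roi_polygon(rois, phases$ed_frame)
  if (is.null(poly_ed)) {
    stop("no ROI outline for selected end-diastolic frame ", phases$ed_frame)
  }
  poly_es <- roi_polygon(rois, phases$es_frame)
  if (is.null(poly_es)) {
    stop("no ROI outline for selected end-systolic frame ", phases$es_frame)
  }
  mask_ed <- rasterize_polygon(poly_ed, shape, frame_index = phases$ed_frame)
  mask_es <- rasterize_polygon(poly_es, shape, frame_index = phases$es_frame)
  frame_ed <- contrast$frames[[phases$ed_frame + 1L]]
  frame_es <- contrast$frames[[phases$es_frame + 1L]]

  if (config$otsu_pooling == "pooled_over_selected_frames") {
    thr <- otsu_threshold(c(frame_ed[mask_ed$mask], frame_es[mask_es$mask]),
                          config$otsu_bins)
    thresholds <- list(ed = thr, es = thr)
  } else {
    thresholds <- list(ed = otsu_threshold(frame_ed[mask_ed$mask],
                                           config$otsu_bins),
                       es = otsu_threshold(frame_es[mask_es$mask],
                                           config$otsu_bins))
  }
  log <- c(log, sprintf("otsu: pooling=%s threshold_ed=%g threshold_es=%g",
                        config$otsu_pooling, thresholds$ed$threshold,
                        thresholds$es$threshold))

  blush_ed <- measure_blush(frame_ed, mask_ed, thresholds$ed)
  blush_es <- measure_blush(frame_es, mask_es, thresholds$es)
  log <- c(log, sprintf("blush: ed=%d/%d es=%d/%d",
                        blush_ed$blush_px, blush_ed$roi_area_px,
                        blush_es$blush_px, blush_es$roi_area_px))

  metrics <- ventricle_metrics(
    ed = c(blush_ed$roi_area_px, blush_ed$blush_px),
    es = c(blush_es$roi_area_px, blush_es$blush_px),
    phases = phases, embryo_id = embryo_id, group = group)
  log <- c(log, sprintf("metrics: EF=%.3f SA=%.1f delta_pct_tA=%.3f MMI=%.1f",
                        metrics$EF, metrics$SA, metrics$delta_pct_tA,
                        metrics$MMI))

  list(metrics = metrics, phases = phases, threshold = thresholds,
       blush = list(ed = blush_ed, es = blush_es),
       blush_trace = blush_trace, log = log)
}

run_record <- function(stage_log, inputs, config, seed = NA_integer_) {
  list(software = paste0("hcsa ",
                         as.character(utils::packageVersion("hcsa"))),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       inputs = inputs,
       config = if (inherits(config, "RunConfig")) unclass(config) else config,
       stages = stage_log)
}

write_run_record <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Quantify one embryo from files (CLI `quantify`)
#'
#' Reads an image series, its ROI sidecar, and an optional run
#' configuration; runs [quantify_series()]; writes a one-row metrics
#' table plus a JSON run record (`<out_path>.run.json`) capturing the
#' configuration snapshot, input paths, software version, and per-stage
#' log so every output table is auditable.
#'
#' @param series_path image series path (see [read_image_series()]).
#' @param roi_path ROI sidecar path.
#' @param out_path output metrics CSV.
#' @param config_path optional `key=value` config file; defaults used
#'   when `NULL`.
#' @param embryo_id,group labels for the output row.
#' @param record_path run-record path; default `<out_path>.run.json`.
#' @return the [quantify_series()] result, invisibly.
#' @export
hcsa_quantify <- function(series_path, roi_path, out_path,
                          config_path = NULL,
                          embryo_id = "embryo", group = "unlabeled",
                          record_path = NULL) {
  config <- if (is.null(config_path)) run_config()
            else read_run_config(config_path)
  series <- read_image_series(series_path)
  rois <- read_roi(roi_path)
  res <- quantify_series(series, rois, config,
                         embryo_id = embryo_id, group = group)
  write_metrics_table(list(res$metrics), out_path)
  rec <- run_record(res$log,
                    inputs = list(series = series_path, roi = roi_path,
                                  config = config_path),
                    config = config)
  write_run_record(rec, record_path %||% paste0(out_path, ".run.json"))
  invisible(res)
}

#' Compare groups across metrics tables (CLI `compare`)
#'
#' Reads one or more per-embryo metrics tables, stacks them, and
#' compares the first named group against each subsequent one with
#' [compare_cohorts()] (mirroring a control-versus-dose design).
#'
#' @param table_paths character vector of metrics CSV paths.
#' @param groups character vector of group labels, length >= 2; the
#'   first is the reference.
#' @param out_path output comparison CSV.
#' @param alpha per-comparison significance level.
#' @return the comparison data frame, invisibly.
#' @export
hcsa_compare <- function(table_paths, groups, out_path, alpha = 0.05) {
  tabs <- lapply(table_paths, read_metrics_table)
  tab <- do.call(rbind, tabs)
  if (length(groups) < 2L) stop("need at least two group labels")
  pairs <- lapply(groups[-1L], function(g) c(groups[1L], g))
  cmp <- compare_cohorts(tab, pairs, alpha = alpha)
  write_comparison_table(cmp, out_path)
  rec <- run_record(sprintf("compare: %d rows, alpha=%g", nrow(cmp), alpha),
                    inputs = list(tables = table_paths, groups = groups),
                    config = list(alpha = alpha))
  write_run_record(rec, paste0(out_path, ".run.json"))
  invisible(cmp)
}

#' Generate and write a phantom dataset (CLI `simulate`)
#'
#' Simulates one beating-heart phantom and writes a multi-page 16-bit
#' TIFF stack (`stack.tif`), the ROI sidecar (`roi.csv`), the analytic
#' ground-truth metrics (`ground_truth.csv`), and a run record into
#' `out_dir`. Output is bit-reproducible for a given seed.
#'
#' @param out_dir output directory (created if needed).
#' @param params a [phantom_params()], or `NULL` for defaults.
#' @param params_path optional `key=value` phantom parameter file
#'   (fields of [phantom_params()], vectors comma-separated).
#' @param seed optional seed overriding the one in `params`.
#' @return list of written paths, invisibly.
#' @export
hcsa_simulate <- function(out_dir, params = NULL, params_path = NULL,
                          seed = NULL) {
  if (!is.null(params_path)) params <- read_phantom_params(params_path)
  if (is.null(params)) params <- phantom_params()
  if (!is.null(seed)) {
    p <- unclass(params)
    p$seed <- as.integer(seed)
    params <- structure(p, class = "PhantomParams")
  }
  sim <- simulate_heart_series(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(stack = file.path(out_dir, "stack.tif"),
                roi = file.path(out_dir, "roi.csv"),
                truth = file.path(out_dir, "ground_truth.csv"),
                record = file.path(out_dir, "run.json"))
  write_image_series(sim$series, paths$stack)
  write_roi(sim$rois, paths$roi)
  truth_row <- data.frame(
    embryo_id = "phantom", group = "phantom",
    tEDA = sim$truth$tEDA_true, tESA = sim$truth$tESA_true,
    delta_pct_tA = sim$truth$delta_pct_tA_true,
    EDBA = sim$truth$EDBA_true, ESBA = sim$truth$ESBA_true,
    SA = sim$truth$SA_true, EF = sim$truth$EF_true,
    MMI = sim$truth$MMI_true,
    ed_frame = sim$truth$ed_frame, es_frame = sim$truth$es_frame,
    stringsAsFactors = FALSE)
  write_metrics_table(truth_row, paths$truth)
  rec <- run_record(sprintf("simulate: %d frames seed=%d EF_true=%.3f",
                            params$n_frames, params$seed,
                            sim$truth$EF_true),
                    inputs = list(params = params_path),
                    config = unclass(params), seed = params$seed)
  write_run_record(rec, paths$record)
  invisible(paths)
}

read_phantom_params <- function(path) {
  if (!file.exists(path)) stop("cannot read phantom parameters: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed parameter line in ", path)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  known <- names(formals(phantom_params))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L) {
    stop("unknown phantom parameter(s): ", paste(unknown, collapse = ", "))
  }
  args <- lapply(vals, function(v) as.numeric(strsplit(v, ",")[[1L]]))
  names(args) <- keys
  do.call(phantom_params, args)
}
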