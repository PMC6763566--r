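metrics_columns <- c("embryo_id", "group", "tEDA", "tESA", "delta_pct_tA",
                     "EDBA", "ESBA", "SA", "EF", "MMI",
                     "ed_frame", "es_frame")

#' Write a per-embryo metrics table
#'
#' One row per embryo with the fixed column set `embryo_id, group,
#' tEDA, tESA, delta_pct_tA, EDBA, ESBA, SA, EF, MMI, ed_frame,
#' es_frame`. Numeric values are written at full double precision, so
#' a written table parses back to the values that produced it.
#'
#' @param results a data frame with the columns above, or a list of
#'   [ventricle_metrics()] objects each carrying `embryo_id` and
#'   `group` attributes (see [as.data.frame.VentricleMetrics()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(results, path) {
  tab <- metrics_table(results)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

metrics_table <- function(results) {
  if (is.data.frame(results)) {
    tab <- results
  } else if (is.list(results) && length(results) > 0L &&
             all(vapply(results, inherits, logical(1), "VentricleMetrics"))) {
    tab <- do.call(rbind, lapply(results, as.data.frame))
  } else if (is.list(results) && length(results) == 0L) {
    stop("empty results: nothing to write")
  } else {
    stop("results must be a data frame or a list of VentricleMetrics")
  }
  if (nrow(tab) == 0L) stop("empty results: nothing to write")
  missing <- setdiff(metrics_columns, names(tab))
  if (length(missing) > 0L) {
    stop("results table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab[, metrics_columns, drop = FALSE]
}

#' Read a per-embryo metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return data frame with the standard metric columns.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("cannot read metrics table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(metrics_columns, names(tab))
  if (length(missing) > 0L) {
    stop("not a metrics table (missing ", paste(missing, collapse = ", "),
         "): ", path)
  }
  tab
}
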