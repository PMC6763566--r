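#' Otsu threshold over a collection of contrast values
#'
#' Classic bimodal histogram thresholding: values are histogrammed into
#' `n_bins` equal-width bins over their observed range, and the
#' threshold is the interior bin edge maximizing the between-class
#' variance `w0 * w1 * (mu0 - mu1)^2`, with class statistics computed
#' from bin counts and bin midpoints. Ties are broken toward the lowest
#' qualifying edge, which keeps the rule deterministic and inclusive of
#' blood pixels under the classification rule `value > threshold`
#' implies hemoglobin-containing.
#'
#' With 256 bins over an 8-bit range this reproduces the classic
#' integer-histogram behaviour while remaining applicable to continuous
#' contrast values. The criterion is invariant to affine rescaling of
#' the input (a*x + b, a > 0): the same pixels are classified either
#' side of the threshold.
#'
#' @param values numeric vector of contrast values (at least 2 distinct
#'   values).
#' @param n_bins number of histogram bins, >= 2 (default 256).
#' @return an object of class `ThresholdResult`: list with `threshold`,
#'   `between_class_variance`, `n_bins`, `histogram_range`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values) || any(!is.finite(values))) {
    stop("otsu_threshold needs finite, non-missing values")
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be >= 2")
  lo <- min(values); hi <- max(values)
  if (hi <= lo) {
    stop("degenerate input: all values identical, no threshold exists")
  }
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((values - lo) / width) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * width

  n <- length(values)
  w0 <- cumsum(counts) / n                 # class-0 weight up to edge j
  m0 <- cumsum(counts * mids) / n          # unnormalized class-0 mean
  mt <- m0[n_bins]                         # grand mean
  j <- seq_len(n_bins - 1L)
  denom <- w0[j] * (1 - w0[j])
  sigma_b <- ifelse(denom > 0, (mt * w0[j] - m0[j])^2 / denom, 0)

  best <- which.max(sigma_b)  # first (lowest) maximizing edge
  structure(list(threshold = lo + best * width,
                 between_class_variance = sigma_b[best],
                 n_bins = n_bins,
                 histogram_range = c(lo, hi)),
            class = "ThresholdResult")
}

#' @export
print.ThresholdResult <- function(x, ...) {
  cat("Otsu threshold ", format(x$threshold), " (", x$n_bins,
      " bins over [", format(x$histogram_range[1L]), ", ",
      format(x$histogram_range[2L]), "], between-class variance ",
      format(x$between_class_variance), ")\n", sep = "")
  invisible(x)
}
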