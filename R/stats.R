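#' Mann-Whitney U test (exact by enumeration, or normal approximation)
#'
#' The two-sided, unpaired rank test used for all group comparisons.
#' `U` counts the pairs `(a_i, b_j)` with `a_i > b_j`, ties counting
#' one half. When both samples have at most 8 observations and the
#' pooled data are tie-free (and under the `"auto"` policy), the exact
#' null distribution is obtained by full enumeration of all
#' `choose(n_a + n_b, n_a)` group assignments and the two-sided p-value
#' is `2 * P(U' <= min(U, n_a*n_b - U))`, capped at 1. Otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param a,b numeric samples (each nonempty).
#' @param method_policy `"auto"` (default), `"exact"`, or
#'   `"normal_approx"`.
#' @param alpha significance level for the `significant` flag.
#' @param metric_name optional label carried into the result.
#' @return an object of class `GroupComparison`: list with
#'   `metric_name`, `n_a`, `n_b`, `U`, `p_two_sided`, `method`,
#'   `significant`.
#' @export
mann_whitney_u <- function(a, b,
                           method_policy = c("auto", "exact", "normal_approx"),
                           alpha = 0.05, metric_name = NA_character_) {
  method_policy <- match.arg(method_policy)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be nonempty")
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain missing values")
  na <- length(a); nb <- length(b)
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))

  pooled <- c(a, b)
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- switch(method_policy,
                      exact = TRUE,
                      normal_approx = FALSE,
                      auto = na <= 8L && nb <= 8L && !has_ties)
  if (use_exact) {
    p <- mw_exact_p(pooled, na, nb, U)
    method <- "exact"
  } else {
    p <- mw_normal_p(pooled, na, nb, U)
    method <- "normal_approx"
  }
  structure(list(metric_name = metric_name, n_a = na, n_b = nb,
                 U = U, p_two_sided = p, method = method,
                 significant = p < alpha),
            class = "GroupComparison")
}

# exact two-sided p by enumeration of all choose(n, na) assignments;
# U' for each assignment via the midrank rank-sum identity
mw_exact_p <- function(pooled, na, nb, U) {
  if (choose(na + nb, na) > 5e6) {
    stop("exact enumeration infeasible for n = (", na, ", ", nb,
         "); use method_policy = 'normal_approx'")
  }
  r <- rank(pooled)  # midranks, valid with ties
  idx <- utils::combn(na + nb, na)
  u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
  u_ref <- min(U, na * nb - U)
  min(1, 2 * mean(u_all <= u_ref + 1e-9))
}

# normal approximation with tie-corrected variance and continuity
# correction toward the null mean
mw_normal_p <- function(pooled, na, nb, U) {
  n <- na + nb
  mu <- na * nb / 2
  ties <- table(pooled)
  v <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(1)
  d <- U - mu
  z <- if (d == 0) 0 else (d - 0.5 * sign(d)) / sqrt(v)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("Mann-Whitney", if (!is.na(x$metric_name)) paste0(" [", x$metric_name, "]"),
      ": U = ", format(x$U), ", n = (", x$n_a, ", ", x$n_b, "), p = ",
      format(x$p_two_sided), " (", x$method, ")",
      if (x$significant) "  *", "\n", sep = "")
  invisible(x)
}

#' Median with a distribution-free 95% confidence interval
#'
#' The interval is built from order statistics: with `B ~ binomial(n,
#' 1/2)`, the interval `(x_(l), x_(u))` with symmetric ranks `u = n + 1
#' - l` covers the population median with probability `P(l <= B <= u-1)`.
#' The smallest such interval (largest `l`) with coverage at least
#' `level` is returned. For `n < 6` no symmetric order-statistic
#' interval reaches 95% coverage, so the sample range is returned with
#' a warning.
#'
#' @param x numeric sample.
#' @param level target coverage (default 0.95).
#' @return named numeric vector `c(median, ci_low, ci_high)`.
#' @export
median_with_ci <- function(x, level = 0.95) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty sample")
  if (anyNA(x)) stop("sample must not contain missing values")
  n <- length(x)
  s <- sort(x)
  med <- stats::median(x)
  if (n < 6L) {
    warning("n = ", n, " < 6: order-statistic CI cannot reach ",
            level * 100, "% coverage; reporting the sample range")
    return(c(median = med, ci_low = s[1L], ci_high = s[n]))
  }
  best_l <- NA_integer_
  for (l in seq_len(floor(n / 2))) {
    u <- n + 1L - l
    coverage <- stats::pbinom(u - 1L, n, 0.5) - stats::pbinom(l - 1L, n, 0.5)
    if (coverage >= level) best_l <- l else break
  }
  if (is.na(best_l)) {
    warning("no symmetric order-statistic interval reaches ",
            level * 100, "% coverage; reporting the sample range")
    return(c(median = med, ci_low = s[1L], ci_high = s[n]))
  }
  c(median = med, ci_low = s[best_l], ci_high = s[n + 1L - best_l])
}

canonical_metrics <- c("tEDA", "tESA", "delta_pct_tA", "EDBA", "ESBA",
                       "SA", "EF", "MMI")

#' Compare cohorts metric by metric
#'
#' Runs a two-sided Mann-Whitney test and computes per-group medians
#' with distribution-free 95% confidence intervals for every ventricular
#' metric and every requested group pair. No multiple-testing correction
#' is applied: each comparison is judged at `alpha` on its own, and the
#' output records that policy in the `method` column.
#'
#' @param results_table per-embryo metrics data frame (see
#'   [read_metrics_table()]); must contain a `group` column and the
#'   eight metric columns.
#' @param group_pairs a character vector `c(a, b)` or a list of such
#'   pairs.
#' @param alpha per-comparison significance level (default 0.05).
#' @param method_policy passed to [mann_whitney_u()].
#' @return data frame with one row per (metric, pair), columns
#'   `metric, group_a, group_b, n_a, n_b, U, p, method, median_a,
#'   ci_a_low, ci_a_high, median_b, ci_b_low, ci_b_high, significant`;
#'   metrics appear in canonical order, pairs in the order given.
#' @export
compare_cohorts <- function(results_table, group_pairs, alpha = 0.05,
                            method_policy = "auto") {
  stopifnot(is.data.frame(results_table), "group" %in% names(results_table))
  missing <- setdiff(canonical_metrics, names(results_table))
  if (length(missing) > 0L) {
    stop("results table is missing metric column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.list(group_pairs)) group_pairs <- list(group_pairs)
  rows <- list()
  for (pair in group_pairs) {
    stopifnot(length(pair) == 2L)
    ga <- pair[[1L]]; gb <- pair[[2L]]
    for (g in c(ga, gb)) {
      if (!g %in% results_table$group) {
        stop("unknown group label: '", g, "' (available: ",
             paste(unique(results_table$group), collapse = ", "), ")")
      }
    }
    for (m in canonical_metrics) {
      va <- results_table[results_table$group == ga, m]
      vb <- results_table[results_table$group == gb, m]
      cmp <- mann_whitney_u(va, vb, method_policy = method_policy,
                            alpha = alpha, metric_name = m)
      cia <- suppressWarnings(median_with_ci(va))
      cib <- suppressWarnings(median_with_ci(vb))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group_a = ga, group_b = gb,
        n_a = cmp$n_a, n_b = cmp$n_b, U = cmp$U, p = cmp$p_two_sided,
        method = paste0(cmp$method, ",uncorrected"),
        median_a = cia[["median"]], ci_a_low = cia[["ci_low"]],
        ci_a_high = cia[["ci_high"]],
        median_b = cib[["median"]], ci_b_low = cib[["ci_low"]],
        ci_b_high = cib[["ci_high"]],
        significant = cmp$significant,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a cohort comparison table
#' @param comparisons data frame from [compare_cohorts()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(comparisons, path) {
  stopifnot(is.data.frame(comparisons), nrow(comparisons) > 0L)
  utils::write.csv(comparisons, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
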