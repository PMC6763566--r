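withr_local_tempfile <- function(ext = "") {
  withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
}

withr_local_tempdir <- function() {
  withr::local_tempdir(.local_envir = parent.frame())
}

# Independent oracles used across the suite. Each reimplements the
# quantity it checks by a different route than the package code.

# Scalar even-odd point-in-polygon test casting a vertical ray (the
# package casts a horizontal one), with explicit on-boundary inclusion.
oracle_point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  on_boundary <- FALSE
  crossings <- 0L
  for (k in seq_len(n)) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]
    k2 <- if (k == n) 1L else k + 1L
    x2 <- poly[k2, 1]; y2 <- poly[k2, 2]
    # on-segment?
    d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(d) <= eps * max(1, abs(x2 - x1) + abs(y2 - y1)) &&
        px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
        py >= min(y1, y2) - eps && py <= max(y1, y2) + eps) {
      on_boundary <- TRUE
    }
    # vertical ray toward +y
    if (x1 != x2 && ((x1 > px) != (x2 > px))) {
      yint <- y1 + (px - x1) * (y2 - y1) / (x2 - x1)
      if (py < yint) crossings <- crossings + 1L
    }
  }
  on_boundary || (crossings %% 2L == 1L)
}

# Exhaustive rasterization over a whole frame with the oracle test
oracle_rasterize <- function(poly, shape) {
  h <- shape[1]; w <- shape[2]
  mask <- matrix(FALSE, h, w)
  for (yy in 0:(h - 1)) {
    for (xx in 0:(w - 1)) {
      mask[yy + 1, xx + 1] <- oracle_point_in_polygon(xx, yy, poly)
    }
  }
  mask
}

# Polygon area by fan triangulation from the first vertex (valid for
# convex polygons; used against the shoelace formula)
oracle_fan_area <- function(poly) {
  n <- nrow(poly)
  total <- 0
  for (k in 2:(n - 1)) {
    v1 <- poly[k, ] - poly[1, ]
    v2 <- poly[k + 1, ] - poly[1, ]
    total <- total + abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  unname(total)
}

# Random convex polygon: points on a noisy ellipse, sorted by angle
random_convex_polygon <- function(n_vertices, center, radius) {
  theta <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- radius * stats::runif(1, 0.8, 1)
  cbind(x = center[1] + r * cos(theta), y = center[2] + r * sin(theta))
}

# Brute-force Otsu: histogram values exactly as specified (equal-width
# bins over the observed range), then for every interior bin edge split
# the binned observations and compute w0*w1*(mu0-mu1)^2 naively from
# bin counts and midpoints.
oracle_otsu <- function(values, n_bins) {
  lo <- min(values); hi <- max(values)
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((values - lo) / width) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * width
  n <- length(values)
  crit <- numeric(n_bins - 1L)
  for (j in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:j]); n1 <- n - n0
    if (n0 == 0L || n1 == 0L) { crit[j] <- 0; next }
    w0 <- n0 / n; w1 <- n1 / n
    mu0 <- sum(counts[1:j] * mids[1:j]) / n0
    mu1 <- sum(counts[(j + 1):n_bins] * mids[(j + 1):n_bins]) / n1
    crit[j] <- w0 * w1 * (mu0 - mu1)^2
  }
  list(edges = lo + seq_len(n_bins - 1L) * width, criterion = crit,
       best_edge = lo + which.max(crit) * width, max_criterion = max(crit))
}

# Exact two-sided Mann-Whitney p by direct enumeration: every subset of
# pooled positions is taken as group A and U recomputed by pair counting
# (no rank identity).
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  count_u <- function(av, bv) {
    u <- 0
    for (x in av) for (y in bv) {
      u <- u + (x > y) + 0.5 * (x == y)
    }
    u
  }
  U <- count_u(a, b)
  idx <- utils::combn(na + nb, na)
  u_all <- apply(idx, 2, function(i) count_u(pooled[i], pooled[-i]))
  u_ref <- min(U, na * nb - U)
  list(U = U, p = min(1, 2 * mean(u_all <= u_ref + 1e-9)))
}

# Small fast phantom used by several files
small_phantom <- function(seed = 1, noise_sd = 0.05, ef_true = 50,
                          n_frames = 20L) {
  r_ed <- 30
  r_es <- r_ed * sqrt(1 - ef_true / 100)
  phantom_params(image_shape = c(128L, 128L), n_frames = n_frames,
                 blood_semi_axes_ed = c(r_ed, r_ed),
                 blood_semi_axes_es = c(r_es, r_es),
                 wall_thickness_px = 5, noise_sd = noise_sd, seed = seed)
}
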