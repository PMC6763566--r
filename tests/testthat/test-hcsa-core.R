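make_two_channel_series <- function(weak, strong) {
  # two identical frames so the 2-frame minimum is met
  fr <- array(0, dim = c(dim(weak), 2L))
  fr[, , 1L] <- weak; fr[, , 2L] <- strong
  image_series(list(fr, fr), bit_depth = 16L,
               channel_names = c("weak", "strong"))
}

test_that("channel-difference contrast follows the normalization formula", {
  # channel differences 0.7, -0.1, 0.9 -> series diff range [-0.1, 0.9]
  weak <- matrix(c(0.9, 0.3, 1.0), 1, 3)
  strong <- matrix(c(0.2, 0.4, 0.1), 1, 3)
  series <- make_two_channel_series(weak, strong)
  cfg <- run_config(channel_weak = "weak", channel_strong = "strong")
  cs <- compute_hb_contrast(series, cfg)
  expect_equal(cs$frames[[1]][1, 1], (0.7 - (-0.1)) / 1.0)  # = 0.8
  expect_equal(cs$frames[[1]][1, 2], 0)
  expect_equal(range(unlist(cs$frames)), c(0, 1))
})

test_that("degenerate and misconfigured contrast inputs error", {
  uniform <- image_series(list(matrix(5, 4, 4), matrix(5, 4, 4)),
                          bit_depth = 8L)
  expect_error(compute_hb_contrast(uniform, run_config()),
               "multi-channel")
  expect_error(
    compute_hb_contrast(uniform,
                        run_config(contrast_mode = "single_channel_inverted")),
    "degenerate contrast")
  series <- make_two_channel_series(matrix(1, 2, 2), matrix(0.5, 2, 2))
  expect_error(compute_hb_contrast(series, run_config(channel_weak = "cyan")),
               "configuration error")
})

test_that("phantom blood pool shows higher contrast than myocardium", {
  sim <- simulate_heart_series(small_phantom(seed = 5))
  cs <- compute_hb_contrast(sim$series, run_config())
  p <- sim$params
  h <- p$image_shape[1]; w <- p$image_shape[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xg <- matrix(rep(0:(w - 1), each = h), nrow = h)
  yg <- matrix(rep(0:(h - 1), times = w), nrow = h)
  for (k in seq_len(p$n_frames) - 1L) {
    t <- k * p$interframe_interval_s
    s <- (1 + cos(2 * pi * p$heart_rate_hz * t)) / 2
    a <- p$blood_semi_axes_es[1] + (p$blood_semi_axes_ed[1] -
                                    p$blood_semi_axes_es[1]) * s
    b <- p$blood_semi_axes_es[2] + (p$blood_semi_axes_ed[2] -
                                    p$blood_semi_axes_es[2]) * s
    blood <- ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
    wall <- !blood & (((xg - cx) / (a + p$wall_thickness_px))^2 +
                      ((yg - cy) / (b + p$wall_thickness_px))^2 <= 1)
    fr <- cs$frames[[k + 1L]]
    expect_gt(mean(fr[blood]), mean(fr[wall]))
  }
})

test_that("a two-point distribution is split exactly by the Otsu threshold", {
  vals <- c(rep(0, 50), rep(1, 50))
  thr <- otsu_threshold(vals, 256)
  expect_gt(thr$threshold, 0)
  expect_lt(thr$threshold, 1)
  expect_equal(sum(vals > thr$threshold), 50)
  expect_error(otsu_threshold(rep(3, 10)), "degenerate input")
})

test_that("Otsu equals the brute-force criterion maximizer on bimodal data", {
  set.seed(11)
  vals <- c(rnorm(500, 0.2, 0.05), rnorm(500, 0.8, 0.05))
  thr <- otsu_threshold(vals, 256)
  oracle <- oracle_otsu(vals, 256)
  expect_equal(thr$threshold, oracle$best_edge)
  expect_equal(thr$between_class_variance, oracle$max_criterion,
               tolerance = 1e-12)
  # argmax property: criterion at the returned edge dominates every edge
  expect_true(all(thr$between_class_variance >= oracle$criterion - 1e-12))
})

test_that("Otsu classification is invariant to affine intensity rescaling", {
  set.seed(12)
  vals <- c(runif(300, 0, 0.4), runif(200, 0.6, 1))
  thr <- otsu_threshold(vals, 256)
  for (ab in list(c(3, 2), c(0.25, -1), c(1000, 12345))) {
    scaled <- ab[1] * vals + ab[2]
    thr2 <- otsu_threshold(scaled, 256)
    expect_identical(scaled > thr2$threshold, vals > thr$threshold)
  }
})

test_that("blush counting respects the ROI and is monotone in threshold", {
  square <- cbind(x = c(2, 2, 9, 9), y = c(2, 9, 9, 2))
  mask <- rasterize_polygon(square, c(12L, 12L), frame_index = 0L)
  frame <- matrix(seq(0, 1, length.out = 144), 12, 12)
  expect_equal(measure_blush(frame, mask, 2)$blush_px, 0)
  expect_equal(measure_blush(frame, mask, -1)$blush_px, mask$area_px)
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(t) measure_blush(frame, mask, t)$blush_px,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  b <- measure_blush(frame, mask, 0.5)
  expect_true(b$blush_px >= 0 && b$blush_px <= b$roi_area_px)
  expect_error(measure_blush(matrix(0, 5, 5), mask, 0.5), "shape mismatch")
})

test_that("end-diastolic blush recovers the analytic blood area", {
  sim <- simulate_heart_series(small_phantom(seed = 9, noise_sd = 0.02))
  res <- quantify_series(sim$series, sim$rois, run_config())
  expect_lt(abs(res$metrics$EDBA - sim$truth$EDBA_true) /
              sim$truth$EDBA_true, 0.05)
})
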