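test_that("circular phantom radii give the closed-form ejection fraction", {
  sim_truth <- simulate_heart_series(
    phantom_params(image_shape = c(160, 160), n_frames = 12,
                   blood_semi_axes_ed = c(60, 60),
                   blood_semi_axes_es = c(42.4264, 42.4264),
                   wall_thickness_px = 6, noise_sd = 0))$truth
  expect_equal(sim_truth$EF_true, 100 * (1 - 42.4264^2 / 60^2),
               tolerance = 1e-9)
  expect_equal(sim_truth$EF_true, 50, tolerance = 1e-3)
})

test_that("ground-truth metrics satisfy the algebraic identities exactly", {
  set.seed(41)
  for (rep in 1:10) {
    r_ed <- runif(1, 25, 35)
    shrink <- runif(1, 0.5, 0.9)
    sim <- simulate_heart_series(
      phantom_params(image_shape = c(128, 128), n_frames = 15,
                     blood_semi_axes_ed = c(r_ed, r_ed * 0.9),
                     blood_semi_axes_es = c(r_ed, r_ed * 0.9) * shrink,
                     wall_thickness_px = 5, seed = rep))
    tr <- sim$truth
    expect_identical(tr$SA_true, tr$EDBA_true - tr$ESBA_true)
    expect_identical(tr$EF_true, 100 * tr$SA_true / tr$EDBA_true)
    expect_identical(tr$MMI_true, tr$tESA_true - tr$ESBA_true)
    expect_identical(tr$delta_pct_tA_true,
                     100 * (tr$tEDA_true - tr$tESA_true) / tr$tEDA_true)
    expect_equal(tr$EDBA_true, max(tr$blood_area_px2))
    expect_equal(tr$ESBA_true, min(tr$blood_area_px2))
  }
})

test_that("phantom generation is bit-reproducible per seed", {
  p <- small_phantom(seed = 1234)
  s1 <- simulate_heart_series(p)
  s2 <- simulate_heart_series(p)
  expect_identical(s1$series$frames, s2$series$frames)
  expect_identical(s1$rois$entries, s2$rois$entries)
  s3 <- simulate_heart_series(small_phantom(seed = 1235))
  expect_false(identical(s1$series$frames, s3$series$frames))
})

test_that("a non-beating phantom yields zero stroke and no pulsatility", {
  p <- phantom_params(image_shape = c(96, 96), n_frames = 10,
                      blood_semi_axes_ed = c(25, 25),
                      blood_semi_axes_es = c(25, 25),
                      wall_thickness_px = 5, noise_sd = 0)
  sim <- simulate_heart_series(p)
  expect_equal(sim$truth$SA_true, 0)
  expect_equal(sim$truth$EF_true, 0)
  expect_error(quantify_series(sim$series, sim$rois, run_config()),
               "no pulsatility")
})

test_that("parameter invariants are enforced", {
  expect_error(phantom_params(heart_rate_hz = 2.0),
               "frames per cycle")
  expect_error(phantom_params(n_frames = 3, heart_rate_hz = 2.0),
               "frames per cycle")
  expect_error(phantom_params(blood_semi_axes_es = c(70, 70)),
               "must not exceed")
  expect_error(phantom_params(myocardium_absorption = 0.9),
               "more than myocardium")
  expect_error(phantom_params(noise_sd = -0.1), ">= 0")
  expect_error(phantom_params(blood_semi_axes_ed = c(200, 200)),
               "does not fit")
})

test_that("ROI outlines sit on the analytic extreme frames", {
  sim <- simulate_heart_series(small_phantom(seed = 2))
  roi_frames <- sort(as.integer(names(sim$rois$entries)))
  area <- sim$truth$blood_area_px2
  extremes <- sort(c(which(area == max(area)), which(area == min(area))) - 1L)
  expect_equal(roi_frames, extremes)
  expect_true(sim$truth$ed_frame %in% roi_frames)
  expect_true(sim$truth$es_frame %in% roi_frames)
})

test_that("cohorts have labeled embryos with distinct derived seeds", {
  cohort <- simulate_cohort(small_phantom(), n_per_group = 3L, base_seed = 9)
  expect_equal(nrow(cohort$truth_table), 6L)
  expect_equal(sum(cohort$truth_table$group == "control"), 3L)
  seeds <- vapply(cohort$embryo_params, `[[`, integer(1), "seed")
  expect_equal(length(unique(seeds)), 6L)
  # same base seed reproduces the cohort exactly
  again <- simulate_cohort(small_phantom(), n_per_group = 3L, base_seed = 9)
  expect_identical(cohort$truth_table, again$truth_table)
})

test_that("null cohorts share the generating law; effects shift truth EF", {
  null_cohort <- simulate_cohort(small_phantom(), effect = list(),
                                 n_per_group = 20L, base_seed = 10)
  tt <- null_cohort$truth_table
  expect_equal(mean(tt$EF[tt$group == "control"]),
               mean(tt$EF[tt$group == "treated"]), tolerance = 0.15)

  eff <- simulate_cohort(small_phantom(),
                         effect = list(blood_semi_axes_es = 1.15),
                         n_per_group = 20L, base_seed = 10)
  et <- eff$truth_table
  expect_lt(mean(et$EF[et$group == "treated"]),
            mean(et$EF[et$group == "control"]))
})

test_that("invalid effect multipliers fail naming the embryo", {
  expect_error(
    simulate_cohort(small_phantom(),
                    effect = list(blood_semi_axes_es = 1.6),
                    n_per_group = 2L, base_seed = 1),
    "invalid parameters for embryo treated_")
  expect_error(
    simulate_cohort(small_phantom(), effect = list(bogus = 2),
                    n_per_group = 2L, base_seed = 1),
    "effect names no parameter")
})
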