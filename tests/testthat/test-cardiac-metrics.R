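test_that("phase selection picks trace extremes with 0-based indices", {
  sel <- select_phases(c(3, 9, 5, 1, 7), run_config())
  expect_equal(sel$ed_frame, 1L)
  expect_equal(sel$es_frame, 3L)
  expect_error(select_phases(c(5, 5, 5, 5), run_config()), "no pulsatility")
  # ties break to the earliest frame
  sel2 <- select_phases(c(1, 4, 1, 4), run_config())
  expect_equal(sel2$ed_frame, 1L)
  expect_equal(sel2$es_frame, 0L)
})

test_that("moving-average smoothing changes the picked extremes as computed", {
  trace <- c(0, 10, 0, 6, 5, 6, 0)
  raw <- select_phases(trace, run_config())
  expect_equal(raw$ed_frame, 1L)
  sm <- select_phases(trace, run_config(smoothing_window = 3))
  # centered window-3 average, edges truncated
  expected <- vapply(seq_along(trace), function(i) {
    mean(trace[max(1, i - 1):min(length(trace), i + 1)])
  }, numeric(1))
  expect_equal(sm$blush_trace, expected)
  expect_equal(sm$ed_frame, which.max(expected) - 1L)
  expect_equal(sm$es_frame, which.min(expected) - 1L)
  expect_error(select_phases(c(1, 2), run_config(smoothing_window = 5)),
               "exceeds trace length")
})

test_that("manual phase selection validates and passes indices through", {
  cfg <- run_config(phase_selection = "manual", ed_frame = 2, es_frame = 7)
  sel <- select_phases(rep(0, 10), cfg)
  expect_equal(sel$ed_frame, 2L)
  expect_equal(sel$es_frame, 7L)
  expect_equal(sel$mode, "manual")
  expect_error(select_phases(rep(0, 5), cfg), "out of range")
})

test_that("the worked metric example reproduces by hand arithmetic", {
  m <- ventricle_metrics(ed = c(1000, 800), es = c(600, 200))
  expect_equal(m$delta_pct_tA, 40.0)
  expect_equal(m$SA, 600)
  expect_equal(m$EF, 75.0)
  expect_equal(m$MMI, 400)
})

test_that("a non-contracting heart yields all-zero change metrics", {
  m <- ventricle_metrics(ed = c(800, 500), es = c(800, 500))
  expect_equal(m$SA, 0)
  expect_equal(m$EF, 0)
  expect_equal(m$delta_pct_tA, 0)
  expect_false(m$paradoxical)
})

test_that("undefined metrics and inconsistent areas error", {
  expect_error(ventricle_metrics(ed = c(1000, 0), es = c(600, 100)),
               "undefined ejection fraction")
  expect_error(ventricle_metrics(ed = c(0, 0), es = c(600, 100)),
               "undefined area change")
  expect_error(ventricle_metrics(ed = c(100, 200), es = c(600, 100)),
               "exceeds ROI area")
})

test_that("paradoxical filling is flagged, reported, never clamped", {
  m <- ventricle_metrics(ed = c(1000, 300), es = c(900, 500))
  expect_true(m$paradoxical)
  expect_equal(m$SA, -200)
  expect_lt(m$EF, 0)
})

test_that("algebraic identities hold to machine precision on random areas", {
  set.seed(21)
  for (rep in 1:200) {
    tEDA <- runif(1, 500, 5000)
    tESA <- runif(1, 100, tEDA)
    EDBA <- runif(1, 1, tEDA)
    ESBA <- runif(1, 0, tESA)
    m <- ventricle_metrics(ed = c(tEDA, EDBA), es = c(tESA, ESBA))
    expect_equal(m$SA, EDBA - ESBA)
    expect_equal(m$EF, 100 * (1 - ESBA / EDBA))
    expect_equal(m$delta_pct_tA, 100 * (1 - tESA / tEDA))
    expect_equal(m$MMI + m$ESBA, m$tESA)
  }
})

test_that("EF is scale invariant while SA and MMI scale with area", {
  m1 <- ventricle_metrics(ed = c(1000, 800), es = c(600, 200))
  m2 <- ventricle_metrics(ed = c(2000, 1600), es = c(1200, 400))
  expect_equal(m2$EF, m1$EF)
  expect_equal(m2$delta_pct_tA, m1$delta_pct_tA)
  expect_equal(m2$SA, 2 * m1$SA)
  expect_equal(m2$MMI, 2 * m1$MMI)
  m3 <- scale_metrics(m1, um_per_px = 3)
  expect_equal(m3$SA, 9 * m1$SA)
  expect_equal(m3$EF, m1$EF)
})

test_that("EF and SA decrease strictly as end-systolic emptying worsens", {
  esba <- seq(100, 700, by = 100)  # rising residual blood at fixed EDBA
  ms <- lapply(esba, function(e) {
    ventricle_metrics(ed = c(1000, 800), es = c(900, e))
  })
  efs <- vapply(ms, `[[`, numeric(1), "EF")
  sas <- vapply(ms, `[[`, numeric(1), "SA")
  expect_true(all(diff(efs) < 0))
  expect_true(all(diff(sas) < 0))
})
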