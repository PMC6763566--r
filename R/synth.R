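#' Parameters of the synthetic beating-heart phantom
#'
#' The phantom is a periodically contracting elliptical blood pool
#' surrounded by a myocardial annulus of fixed thickness, imaged in two
#' informative colour channels: the weak-absorption (red) channel is
#' uniformly bright, while the strong-absorption (green/blue) channels
#' are attenuated by `exp(-k)` inside tissue, with `k = hb_absorption`
#' in blood and `k = myocardium_absorption` in the wall. Additive
#' Gaussian sensor noise is expressed as a fraction of the signal
#' level. The blood-pool semi-axes follow a raised-cosine waveform
#' between their end-systolic and end-diastolic values, with `t = 0` at
#' end-diastole:
#' `a(t) = a_es + (a_ed - a_es) * (1 + cos(2 pi f t)) / 2`.
#'
#' Defaults mirror a standard still-series acquisition: 50 frames at
#' 0.2 s. The default heart rate of 0.5 Hz gives 10 frames per cycle
#' (5 full cycles in 50 frames) so that end-diastolic and end-systolic
#' phases fall exactly on sampled frames; the generator requires at
#' least 4 frames per cycle so the extremes are always resolvable. The
#' default geometry (ED radius 60 px, ES radius `60/sqrt(2)`) yields a
#' true ejection fraction of 50%.
#'
#' @param image_shape `c(height, width)`, default 256 x 256.
#' @param n_frames number of frames, default 50.
#' @param interframe_interval_s seconds between frames, default 0.2.
#' @param heart_rate_hz contraction frequency, default 0.5.
#' @param blood_semi_axes_ed,blood_semi_axes_es `c(a, b)` ellipse
#'   semi-axes (px) of the blood pool at end-diastole / end-systole;
#'   ES axes must not exceed ED axes componentwise.
#' @param wall_thickness_px myocardial annulus width (px), default 8.
#' @param hb_absorption attenuation coefficient of the strong channel
#'   in blood, in `[0, 1]`; default 0.7.
#' @param myocardium_absorption same for the wall; must be smaller than
#'   `hb_absorption`; default 0.15.
#' @param noise_sd Gaussian noise standard deviation as a fraction of
#'   the signal level; default 0.05.
#' @param seed integer RNG seed; the generated series is bit-identical
#'   per seed.
#' @return an object of class `PhantomParams`.
#' @export
phantom_params <- function(image_shape = c(256L, 256L),
                           n_frames = 50L,
                           interframe_interval_s = 0.2,
                           heart_rate_hz = 0.5,
                           blood_semi_axes_ed = c(60, 60),
                           blood_semi_axes_es = c(60, 60) / sqrt(2),
                           wall_thickness_px = 8,
                           hb_absorption = 0.7,
                           myocardium_absorption = 0.15,
                           noise_sd = 0.05,
                           seed = 1L) {
  p <- list(image_shape = as.integer(image_shape),
            n_frames = as.integer(n_frames),
            interframe_interval_s = interframe_interval_s,
            heart_rate_hz = heart_rate_hz,
            blood_semi_axes_ed = as.numeric(blood_semi_axes_ed),
            blood_semi_axes_es = as.numeric(blood_semi_axes_es),
            wall_thickness_px = as.numeric(wall_thickness_px),
            hb_absorption = hb_absorption,
            myocardium_absorption = myocardium_absorption,
            noise_sd = noise_sd,
            seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "PhantomParams")
}

validate_phantom_params <- function(p, what = "phantom parameters") {
  with(p, {
    if (length(image_shape) != 2L || any(image_shape < 8L)) {
      stop(what, ": image_shape must be c(height, width), each >= 8")
    }
    if (n_frames < 2L) stop(what, ": n_frames must be >= 2")
    if (interframe_interval_s <= 0) {
      stop(what, ": interframe_interval_s must be > 0")
    }
    if (heart_rate_hz <= 0) stop(what, ": heart_rate_hz must be > 0")
    frames_per_cycle <- 1 / (heart_rate_hz * interframe_interval_s)
    if (frames_per_cycle < 4) {
      stop(what, ": heart period unresolvable -- ",
           format(frames_per_cycle), " frames per cycle, need at least 4")
    }
    if (length(blood_semi_axes_ed) != 2L || length(blood_semi_axes_es) != 2L ||
        any(blood_semi_axes_ed <= 0) || any(blood_semi_axes_es <= 0)) {
      stop(what, ": semi-axes must be positive c(a, b) pairs")
    }
    if (any(blood_semi_axes_es > blood_semi_axes_ed)) {
      stop(what, ": end-systolic semi-axes must not exceed end-diastolic")
    }
    if (wall_thickness_px <= 0) stop(what, ": wall_thickness_px must be > 0")
    if (hb_absorption < 0 || hb_absorption > 1 ||
        myocardium_absorption < 0 || myocardium_absorption > 1) {
      stop(what, ": absorption coefficients must lie in [0, 1]")
    }
    if (myocardium_absorption >= hb_absorption) {
      stop(what, ": blood must absorb more than myocardium")
    }
    if (noise_sd < 0) stop(what, ": noise_sd must be >= 0")
    outer_a <- blood_semi_axes_ed[1L] + wall_thickness_px
    outer_b <- blood_semi_axes_ed[2L] + wall_thickness_px
    cx <- (image_shape[2L] - 1) / 2; cy <- (image_shape[1L] - 1) / 2
    if (outer_a > cx || outer_b > cy) {
      stop(what, ": heart (outer ellipse ", format(outer_a), " x ",
           format(outer_b), " px) does not fit the image")
    }
  })
  invisible(p)
}

# semi-axes at frame k (0-based): raised cosine, t = 0 is end-diastole
phantom_axes_at <- function(p, k) {
  t <- k * p$interframe_interval_s
  s <- (1 + cos(2 * pi * p$heart_rate_hz * t)) / 2
  list(a = p$blood_semi_axes_es[1L] +
         (p$blood_semi_axes_ed[1L] - p$blood_semi_axes_es[1L]) * s,
       b = p$blood_semi_axes_es[2L] +
         (p$blood_semi_axes_ed[2L] - p$blood_semi_axes_es[2L]) * s,
       phase = 2 * pi * p$heart_rate_hz * t)
}

# analytic ground-truth metrics over the sampled frames
phantom_ground_truth <- function(p) {
  k <- seq_len(p$n_frames) - 1L
  ax <- phantom_axes_at(p, k)
  blood_area <- pi * ax$a * ax$b
  ed <- which.max(blood_area)  # earliest analytic maximum
  es <- which.min(blood_area)
  w <- p$wall_thickness_px
  tEDA <- pi * (ax$a[ed] + w) * (ax$b[ed] + w)
  tESA <- pi * (ax$a[es] + w) * (ax$b[es] + w)
  EDBA <- blood_area[ed]; ESBA <- blood_area[es]
  SA <- EDBA - ESBA
  list(blood_area_px2 = blood_area,
       phase = ax$phase,
       ed_frame = ed - 1L, es_frame = es - 1L,
       tEDA_true = tEDA, tESA_true = tESA,
       delta_pct_tA_true = 100 * (tEDA - tESA) / tEDA,
       EDBA_true = EDBA, ESBA_true = ESBA,
       SA_true = SA, EF_true = 100 * SA / EDBA,
       MMI_true = tESA - ESBA)
}

# run code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a beating-heart image series with analytic ground truth
#'
#' Renders the phantom described by [phantom_params()] as a 3-channel
#' 16-bit [image_series()] (red = weak absorption, green and blue =
#' strong absorption), builds a [roi_set()] with 64-gon outlines of the
#' outer (epicardial) ellipse at the analytic end-diastolic and
#' end-systolic frames, and returns the analytic per-frame blood areas
#' and ventricular metrics as the recovery target for the pipeline.
#'
#' @param params a [phantom_params()].
#' @return list with `series` (ImageSeries), `rois` (RoiSet), `truth`
#'   (ground-truth list, see Details), and `params`.
#'
#' @details The `truth` element contains the per-frame analytic blood
#'   area `blood_area_px2`, the phase function, the 0-based
#'   `ed_frame`/`es_frame` of the sampled extremes, and
#'   `tEDA_true, tESA_true, delta_pct_tA_true, EDBA_true, ESBA_true,
#'   SA_true, EF_true, MMI_true`, which satisfy the same algebraic
#'   identities as the measured metrics exactly.
#' @export
simulate_heart_series <- function(params = phantom_params()) {
  stopifnot(inherits(params, "PhantomParams"))
  p <- params
  truth <- phantom_ground_truth(p)
  h <- p$image_shape[1L]; w <- p$image_shape[2L]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xg <- matrix(rep(0:(w - 1L), each = h), nrow = h)   # x at each pixel
  yg <- matrix(rep(0:(h - 1L), times = w), nrow = h)  # y at each pixel
  signal <- 15000  # 14-bit-scale signal level in a 16-bit container
  maxval <- 65535

  frames <- with_seed(p$seed, {
    lapply(seq_len(p$n_frames) - 1L, function(k) {
      ax <- phantom_axes_at(p, k)
      in_blood <- ((xg - cx) / ax$a)^2 + ((yg - cy) / ax$b)^2 <= 1
      in_outer <- ((xg - cx) / (ax$a + p$wall_thickness_px))^2 +
                  ((yg - cy) / (ax$b + p$wall_thickness_px))^2 <= 1
      absorb <- matrix(0, h, w)
      absorb[in_outer] <- p$myocardium_absorption
      absorb[in_blood] <- p$hb_absorption
      strong <- signal * exp(-absorb)
      fr <- array(0, dim = c(h, w, 3L))
      fr[, , 1L] <- signal   # red: weak absorption
      fr[, , 2L] <- strong   # green: strong absorption
      fr[, , 3L] <- strong   # blue: strong absorption
      if (p$noise_sd > 0) {
        fr <- fr + stats::rnorm(length(fr), 0, p$noise_sd * signal)
      }
      fr <- round(fr)
      fr[fr < 0] <- 0
      fr[fr > maxval] <- maxval
      fr
    })
  })
  series <- image_series(frames, bit_depth = 16L,
                         interframe_interval_s = p$interframe_interval_s,
                         channel_names = c("red", "green", "blue"),
                         source_id = paste0("phantom seed ", p$seed))

  outline <- function(k) {
    ax <- phantom_axes_at(p, k)
    theta <- 2 * pi * (0:63) / 64
    cbind(x = cx + (ax$a + p$wall_thickness_px) * cos(theta),
          y = cy + (ax$b + p$wall_thickness_px) * sin(theta))
  }
  # outline every frame whose analytic blood area attains the series
  # extreme: all cycles' ED/ES frames are equivalent segmentation
  # targets, and noise may drive the measured extreme to any of them
  area <- truth$blood_area_px2
  tol <- 1e-9 * max(area)
  extreme <- which(area >= max(area) - tol | area <= min(area) + tol) - 1L
  entries <- list()
  for (k in extreme) entries[[as.character(k)]] <- outline(k)
  rois <- roi_set(entries, image_shape = c(h, w))

  list(series = series, rois = rois, truth = truth, params = p)
}

#' Simulate a two-group cohort with per-embryo biological variability
#'
#' Generates `n_per_group` embryos per group. Group 1 uses the control
#' parameters; group 2 applies the named `effect` multipliers (for
#' example `list(blood_semi_axes_es = 1.15)` models impaired emptying).
#' Each embryo's four blood-pool semi-axes are then jittered by
#' independent lognormal factors (`sdlog = jitter_sdlog`, default 5%)
#' so the groups overlap realistically. All randomness derives
#' deterministically from `base_seed`; each embryo also receives its
#' own derived image seed.
#'
#' @param control a [phantom_params()] describing the control group.
#' @param effect named list of multipliers applied to the second
#'   group's parameters before jitter; multiplied entries must keep the
#'   parameters valid.
#' @param n_per_group embryos per group (scalar or length-2).
#' @param base_seed master seed.
#' @param group_names labels, default `c("control", "treated")`.
#' @param jitter_sdlog lognormal jitter sdlog, default 0.05.
#' @param generate_images render and keep the image series for every
#'   embryo (default `FALSE`: only analytic ground-truth metrics, which
#'   is what cohort-level statistics consume).
#' @return list with `truth_table` (data frame in the standard metrics
#'   table layout, with true metric values), `embryo_params` (list of
#'   per-embryo `PhantomParams`), and, when `generate_images = TRUE`,
#'   `datasets` (list of [simulate_heart_series()] results).
#' @export
simulate_cohort <- function(control = phantom_params(),
                            effect = list(),
                            n_per_group = 30L,
                            base_seed = 1L,
                            group_names = c("control", "treated"),
                            jitter_sdlog = 0.05,
                            generate_images = FALSE) {
  stopifnot(inherits(control, "PhantomParams"))
  n_per_group <- rep_len(as.integer(n_per_group), 2L)
  if (any(n_per_group < 1L)) stop("n_per_group must be >= 1")
  if (length(effect) > 0L && is.null(names(effect))) {
    stop("effect must be a named list of parameter multipliers")
  }
  unknown <- setdiff(names(effect), names(unclass(control)))
  if (length(unknown) > 0L) {
    stop("effect names no parameter: ", paste(unknown, collapse = ", "))
  }

  treated <- unclass(control)
  for (nm in names(effect)) {
    treated[[nm]] <- treated[[nm]] * effect[[nm]]
  }

  rows <- list(); plist <- list(); datasets <- list()
  with_seed(base_seed, {
    for (g in 1:2) {
      base <- if (g == 1L) unclass(control) else treated
      for (i in seq_len(n_per_group[g])) {
        id <- sprintf("%s_%02d", group_names[g], i)
        # the multiplied (pre-jitter) parameters must themselves be valid
        tryCatch(validate_phantom_params(base, what = paste0("embryo ", id)),
                 error = function(e) stop("invalid parameters for embryo ",
                                          id, ": ", conditionMessage(e)))
        jit <- exp(stats::rnorm(4L, 0, jitter_sdlog))
        ep <- base
        ep$blood_semi_axes_ed <- ep$blood_semi_axes_ed * jit[1:2]
        # biological jitter may not undo systole: a jittered ES axis is
        # capped at its ED axis (that axis simply fails to contract)
        ep$blood_semi_axes_es <- pmin(ep$blood_semi_axes_es * jit[3:4],
                                      ep$blood_semi_axes_ed)
        ep$seed <- sample.int(.Machine$integer.max - 1L, 1L)
        ep <- tryCatch({
          validate_phantom_params(ep, what = paste0("embryo ", id))
          structure(ep, class = "PhantomParams")
        }, error = function(e) stop("invalid parameters for embryo ", id,
                                    ": ", conditionMessage(e)))
        truth <- phantom_ground_truth(ep)
        rows[[id]] <- data.frame(
          embryo_id = id, group = group_names[g],
          tEDA = truth$tEDA_true, tESA = truth$tESA_true,
          delta_pct_tA = truth$delta_pct_tA_true,
          EDBA = truth$EDBA_true, ESBA = truth$ESBA_true,
          SA = truth$SA_true, EF = truth$EF_true, MMI = truth$MMI_true,
          ed_frame = truth$ed_frame, es_frame = truth$es_frame,
          stringsAsFactors = FALSE)
        plist[[id]] <- ep
        if (generate_images) datasets[[id]] <- simulate_heart_series(ep)
      }
    }
  })
  out <- list(truth_table = do.call(rbind, c(rows, make.row.names = FALSE)),
              embryo_params = plist)
  if (generate_images) out$datasets <- datasets
  out
}
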