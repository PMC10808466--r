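test_that("background subtraction clips at zero and checks its inputs", {
  fr <- sensor_frame(matrix(c(10, 100, 200), 1, 3), "cyan", timestamp = 30)
  bg <- sensor_frame(matrix(c(15, 40, 0), 1, 3), "cyan")
  out <- subtract_background(fr, bg)
  expect_equal(as.numeric(out), c(0, 60, 200))  # 10 - 15 clips to 0
  expect_equal(attr(out, "timestamp"), 30)
  expect_false(attr(out, "quantized"))
  expect_equal(as.numeric(subtract_background(fr, fr)), c(0, 0, 0))
  zero <- sensor_frame(matrix(0, 1, 3), "cyan")
  expect_equal(as.numeric(subtract_background(fr, zero)),
               as.numeric(fr))
  expect_error(subtract_background(fr, sensor_frame(matrix(0, 1, 3),
                                                    "amber")),
               "channel mismatch")
  expect_error(subtract_background(fr, sensor_frame(matrix(0, 2, 3),
                                                    "cyan")),
               "shapes differ")
})

test_that("ROI means are plain arithmetic means over the rectangle", {
  fr <- sensor_frame(matrix(c(0, 100, 100, 200), 2, 2), "cyan")
  expect_equal(roi_mean_intensity(fr, roi_rect(0, 2, 0, 2)), 100)
  expect_equal(roi_mean_intensity(fr, roi_rect(0, 1, 0, 1)), 0)
  uni <- sensor_frame(matrix(42, 5, 5), "cyan")
  expect_equal(roi_mean_intensity(uni, roi_rect(1, 4, 2, 5)), 42)
  expect_error(roi_mean_intensity(fr, roi_rect(0, 3, 0, 2)),
               "exceeds frame bounds")
  expect_error(roi_rect(0, 0, 0, 2), "empty")
})

test_that("acquisition schedule cycles channels at fixed period", {
  sch <- acquisition_schedule(c("cyan", "amber"), 120, 600)
  expect_equal(nrow(sch), 6 * 2)         # t = 0..600 inclusive, 2 events
  expect_equal(unique(sch$time_s), seq(0, 600, by = 120))
  expect_equal(sch$channel[1:2], c("cyan", "amber"))
  # fixed order holds even if the caller lists amber first
  sch2 <- acquisition_schedule(c("amber", "cyan"), 120, 600)
  expect_equal(sch2$channel[1:2], c("cyan", "amber"))
  one <- acquisition_schedule("cyan", 15, 60)
  expect_equal(nrow(one), 5)             # t = 0, 15, 30, 45, 60
  expect_equal(unique(one$channel), "cyan")
  expect_error(acquisition_schedule("cyan", 5, 60), "below the minimum")
})

test_that("diffusion percentage and intensity ratio follow their ratios", {
  expect_equal(diffusion_percentage(0.1, 0.1), 100)
  expect_equal(diffusion_percentage(0, 0.1), 0)
  expect_equal(diffusion_percentage(0.0344, 0.1), 34.4)
  e <- tryCatch(diffusion_percentage(0.1, 0), error = identity)
  expect_s3_class(e, "gfbsense_undefined_ratio")
  expect_equal(intensity_ratio(100, 100), 1)
  expect_equal(intensity_ratio(50, 100), 0.5)
  expect_s3_class(tryCatch(intensity_ratio(50, 0), error = identity),
                  "gfbsense_undefined_ratio")
})

# build an analysis-ready world: truth curve, gradient illumination,
# stray-light background, all consumed through the public pipeline
analysis_world <- function(sigma = 0, seed = 5, nr = 60, nc = 80) {
  tc <- truth_curve()
  mask <- gradient_mask(nr, nc)
  rois <- small_rois()
  nm <- noise_model(gaussian_sigma = sigma, seed = seed)
  bg <- render_background_frame(mask, nm, channel = "cyan",
                                background_au = 8, seed = seed)
  list(curve = tc, mask = mask, rois = rois, noise = nm, bg = bg,
       background_au = 8)
}

test_that("equal loading on both sides yields a flat 100% series", {
  w <- analysis_world()
  frames <- lapply(c(0, 120, 240), function(t) {
    render_frame(0.5, 0.5, w$curve, w$mask, w$rois, w$noise,
                 timestamp = t, background_au = w$background_au,
                 seed = 17 + t)
  })
  ts <- analyze_timeseries(frames, w$rois, curves = list(cyan = w$curve),
                           masks = list(cyan = w$mask),
                           backgrounds = list(cyan = w$bg))
  expect_s3_class(ts, "barrier_timeseries")
  expect_equal(ts$time_s, c(0, 120, 240))
  expect_true(all(ts$flag_capillary == "ok"))
  expect_equal(ts$capillary_concentration, rep(0.5, 3), tolerance = 0.05)
  expect_equal(ts$filtrate_concentration, rep(0.5, 3), tolerance = 0.05)
  expect_equal(ts$diffusion_percent, rep(100, 3), tolerance = 5)
  expect_equal(ts$intensity_ratio, rep(1, 3), tolerance = 0.02)
})

test_that("a step injection produces the configured exponential rise", {
  w <- analysis_world()
  cfg <- default_config()
  tau <- 120
  trc <- cfg$tracers$cyan
  op <- function(c0) operating_point(ul_min(8), c0)
  eq1 <- steady_state_filtrate_concentration(cfg$geometry, cfg$fluid, trc,
                                             op(0.2))
  times <- seq(0, 600, by = 60)
  cf_true <- transient_response(0, eq1, tau, times)
  frames <- lapply(seq_along(times), function(i) {
    render_frame(0.2, cf_true[i], w$curve, w$mask, w$rois, w$noise,
                 timestamp = times[i], background_au = w$background_au,
                 seed = 23 + i)
  })
  ts <- analyze_timeseries(frames, w$rois, curves = list(cyan = w$curve),
                           masks = list(cyan = w$mask),
                           backgrounds = list(cyan = w$bg),
                           c0 = c(cyan = 0.2))
  ok <- ts$flag_filtrate == "ok"
  expect_gt(mean(ok), 0.6)  # early points sit below the curve floor
  expect_equal(ts$filtrate_concentration[ok], cf_true[ok],
               tolerance = 0.05)
  # the recovered trace rises monotonically toward equilibrium
  expect_true(all(diff(ts$filtrate_concentration[ok]) > -0.002))
})

test_that("saturated and out-of-range points are flagged, not dropped", {
  w <- analysis_world()
  # ROI mean far above the maximum asymptote -> above_range, NA conc
  hot <- sensor_frame(matrix(250, 60, 80), "cyan", timestamp = 0)
  ts <- analyze_timeseries(list(hot), w$rois,
                           curves = list(cyan = w$curve),
                           masks = list(cyan = flat_mask()),
                           backgrounds = list(
                             cyan = sensor_frame(matrix(0, 60, 80),
                                                 "cyan")))
  expect_equal(ts$flag_capillary, "above_range")
  expect_true(is.na(ts$capillary_concentration))
  expect_equal(nrow(ts), 1)  # the pipeline continues, nothing dropped
  # in-range mean but > 1% of ROI pixels pinned at 255 -> saturated flag
  px <- matrix(100, 60, 80)
  px[11:13, 11:30] <- 255    # 60 of 800 capillary ROI pixels
  part <- sensor_frame(px, "cyan", timestamp = 0)
  ts2 <- analyze_timeseries(list(part), w$rois,
                            curves = list(cyan = w$curve),
                            masks = list(cyan = flat_mask()),
                            backgrounds = list(
                              cyan = sensor_frame(matrix(0, 60, 80),
                                                  "cyan")))
  expect_equal(ts2$flag_capillary, "saturated")
  expect_false(is.na(ts2$capillary_concentration))
})

test_that("a blank run never reports concentrations above the floor", {
  w <- analysis_world(sigma = 1)
  conc <- 10^seq(-4, 1, length.out = 10)
  ds <- generate_calibration_dataset(w$curve, conc, 3,
                                     noise_model(2, seed = 31))
  fit <- fit_4pl(ds)
  sr <- sensitivity_region(fit)
  frames <- lapply(1:5, function(i) {
    render_frame(0, 0, w$curve, w$mask, w$rois, w$noise,
                 timestamp = (i - 1) * 120,
                 background_au = w$background_au, seed = 400 + i)
  })
  ts <- analyze_timeseries(frames, w$rois, curves = list(cyan = fit),
                           masks = list(cyan = w$mask),
                           backgrounds = list(cyan = w$bg))
  below <- is.na(ts$filtrate_concentration) |
    ts$filtrate_concentration < sr$lower
  expect_true(all(below))
  expect_true(all(ts$flag_filtrate %in% c("below_range", "ok")))
})

test_that("missing per-channel configuration is a hard error", {
  w <- analysis_world()
  fr <- render_frame(0.5, 0.5, w$curve, w$mask, w$rois, w$noise, seed = 1)
  expect_error(
    analyze_timeseries(list(fr), w$rois, curves = list(),
                       masks = list(cyan = w$mask),
                       backgrounds = list(cyan = w$bg)),
    "missing calibration curve, mask or background.*cyan")
})
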