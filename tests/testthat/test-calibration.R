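test_that("4PL evaluation honours its closed form and limit conventions", {
  cv <- calibration_curve(a = 5, b = 1, c = 0.5, d = 205)
  expect_equal(eval_4pl(cv, 1.5), 155)                 # 5 + 200/(1+3)
  expect_equal(eval_4pl(cv, cv$c), (cv$a + cv$d) / 2)  # midpoint
  expect_equal(eval_4pl(cv, 0), cv$a)                  # x = 0 limit, b > 0
  dec <- calibration_curve(a = 220, b = -1.2, c = 0.5, d = 5)
  expect_equal(eval_4pl(dec, 0), dec$d)                # roles swap, b < 0
  expect_error(eval_4pl(cv, -0.1), "must be >= 0")
})

test_that("4PL is strictly monotone with direction sign(b) * sign(d - a)", {
  set.seed(42)
  xs <- 10^seq(-3, 2, length.out = 40)
  for (i in 1:25) {
    cv <- random_curve()
    dy <- diff(eval_4pl(cv, xs))
    dir <- sign(cv$b) * sign(cv$d - cv$a)
    expect_true(all(sign(dy) == dir),
                info = sprintf("a=%g b=%g c=%g d=%g", cv$a, cv$b, cv$c,
                               cv$d))
  }
})

test_that("inversion matches the bisection oracle and round-trips", {
  cv <- calibration_curve(a = 5, b = 1, c = 0.5, d = 205)
  expect_equal(invert_4pl(cv, 155), 1.5, tolerance = 1e-9)
  expect_equal(invert_4pl(cv, 155), bisect_invert(cv, 155),
               tolerance = 1e-9)
  expect_equal(invert_4pl(cv, (cv$a + cv$d) / 2), cv$c, tolerance = 1e-12)
  # just above the minimum asymptote the concentration collapses to 0+
  expect_lt(invert_4pl(cv, cv$a + 1e-7), 1e-8)
  set.seed(7)
  for (i in 1:25) {
    rc <- random_curve()
    for (x in rc$c * 10^runif(4, -2, 2)) {
      expect_equal(invert_4pl(rc, eval_4pl(rc, x)), x,
                   tolerance = 1e-9)
    }
  }
})

test_that("inversion refuses intensities outside the open asymptote range", {
  cv <- calibration_curve(a = 5, b = 1, c = 0.5, d = 205)
  e_lo <- tryCatch(invert_4pl(cv, 4), error = identity)
  expect_s3_class(e_lo, "gfbsense_out_of_range")
  expect_identical(e_lo$violated, "lower")
  expect_match(conditionMessage(e_lo), "minimum asymptote")
  e_hi <- tryCatch(invert_4pl(cv, 205), error = identity)
  expect_s3_class(e_hi, "gfbsense_out_of_range")
  expect_identical(e_hi$violated, "upper")
})

test_that("fitting recovers exact-model parameters to 1e-6 relative", {
  conc <- 10^seq(-3, 1, length.out = 8)
  for (tc in list(truth_curve(),
                  calibration_curve(a = 180, b = -0.8, c = 0.2, d = 12))) {
    ds <- calibration_dataset(rep(conc, each = 3),
                              rep(eval_4pl(tc, conc), each = 3))
    fit <- canonical_4pl(fit_4pl(ds))
    tcc <- canonical_4pl(tc)
    for (p in c("a", "b", "c", "d")) {
      expect_equal(fit[[p]], tcc[[p]], tolerance = 1e-6,
                   info = sprintf("param %s", p))
    }
    expect_gt(fit$r_squared, 1 - 1e-9)
  }
})

test_that("fitting under noise tracks the grid-search oracle", {
  tc <- truth_curve()
  conc <- 10^seq(-3, 1, length.out = 8)
  ds <- generate_calibration_dataset(tc, conc, replicates = 3,
                                     noise_model(gaussian_sigma = 2,
                                                 seed = 101))
  fit <- canonical_4pl(fit_4pl(ds))
  expect_lt(abs(fit$c - tc$c) / tc$c, 0.10)
  oracle <- grid_fit_4pl(ds$concentration, ds$intensity)
  expect_lt(abs(oracle$c - tc$c) / tc$c, 0.10)
  # the analytic fit must be at least as good as the coarse grid search
  rss_fit <- sum((ds$intensity - eval_4pl(fit, ds$concentration))^2)
  expect_lte(rss_fit, oracle$rss * (1 + 1e-6))
  # asymptotic CIs bracket the point estimates
  expect_true(all(fit_4pl(ds)$param_ci95["lower", ] <=
                    unlist(fit_4pl(ds)[c("a", "b", "c", "d")])))
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(calibration_dataset(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "at least 5 distinct")
  conc <- 10^seq(-2, 1, length.out = 6)
  flat <- calibration_dataset(conc, rep(100, 6))
  expect_error(fit_4pl(flat), "degenerate|no signal")
  expect_error(calibration_dataset(c(-1, 1, 2, 3, 4, 5), rep(1, 6)),
               "strictly positive")
})

test_that("illumination mask estimation matches the worked multipliers", {
  mk <- function(v) sensor_frame(matrix(v, 1, 3, byrow = TRUE), "cyan")
  frames <- list(mk(c(50, 100, 150)), mk(c(50, 100, 150)),
                 mk(c(50, 100, 150)))
  mask <- estimate_illumination_mask(frames)
  expect_equal(as.numeric(unclass(mask)), c(2, 1, 2 / 3),
               tolerance = 1e-12)
  # already-flat frames give the identity mask
  uni <- lapply(1:3, function(i) sensor_frame(matrix(100, 4, 5), "cyan"))
  expect_equal(as.numeric(unclass(estimate_illumination_mask(uni))),
               rep(1, 20))
  # a dead pixel is a hard error naming its coordinates
  dead <- lapply(1:3, function(i) {
    m <- matrix(100, 4, 5); m[2, 3] <- 0
    sensor_frame(m, "cyan")
  })
  expect_error(estimate_illumination_mask(dead), "\\(2, 3\\)")
  expect_error(estimate_illumination_mask(uni[1:2]), "at least 3")
  mixed <- c(uni[1:2], list(sensor_frame(matrix(100, 4, 5), "amber")))
  expect_error(estimate_illumination_mask(mixed), "same LED channel")
})

test_that("mask correction flattens the field and is idempotent", {
  set.seed(3)
  field <- outer(seq(0.6, 1.4, length.out = 30),
                 seq(0.8, 1.2, length.out = 40))
  frames <- lapply(1:3, function(i) {
    sensor_frame(120 * field, "cyan", quantized = FALSE)
  })
  mask <- estimate_illumination_mask(frames)
  corrected <- apply_mask(frames[[1]], mask)
  cv_spatial <- stats::sd(corrected) / mean(corrected)
  expect_lt(cv_spatial, 1e-9)
  # global intensity level is preserved by the normalization convention
  expect_equal(mean(corrected), mean(unclass(frames[[1]])))
  # re-estimating from corrected frames gives the identity mask
  mask2 <- estimate_illumination_mask(lapply(1:3, function(i) corrected))
  expect_equal(as.numeric(unclass(mask2)), rep(1, length(mask2)),
               tolerance = 1e-9)
})

test_that("apply_mask is a checked pixelwise product", {
  fr <- sensor_frame(matrix(c(50, 100, 150), 1, 3), "cyan")
  mask <- illumination_mask(matrix(c(2, 1, 2 / 3), 1, 3))
  expect_equal(as.numeric(apply_mask(fr, mask)), c(100, 100, 100))
  ones <- illumination_mask(matrix(1, 1, 3))
  expect_equal(as.numeric(apply_mask(fr, ones)), c(50, 100, 150))
  zero <- sensor_frame(matrix(0, 1, 3), "cyan")
  expect_equal(as.numeric(apply_mask(zero, mask)), c(0, 0, 0))
  expect_false(attr(apply_mask(fr, mask), "quantized"))
  expect_error(apply_mask(fr, illumination_mask(matrix(1, 2, 2))),
               "shapes differ")
})

test_that("concentration error reverse-maps the regression error", {
  cv <- calibration_curve(a = 5, b = 1, c = 0.5, d = 205,
                          se_regression = 4)
  # frozen from the bisection oracle: (invert(159) - invert(151)) / 2
  expect_equal(as.numeric(concentration_error(cv, 155)), 0.161030595813,
               tolerance = 1e-9)
  expect_false(attr(concentration_error(cv, 155), "one_sided"))
  cv0 <- calibration_curve(a = 5, b = 1, c = 0.5, d = 205,
                           se_regression = 0)
  expect_identical(as.numeric(concentration_error(cv0, 155)), 0)
  # near the floor only the upper side is invertible -> one-sided result
  near_floor <- concentration_error(cv, 7, se = 4)
  expect_true(attr(near_floor, "one_sided"))
  expect_s3_class(tryCatch(concentration_error(cv, 2, se = 1),
                           error = identity),
                  "gfbsense_out_of_range")
})

test_that("sensitivity region brackets the steep part of the curve", {
  tc <- truth_curve()
  conc <- 10^seq(-4, 1, length.out = 10)
  ds <- generate_calibration_dataset(tc, conc, replicates = 3,
                                     noise_model(gaussian_sigma = 3,
                                                 seed = 11))
  fit <- fit_4pl(ds)
  sr <- sensitivity_region(fit)
  expect_lt(sr$lower, fit$c)
  expect_gt(sr$upper, fit$c)
  expect_gt(sr$lower, 0)
  # agreement with the independent bisection inversion of the CI edge of
  # the asymptote reached at x -> 0 (a for b > 0, d for b < 0)
  p0 <- if (fit$b > 0) "a" else "d"
  pinf <- setdiff(c("a", "d"), p0)
  edge0 <- if (fit[[pinf]] > fit[[p0]]) fit$param_ci95["upper", p0] else
    fit$param_ci95["lower", p0]
  expect_equal(sr$lower, bisect_invert(fit, edge0), tolerance = 1e-6)
  expect_false(sr$unbounded_lower || sr$unbounded_upper)
  expect_gt(sr$lower_err, 0)
})

test_that("degenerate and decreasing curves keep the region ordered", {
  # noiseless fit: zero-width CIs collapse the region to (0, Inf)
  tc <- truth_curve()
  conc <- 10^seq(-3, 1, length.out = 8)
  ds <- calibration_dataset(conc, eval_4pl(tc, conc))
  sr0 <- sensitivity_region(fit_4pl(ds))
  expect_true(sr0$unbounded_lower)
  expect_true(sr0$unbounded_upper)
  expect_identical(sr0$lower, 0)
  expect_identical(sr0$upper, Inf)
  # decreasing response (a > d): bounds still ordered
  dec <- calibration_curve(a = 220, b = 1.2, c = 0.5, d = 5,
                           se_regression = 2,
                           param_ci95 = matrix(
                             c(218, 222, 1.0, 1.4, 0.45, 0.55, 4, 6), 2,
                             dimnames = list(c("lower", "upper"),
                                             c("a", "b", "c", "d"))))
  srd <- sensitivity_region(dec)
  expect_lt(srd$lower, srd$upper)
  expect_gt(srd$lower, 0)
})
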