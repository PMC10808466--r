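# Shared fixtures: small frames keep the suite fast; the physics does not
# depend on frame size.

truth_curve <- function(channel = "cyan") {
  calibration_curve(a = 5, b = 1.2, c = 0.5, d = 220,
                    channel_label = channel)
}

# 60 x 80 test frames with two 40 x 20 ROIs
small_rois <- function() {
  roi_set(capillary = roi_rect(10, 50, 10, 30),
          filtrate = roi_rect(10, 50, 50, 70))
}

flat_mask <- function(nr = 60, nc = 80, channel = "cyan") {
  illumination_mask(matrix(1, nr, nc), channel = channel)
}

# smooth, clearly uneven illumination correction field
gradient_mask <- function(nr = 60, nc = 80, channel = "cyan") {
  field <- outer(seq(0.7, 1.3, length.out = nr),
                 seq(0.85, 1.15, length.out = nc))
  illumination_mask(mean(field) / field, channel = channel)
}

default_config <- function() load_config(default_chip_config())

ul_min <- function(x) x / 6e4   # uL/min -> mL/s

# Independent inversion oracle: log-scale bisection on eval_4pl, blind to
# the closed-form inverse.
bisect_invert <- function(curve, f, lo = 1e-12, hi = 1e6) {
  g <- function(x) eval_4pl(curve, x) - f
  stopifnot(g(lo) * g(hi) < 0)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (g(mid) * g(lo) <= 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# Independent 4PL fit oracle: coarse grid over (b, c); (a, d) solved by
# linear least squares since F is linear in the asymptotes given (b, c).
grid_fit_4pl <- function(x, y, b_grid = seq(0.3, 3, by = 0.05),
                         c_grid = exp(seq(log(1e-3), log(10),
                                          length.out = 120))) {
  best <- list(rss = Inf)
  for (b in b_grid) {
    for (cc in c_grid) {
      w <- 1 / (1 + (x / cc)^b)
      X <- cbind(a = w, d = 1 - w)
      fit <- stats::lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) {
        best <- list(rss = rss, a = fit$coefficients[["a"]],
                     b = b, c = cc, d = fit$coefficients[["d"]])
      }
    }
  }
  best
}

# Map a fitted 4PL to the canonical representation with b > 0 (the model
# is invariant under (a, b, c, d) -> (d, -b, c, a)).
canonical_4pl <- function(curve) {
  if (curve$b < 0) {
    calibration_curve(a = curve$d, b = -curve$b, c = curve$c, d = curve$a,
                      channel_label = curve$channel_label,
                      r_squared = curve$r_squared,
                      se_regression = curve$se_regression)
  } else curve
}

random_curve <- function() {
  a <- runif(1, 0, 30)
  d <- a + runif(1, 50, 230)
  if (runif(1) < 0.5) { tmp <- a; a <- d; d <- tmp }
  calibration_curve(a = a, b = sample(c(-1, 1), 1) * runif(1, 0.4, 3),
                    c = 10^runif(1, -2, 1), d = d)
}
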