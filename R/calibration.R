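#' Four-parameter logistic (4PL) dose-response model
#'
#' The sensor's pixel intensity responds sigmoidally to tracer
#' concentration and is modelled by the four-parameter logistic
#'
#' \deqn{F(x) = d + \frac{a - d}{1 + (x/c)^b}}
#'
#' where `F(x)` is pixel intensity (AU), `x` is concentration (mg/mL),
#' `a` the minimum asymptote (AU), `b` the Hill slope, `c` the
#' half-maximal concentration (mg/mL) and `d` the maximum asymptote (AU).
#' At `x = 0` the limit `F(0) = a` is used for `b > 0`; negative `b`
#' (decreasing curves) is permitted, with the asymptote roles swapped by
#' the sign convention.
#'
#' @name four_pl
NULL

#' Calibration dataset
#'
#' Replicate mean-ROI intensities measured at a serial dilution of one
#' tracer.  At least five distinct, strictly positive concentrations are
#' required for the 4PL fit to be identifiable.
#'
#' @param concentration Numeric vector of tracer concentrations (mg/mL),
#'   one entry per measurement (replicates repeat the concentration).
#' @param intensity Numeric vector of mean ROI pixel intensities (AU).
#' @param replicate Optional integer replicate index; defaults to numbering
#'   within each concentration.
#' @return A `data.frame` of class `calibration_dataset` with columns
#'   `concentration`, `replicate`, `intensity`.
#' @export
calibration_dataset <- function(concentration, intensity, replicate = NULL) {
  if (length(concentration) != length(intensity)) {
    stop("`concentration` and `intensity` must have equal length",
         call. = FALSE)
  }
  if (any(concentration <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (length(unique(concentration)) < 5L) {
    stop("at least 5 distinct concentrations are required", call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(concentration), concentration,
                            FUN = seq_along)
  }
  structure(data.frame(concentration = as.numeric(concentration),
                       replicate = as.integer(replicate),
                       intensity = as.numeric(intensity)),
            class = c("calibration_dataset", "data.frame"))
}

#' Construct a calibration curve object directly
#'
#' Normally produced by [fit_4pl()]; direct construction is useful for
#' simulation ground truth and testing.
#'
#' @param a,b,c,d 4PL parameters (see [four_pl]).
#' @param channel_label Fluorophore / LED channel identifier.
#' @param r_squared,se_regression Goodness-of-fit summaries; `NA` when the
#'   curve is a stated truth rather than a fit.
#' @param param_ci95 2 x 4 matrix of lower/upper 95% confidence bounds,
#'   columns named `a`, `b`, `c`, `d`.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(a, b, c, d, channel_label = "cyan",
                              r_squared = NA_real_,
                              se_regression = NA_real_,
                              param_ci95 = NULL) {
  if (c <= 0) stop("`c` (half-maximal concentration) must be > 0",
                   call. = FALSE)
  if (a == d) stop("asymptotes `a` and `d` must differ", call. = FALSE)
  if (b == 0) stop("Hill slope `b` must be non-zero", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("`r_squared` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(param_ci95)) {
    param_ci95 <- matrix(NA_real_, 2, 4,
                         dimnames = list(c("lower", "upper"),
                                         c("a", "b", "c", "d")))
  } else {
    est <- c(a = a, b = b, c = c, d = d)
    bad <- !is.na(param_ci95[1, ]) &
      (param_ci95[1, ] > est | est > param_ci95[2, ])
    if (any(bad)) {
      stop("param_ci95 must bracket the point estimates (violated for: ",
           paste(names(est)[bad], collapse = ", "), ")", call. = FALSE)
    }
  }
  structure(list(channel_label = channel_label,
                 a = a, b = b, c = c, d = d,
                 r_squared = r_squared,
                 se_regression = se_regression,
                 param_ci95 = param_ci95),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("<calibration_curve [%s]: a = %.4g, b = %.4g, ",
                     "c = %.4g mg/mL, d = %.4g; R2 = %.4f, se = %.3g AU>\n"),
              x$channel_label, x$a, x$b, x$c, x$d,
              x$r_squared, x$se_regression))
  invisible(x)
}

#' Evaluate the 4PL calibration curve
#'
#' @param curve A [calibration_curve()].
#' @param x Concentration(s), mg/mL, `>= 0`.
#' @return Predicted pixel intensity (AU); `F(0) = a` by the limit
#'   convention.
#' @export
eval_4pl <- function(curve, x) {
  if (any(x < 0)) stop("concentration `x` must be >= 0", call. = FALSE)
  out <- curve$d + (curve$a - curve$d) / (1 + (x / curve$c)^curve$b)
  # x = 0 limit: F(0) = a for b > 0; for b < 0 the asymptote roles swap
  # and (x/c)^b -> Inf already yields F(0) = d from the arithmetic.
  if (curve$b > 0) out[x == 0] <- curve$a
  out
}

#' Invert the 4PL calibration curve
#'
#' Maps a measured intensity back to concentration,
#' `x = c * ((a - d) / (f - d) - 1)^(1/b)`.  `f` must lie strictly between
#' the asymptotes; out-of-range intensities raise a condition of class
#' `gfbsense_out_of_range` carrying which asymptote was violated.  The
#' library never silently clamps: the caller decides how to treat
#' saturated or sub-floor readings.
#'
#' @param curve A [calibration_curve()].
#' @param f Measured intensity (AU), strictly inside
#'   `(min(a, d), max(a, d))`.
#' @return Concentration, mg/mL.
#' @export
invert_4pl <- function(curve, f) {
  lo <- min(curve$a, curve$d)
  hi <- max(curve$a, curve$d)
  bad_lo <- f <= lo
  bad_hi <- f >= hi
  if (any(bad_lo | bad_hi)) {
    side <- if (any(bad_lo)) lo else hi
    which_par <- if (side == curve$a) "a (minimum asymptote)" else
      "d (maximum asymptote)"
    cond <- structure(
      class = c("gfbsense_out_of_range", "error", "condition"),
      list(message = sprintf(
             "intensity %g outside invertible range (%g, %g): violates %s",
             f[which(bad_lo | bad_hi)[1]], lo, hi, which_par),
           call = sys.call(-1),
           violated = if (any(bad_lo)) "lower" else "upper"))
    stop(cond)
  }
  curve$c * ((curve$a - curve$d) / (f - curve$d) - 1)^(1 / curve$b)
}

#' Fit the 4PL calibration curve to a dilution series
#'
#' Least squares on the linear intensity scale via `nls()` (port
#' algorithm, bounded so `c > 0`) with multi-start initialization:
#' `a` at the minimum observed intensity, `d` at the maximum, `c` at the
#' geometric mean of the concentrations and Hill slopes
#' `b in {0.5, 1, 2, -0.5, -1, -2}`.  The best converged start by residual
#' sum of squares wins.  95% confidence intervals come from the asymptotic
#' (Jacobian-based) covariance of the fit.
#'
#' @param dataset A [calibration_dataset()] (or data.frame with
#'   `concentration` and `intensity` columns).
#' @param channel_label Stored on the returned curve.
#' @return A [calibration_curve()] with `r_squared`, `se_regression` and
#'   `param_ci95` populated.
#' @export
fit_4pl <- function(dataset, channel_label = "cyan") {
  x <- dataset$concentration
  y <- dataset$intensity
  if (length(unique(x)) < 5L) {
    stop("at least 5 distinct concentrations are required", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("degenerate fit: all intensities are equal (no signal)",
         call. = FALSE)
  }
  dat <- data.frame(x = x, y = y)
  c0 <- exp(mean(log(x)))
  starts <- expand.grid(b0 = c(0.5, 1, 2, -0.5, -1, -2),
                        KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  last_rss <- NA_real_
  for (b0 in starts$b0) {
    st <- list(a = min(y), b = b0, c = c0, d = max(y))
    fit <- tryCatch(
      stats::nls(y ~ d + (a - d) / (1 + (x / c)^b),
                 data = dat, start = st, algorithm = "port",
                 lower = c(a = -Inf, b = -Inf, c = .Machine$double.xmin,
                           d = -Inf),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    last_rss <- rss
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop(sprintf("4PL fit failed to converge from any start (last residual norm: %s)",
                 ifelse(is.na(last_rss), "none", format(sqrt(last_rss)))),
         call. = FALSE)
  }
  fit <- best$fit
  est <- stats::coef(fit)
  n <- length(y)
  dfres <- n - 4L
  rss <- best$rss
  tss <- sum((y - mean(y))^2)
  se_reg <- sqrt(rss / dfres)
  # asymptotic 95% CI from the Jacobian-based covariance
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  ci <- matrix(NA_real_, 2, 4,
               dimnames = list(c("lower", "upper"), c("a", "b", "c", "d")))
  if (!is.null(vc)) {
    se_par <- sqrt(pmax(diag(vc), 0))
    tq <- stats::qt(0.975, dfres)
    ci["lower", ] <- est[c("a", "b", "c", "d")] - tq * se_par
    ci["upper", ] <- est[c("a", "b", "c", "d")] + tq * se_par
  }
  calibration_curve(a = est[["a"]], b = est[["b"]], c = est[["c"]],
                    d = est[["d"]], channel_label = channel_label,
                    r_squared = max(0, min(1, 1 - rss / tss)),
                    se_regression = se_reg,
                    param_ci95 = ci)
}

#' Estimate the flat-field illumination mask
#'
#' LED illumination across the field of view is uneven; at a uniform
#' tracer concentration the pixelwise mean of several frames maps that
#' unevenness.  The per-pixel multiplier is
#' `global mean of the pixelwise-mean image / pixelwise mean`, so that
#' applying the mask flattens the calibration image while preserving its
#' global intensity level.  One mask is estimated per LED channel, since
#' each LED has its own illumination field.
#'
#' @param frames List of at least 3 [sensor_frame()]s of one uniform
#'   concentration, same shape and LED channel.
#' @return An `illumination_mask`: a positive numeric matrix of
#'   multipliers with the source channel as attribute.
#' @export
estimate_illumination_mask <- function(frames) {
  if (length(frames) < 3L) {
    stop("at least 3 frames are required to estimate the mask",
         call. = FALSE)
  }
  ch <- unique(vapply(frames, frame_channel, character(1)))
  if (length(ch) != 1L) {
    stop("all mask frames must come from the same LED channel",
         call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) {
    stop("all mask frames must have the same shape", call. = FALSE)
  }
  pixmean <- Reduce(`+`, lapply(frames, unclass)) / length(frames)
  if (any(pixmean <= 0)) {
    idx <- which(pixmean <= 0, arr.ind = TRUE)
    show <- utils::head(idx, 5)
    stop(sprintf(
      "degenerate pixels with zero mean intensity at (row, col): %s%s",
      paste(apply(show, 1, function(r) sprintf("(%d, %d)", r[1], r[2])),
            collapse = ", "),
      if (nrow(idx) > 5) sprintf(" and %d more", nrow(idx) - 5) else ""),
      call. = FALSE)
  }
  mult <- mean(pixmean) / pixmean
  illumination_mask(mult, channel = ch)
}

#' @rdname estimate_illumination_mask
#' @param multipliers Positive numeric matrix of per-pixel correction
#'   factors.
#' @param channel LED channel the mask corrects.
#' @export
illumination_mask <- function(multipliers, channel = "cyan") {
  if (!is.matrix(multipliers) || any(multipliers <= 0)) {
    stop("mask multipliers must form a strictly positive matrix",
         call. = FALSE)
  }
  structure(multipliers, channel = channel,
            class = c("illumination_mask", "matrix", "array"))
}

#' Apply a flat-field mask to a frame
#'
#' Pixelwise product; the result is a float frame (never re-quantized to
#' 8-bit).
#'
#' @param frame A [sensor_frame()].
#' @param mask An [illumination_mask()] of the same shape.
#' @return A float [sensor_frame()].
#' @export
apply_mask <- function(frame, mask) {
  if (!all(dim(frame) == dim(mask))) {
    stop("frame and mask shapes differ", call. = FALSE)
  }
  sensor_frame(unclass(frame) * unclass(mask),
               led_channel = frame_channel(frame),
               timestamp = frame_time(frame),
               quantized = FALSE)
}

#' Concentration-scale read error at a given intensity
#'
#' Reverse-maps the standard error of the regression into concentration
#' units: the half-width `|invert(f + se) - invert(f - se)| / 2`.  When
#' only one side of the band is invertible (near an asymptote) the
#' one-sided distance `|invert(f +- se) - invert(f)|` is returned and the
#' result carries attribute `one_sided = TRUE`.
#'
#' @param curve A fitted [calibration_curve()] with `se_regression`.
#' @param f Intensity (AU) at which to evaluate the error.
#' @param se Intensity-scale standard error; defaults to the curve's
#'   `se_regression`.
#' @return Concentration error (mg/mL), with attribute `one_sided`.
#' @export
concentration_error <- function(curve, f, se = curve$se_regression) {
  if (is.na(se)) stop("curve has no `se_regression`", call. = FALSE)
  if (se == 0) return(structure(0, one_sided = FALSE))
  up <- tryCatch(invert_4pl(curve, f + se), error = function(e) NULL)
  dn <- tryCatch(invert_4pl(curve, f - se), error = function(e) NULL)
  if (!is.null(up) && !is.null(dn)) {
    return(structure(abs(up - dn) / 2, one_sided = FALSE))
  }
  mid <- tryCatch(invert_4pl(curve, f), error = function(e) NULL)
  one <- if (!is.null(up)) up else dn
  if (is.null(one) || is.null(mid)) {
    cond <- structure(
      class = c("gfbsense_out_of_range", "error", "condition"),
      list(message = sprintf(
        "neither f + se nor f - se is invertible at f = %g, se = %g", f, se),
        call = sys.call(-1)))
    stop(cond)
  }
  structure(abs(one - mid), one_sided = TRUE)
}

#' Sensitivity region of the sensor for one tracer
#'
#' The concentration interval over which inverted readings are reliable,
#' obtained by reverse-mapping the 95% confidence limits of the two
#' asymptotes through the fitted curve: the lower bound inverts the CI
#' edge of the minimum asymptote nearest the interior of the response,
#' the upper bound the interior-side CI edge of the maximum asymptote.
#' `lower_err` / `upper_err` propagate the regression standard error via
#' [concentration_error()] at those intensities.
#'
#' A noiseless fit has zero-width CIs: the edges coincide with the
#' asymptotes themselves, the region degenerates to `(0, Inf)` and is
#' flagged unbounded rather than raising an error.
#'
#' @param curve A fitted [calibration_curve()] with `param_ci95`.
#' @return An object of class `sensitivity_region` with fields `lower`,
#'   `upper`, `lower_err`, `upper_err`, `unbounded_lower`,
#'   `unbounded_upper`.
#' @export
sensitivity_region <- function(curve) {
  ci <- curve$param_ci95
  if (anyNA(ci[, c("a", "d")])) {
    stop("curve has no asymptote confidence intervals", call. = FALSE)
  }
  # the asymptote reached at x -> 0 is `a` for b > 0 and `d` for b < 0
  p0 <- if (curve$b > 0) "a" else "d"
  pinf <- setdiff(c("a", "d"), p0)
  f0 <- curve[[p0]]
  finf <- curve[[pinf]]
  # interior-side CI edge: the edge of each asymptote facing the other
  a_edge <- if (finf > f0) ci["upper", p0] else ci["lower", p0]
  d_edge <- if (finf > f0) ci["lower", pinf] else ci["upper", pinf]
  inv_or_null <- function(f, asymptote) {
    # an edge numerically indistinguishable from its asymptote (zero-width
    # CI, e.g. a noiseless fit) maps to an unbounded concentration
    if (abs(f - asymptote) <= 1e-9 * abs(finf - f0)) return(NULL)
    tryCatch(invert_4pl(curve, f), error = function(e) NULL)
  }
  low <- inv_or_null(a_edge, f0)
  up <- inv_or_null(d_edge, finf)
  unbounded_lower <- is.null(low)
  unbounded_upper <- is.null(up)
  if (unbounded_lower) low <- 0
  if (unbounded_upper) up <- Inf
  if (!unbounded_lower && !unbounded_upper && low >= up) {
    stop("asymptote confidence bands overlap: no sensitivity region",
         call. = FALSE)
  }
  err_at <- function(f, ok) {
    if (!ok || is.na(curve$se_regression)) return(NA_real_)
    tryCatch(as.numeric(concentration_error(curve, f)),
             error = function(e) NA_real_)
  }
  structure(list(lower = low, upper = up,
                 lower_err = err_at(a_edge, !unbounded_lower),
                 upper_err = err_at(d_edge, !unbounded_upper),
                 unbounded_lower = unbounded_lower,
                 unbounded_upper = unbounded_upper),
            class = "sensitivity_region")
}

#' @export
print.sensitivity_region <- function(x, ...) {
  fmt <- function(v, e, unb) {
    if (unb) return("unbounded")
    sprintf("%.4g +- %.2g mg/mL", v, e)
  }
  cat(sprintf("<sensitivity_region [%s, %s]>\n",
              fmt(x$lower, x$lower_err, x$unbounded_lower),
              fmt(x$upper, x$upper_err, x$unbounded_upper)))
  invisible(x)
}
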