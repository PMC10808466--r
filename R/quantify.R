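#' Subtract the per-channel background frame
#'
#' A background image is collected for each LED before sample input
#' (media blank, capturing light leakage) and subtracted from every
#' subsequent frame of that channel.  Differences are clipped at zero:
#' 8-bit data cannot represent negative light, and noise around a dark
#' background would otherwise push pixels negative.
#'
#' @param frame,background [sensor_frame()]s of the same shape and LED
#'   channel.
#' @return A float [sensor_frame()] keeping `frame`'s timestamp.
#' @export
subtract_background <- function(frame, background) {
  if (frame_channel(frame) != frame_channel(background)) {
    stop(sprintf("LED channel mismatch: frame is '%s', background is '%s'",
                 frame_channel(frame), frame_channel(background)),
         call. = FALSE)
  }
  if (!all(dim(frame) == dim(background))) {
    stop("frame and background shapes differ", call. = FALSE)
  }
  sensor_frame(pmax(unclass(frame) - unclass(background), 0),
               led_channel = frame_channel(frame),
               timestamp = frame_time(frame),
               quantized = FALSE)
}

#' Mean pixel intensity over an ROI
#'
#' @param frame A [sensor_frame()].
#' @param roi An [roi_rect()] within the frame bounds.
#' @return Arithmetic mean intensity (AU).
#' @export
roi_mean_intensity <- function(frame, roi) {
  if (!roi_in_bounds(roi, frame)) {
    stop("ROI exceeds frame bounds", call. = FALSE)
  }
  mean(unclass(frame)[roi_rows(roi), roi_cols(roi)])
}

roi_saturation_fraction <- function(frame, roi) {
  px <- unclass(frame)[roi_rows(roi), roi_cols(roi)]
  mean(px >= 255)
}

#' Acquisition schedule for LED cycling
#'
#' The LEDs are switched on one at a time to prevent spectral crosstalk;
#' one "cycle" (all channels in fixed order, cyan before amber) is a
#' single time point.  Time points run from `t = 0` to `duration_s`
#' inclusive, every `period_s` seconds.
#'
#' @param channels Character vector of LED channels to cycle.
#' @param period_s Sampling period, seconds; must be at least
#'   `min_period_s` (the hardware floor of the reference setup is about
#'   7 s).
#' @param duration_s Total acquisition length, seconds.
#' @param min_period_s Minimum feasible cycle time, seconds.
#' @return A `data.frame` with columns `cycle` (0-based), `time_s` and
#'   `channel`, one row per measurement event, in acquisition order.
#' @export
acquisition_schedule <- function(channels, period_s, duration_s,
                                 min_period_s = 7) {
  if (length(channels) < 1L) stop("need at least one channel",
                                  call. = FALSE)
  if (period_s < min_period_s) {
    stop(sprintf("period %g s is below the minimum cycle time %g s",
                 period_s, min_period_s), call. = FALSE)
  }
  if (duration_s < 0) stop("duration must be >= 0", call. = FALSE)
  canonical <- c("cyan", "amber")
  ord <- c(intersect(canonical, channels),
           setdiff(channels, canonical))
  times <- seq(0, duration_s, by = period_s)
  data.frame(cycle = rep(seq_along(times) - 1L, each = length(ord)),
             time_s = rep(times, each = length(ord)),
             channel = rep(ord, length(times)),
             stringsAsFactors = FALSE)
}

#' Diffusion percentage across the membrane
#'
#' `100 * C_filtrate / C_capillary_initial`: the fraction of the initial
#' capillary concentration that has appeared in the filtrate channel, the
#' primary functional readout of barrier integrity.
#'
#' @param c_filtrate Filtrate concentration, mg/mL, `>= 0`.
#' @param c_capillary_initial Initial capillary concentration, mg/mL,
#'   `> 0`.
#' @return Percentage.
#' @export
diffusion_percentage <- function(c_filtrate, c_capillary_initial) {
  if (any(c_capillary_initial <= 0)) {
    cond <- structure(
      class = c("gfbsense_undefined_ratio", "error", "condition"),
      list(message = "initial capillary concentration must be > 0",
           call = sys.call(-1)))
    stop(cond)
  }
  if (any(c_filtrate < 0)) {
    stop("filtrate concentration must be >= 0", call. = FALSE)
  }
  100 * c_filtrate / c_capillary_initial
}

#' Filtrate / capillary intensity ratio
#'
#' The stability QC of the sensor: with the same solution loaded on both
#' sides of the membrane the ratio should sit at 1 across time.
#'
#' @param filtrate_intensity,capillary_intensity Mean ROI intensities
#'   (AU); the capillary intensity must be positive.
#' @return Unitless ratio.
#' @export
intensity_ratio <- function(filtrate_intensity, capillary_intensity) {
  if (any(capillary_intensity <= 0)) {
    cond <- structure(
      class = c("gfbsense_undefined_ratio", "error", "condition"),
      list(message = "capillary intensity must be > 0 to form a ratio",
           call = sys.call(-1)))
    stop(cond)
  }
  filtrate_intensity / capillary_intensity
}

#' Analyze a frame stream into a concentration time series
#'
#' The automated acquisition loop: for each frame, subtract the
#' channel's background, apply the channel's illumination mask, take the
#' ROI means, and invert the channel's calibration curve to
#' concentrations.  Diffusion percentage uses the initial capillary
#' concentration as denominator; the instantaneous percentage relative to
#' the current capillary concentration is reported alongside, as is the
#' filtrate/capillary intensity ratio.
#'
#' Readings whose ROI intensity falls outside the curve's invertible
#' range are kept as flagged rows with the concentration set to `NA`
#' (flag `"below_range"` / `"above_range"`); a point where more than 1%
#' of an ROI's raw pixels sit at 255 is flagged `"saturated"`.  The
#' pipeline never drops points silently.
#'
#' @param frames List of [sensor_frame()]s (any order; sorted by
#'   timestamp, then by fixed channel order within a time point).
#' @param rois An [roi_set()].
#' @param curves Named list of [calibration_curve()]s, one per LED
#'   channel present.
#' @param masks Named list of [illumination_mask()]s, one per channel.
#' @param backgrounds Named list of background [sensor_frame()]s, one per
#'   channel.
#' @param c0 Optional named numeric: the initial capillary concentration
#'   per channel (mg/mL) used as the diffusion-percentage denominator.
#'   Default: the first in-range capillary reading of each channel.
#' @param saturation_limit Fraction of saturated ROI pixels above which a
#'   point is flagged.
#' @return A `data.frame` of class `barrier_timeseries`, one row per
#'   (time point, channel): `time_s`, `channel`,
#'   `capillary_intensity`, `filtrate_intensity`,
#'   `capillary_concentration`, `filtrate_concentration`,
#'   `diffusion_percent`, `diffusion_percent_instant`, `intensity_ratio`,
#'   `flag_capillary`, `flag_filtrate`.
#' @export
analyze_timeseries <- function(frames, rois, curves, masks, backgrounds,
                               c0 = NULL, saturation_limit = 0.01) {
  chans <- unique(vapply(frames, frame_channel, character(1)))
  for (ch in chans) {
    if (is.null(curves[[ch]]) || is.null(masks[[ch]]) ||
        is.null(backgrounds[[ch]])) {
      stop(sprintf(
        "missing calibration curve, mask or background for channel '%s'",
        ch), call. = FALSE)
    }
  }
  ord <- order(vapply(frames, frame_time, numeric(1)),
               match(vapply(frames, frame_channel, character(1)),
                     c("cyan", "amber")))
  frames <- frames[ord]

  one <- function(frame) {
    ch <- frame_channel(frame)
    sat_cap <- roi_saturation_fraction(frame, rois$capillary)
    sat_fil <- roi_saturation_fraction(frame, rois$filtrate)
    corrected <- apply_mask(subtract_background(frame, backgrounds[[ch]]),
                            masks[[ch]])
    f_cap <- roi_mean_intensity(corrected, rois$capillary)
    f_fil <- roi_mean_intensity(corrected, rois$filtrate)
    read <- function(f, sat) {
      conc <- tryCatch(invert_4pl(curves[[ch]], f), error = function(e) e)
      if (inherits(conc, "gfbsense_out_of_range")) {
        flag <- if (identical(conc$violated, "lower")) "below_range"
                else "above_range"
        list(conc = NA_real_, flag = flag)
      } else if (sat > saturation_limit) {
        list(conc = conc, flag = "saturated")
      } else {
        list(conc = conc, flag = "ok")
      }
    }
    cap <- read(f_cap, sat_cap)
    fil <- read(f_fil, sat_fil)
    data.frame(time_s = frame_time(frame), channel = ch,
               capillary_intensity = f_cap, filtrate_intensity = f_fil,
               capillary_concentration = cap$conc,
               filtrate_concentration = fil$conc,
               intensity_ratio = if (f_cap > 0) f_fil / f_cap else NA_real_,
               flag_capillary = cap$flag, flag_filtrate = fil$flag,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(frames, one))

  out$diffusion_percent <- NA_real_
  out$diffusion_percent_instant <- NA_real_
  for (ch in chans) {
    rows <- out$channel == ch
    denom <- if (!is.null(c0) && !is.null(c0[[ch]])) {
      c0[[ch]]
    } else {
      ok <- rows & !is.na(out$capillary_concentration)
      if (!any(ok)) NA_real_ else
        out$capillary_concentration[which(ok)[1]]
    }
    if (!is.na(denom) && denom > 0) {
      out$diffusion_percent[rows] <-
        100 * out$filtrate_concentration[rows] / denom
    }
    cc <- out$capillary_concentration[rows]
    inst <- rep(NA_real_, sum(rows))
    pos <- !is.na(cc) & cc > 0
    inst[pos] <- 100 * out$filtrate_concentration[rows][pos] / cc[pos]
    out$diffusion_percent_instant[rows] <- inst
  }
  cols <- c("time_s", "channel", "capillary_intensity",
            "filtrate_intensity", "capillary_concentration",
            "filtrate_concentration", "diffusion_percent",
            "diffusion_percent_instant", "intensity_ratio",
            "flag_capillary", "flag_filtrate")
  out <- out[, cols]
  rownames(out) <- NULL
  class(out) <- c("barrier_timeseries", "data.frame")
  out
}
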