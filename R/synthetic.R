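#' Sensor noise model
#'
#' Additive Gaussian read noise and optional Poisson shot noise for the
#' synthetic sensor.  The default (sigma = 1 AU, no Poisson term) is a
#' plain read-noise model appropriate for an 8-bit camera binned eight
#' times; shot noise is available for stress-testing but disabled by
#' default.
#'
#' @param gaussian_sigma Read-noise standard deviation, AU, `>= 0`.
#' @param poisson_scale Photons per AU for the shot-noise term; 0
#'   disables it.
#' @param seed Optional integer seed; when set, every generator that
#'   consumes this model is deterministic.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 1, poisson_scale = 0,
                        seed = NULL) {
  if (gaussian_sigma < 0 || poisson_scale < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  structure(list(gaussian_sigma = gaussian_sigma,
                 poisson_scale = poisson_scale,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

# Run `expr` under `seed` (when non-NULL) without disturbing the
# caller's RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render one synthetic sensor frame
#'
#' Builds the ideal fluorescence image (each ROI at the 4PL intensity of
#' its concentration, background at the curve's minimum asymptote),
#' imposes uneven illumination by dividing by the truth mask (the mask is
#' the correction, so the raw field is its reciprocal), adds noise, and
#' quantizes to 8-bit with clipping at `[0, 255]`.  Identical seeds give
#' bitwise-identical frames.
#'
#' @param cap_conc,filt_conc Tracer concentrations in the capillary and
#'   filtrate ROIs, mg/mL, `>= 0`.
#' @param curve The ground-truth [calibration_curve()].
#' @param truth_mask An [illumination_mask()] describing the true
#'   flat-field correction; dimensions set the frame size.
#' @param rois An [roi_set()] within the mask bounds.
#' @param noise A [noise_model()].
#' @param timestamp Seconds since acquisition start, stored on the frame.
#' @param background_au Constant stray-light offset added before the
#'   illumination field, AU; subtracted later by the analysis pipeline's
#'   background step.
#' @param seed Overrides `noise$seed` for this frame.
#' @return An 8-bit [sensor_frame()]; if more than half of either ROI
#'   saturates, attribute `saturated_warning` is `TRUE`.
#' @export
render_frame <- function(cap_conc, filt_conc, curve, truth_mask, rois,
                         noise = noise_model(), timestamp = 0,
                         background_au = 0, seed = noise$seed) {
  if (cap_conc < 0 || filt_conc < 0) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  dims <- dim(truth_mask)
  fl <- matrix(curve$a, dims[1], dims[2])
  fl[roi_rows(rois$capillary), roi_cols(rois$capillary)] <-
    eval_4pl(curve, cap_conc)
  fl[roi_rows(rois$filtrate), roi_cols(rois$filtrate)] <-
    eval_4pl(curve, filt_conc)
  ideal <- (background_au + fl) / unclass(truth_mask)
  px <- with_local_seed(seed, {
    out <- ideal
    if (noise$poisson_scale > 0) {
      out <- stats::rpois(length(out), out * noise$poisson_scale) /
        noise$poisson_scale
      dim(out) <- dims
    }
    if (noise$gaussian_sigma > 0) {
      out <- out + stats::rnorm(length(out), 0, noise$gaussian_sigma)
    }
    out
  })
  px <- matrix(pmin(pmax(round(px), 0), 255), dims[1], dims[2])
  frame <- sensor_frame(px, led_channel = curve$channel_label,
                        timestamp = timestamp, quantized = TRUE)
  sat <- c(roi_saturation_fraction(frame, rois$capillary),
           roi_saturation_fraction(frame, rois$filtrate))
  if (any(sat > 0.5)) {
    attr(frame, "saturated_warning") <- TRUE
  }
  frame
}

#' Render the per-channel background (media blank) frame
#'
#' The dye-free frame captured before sample input: only the stray-light
#' offset under the channel's illumination field.  Subtracting it from
#' subsequent frames removes the offset exactly, which is the contract
#' the analysis pipeline relies on.
#'
#' @inheritParams render_frame
#' @param channel LED channel tag for the frame.
#' @return An 8-bit [sensor_frame()].
#' @export
render_background_frame <- function(truth_mask, noise = noise_model(),
                                    channel = "cyan", background_au = 0,
                                    seed = noise$seed) {
  dims <- dim(truth_mask)
  ideal <- matrix(background_au, dims[1], dims[2]) / unclass(truth_mask)
  px <- with_local_seed(seed, {
    out <- ideal
    if (noise$gaussian_sigma > 0) {
      out <- out + stats::rnorm(length(out), 0, noise$gaussian_sigma)
    }
    out
  })
  px <- matrix(pmin(pmax(round(px), 0), 255), dims[1], dims[2])
  sensor_frame(px, led_channel = channel, timestamp = 0, quantized = TRUE)
}

#' Experiment protocol for the simulator
#'
#' A piecewise-constant command sequence: each segment holds the
#' capillary concentration and flowrate for a duration, emulating the
#' step injections of the reference experiments (injections are treated
#' as instantaneous steps at segment boundaries).
#'
#' @param segments A `data.frame` with columns `duration_s`,
#'   `c0_mg_ml`, `flowrate_ml_s` (one row per segment), or a named list
#'   of such data.frames keyed by LED channel for multi-tracer
#'   protocols.
#' @param sampling_period_s Sensor sampling period, s, `> 0`.
#' @param initial_filtrate_mg_ml Filtrate concentration at `t = 0`
#'   (scalar, or named by channel).
#' @return An object of class `experiment_protocol`.
#' @export
experiment_protocol <- function(segments, sampling_period_s,
                                initial_filtrate_mg_ml = 0) {
  check_seg <- function(df) {
    need <- c("duration_s", "c0_mg_ml", "flowrate_ml_s")
    if (!all(need %in% names(df))) {
      stop("segments need columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(df$duration_s <= 0)) {
      stop("segment durations must be > 0", call. = FALSE)
    }
    if (any(df$c0_mg_ml < 0) || any(df$flowrate_ml_s < 0)) {
      stop("segment concentrations and flowrates must be >= 0",
           call. = FALSE)
    }
    df
  }
  if (is.data.frame(segments)) {
    segments <- check_seg(segments)
  } else {
    segments <- lapply(segments, check_seg)
  }
  if (sampling_period_s <= 0) {
    stop("sampling period must be > 0", call. = FALSE)
  }
  structure(list(segments = segments,
                 sampling_period_s = sampling_period_s,
                 initial_filtrate_mg_ml = initial_filtrate_mg_ml),
            class = "experiment_protocol")
}

# Piecewise first-order ground truth for one channel: at each segment
# boundary the trajectory restarts from the current filtrate
# concentration toward the new segment's equilibrium (capped at C0 --
# passive diffusion cannot overshoot its source).
truth_trajectory <- function(segments, times, cf0, geom, fluid, trc,
                             tau_s) {
  starts <- cumsum(c(0, segments$duration_s))
  total <- starts[length(starts)]
  eqs <- vapply(seq_len(nrow(segments)), function(i) {
    q <- segments$flowrate_ml_s[i]
    c0 <- segments$c0_mg_ml[i]
    if (q <= 0 || c0 < 0) return(cf0)
    min(c0, steady_state_filtrate_concentration(
      geom, fluid, trc, operating_point(q, c0)))
  }, numeric(1))
  cf_at_start <- numeric(nrow(segments))
  cf_at_start[1] <- cf0
  if (nrow(segments) > 1) {
    for (i in 2:nrow(segments)) {
      dt <- segments$duration_s[i - 1]
      cf_at_start[i] <- eqs[i - 1] +
        (cf_at_start[i - 1] - eqs[i - 1]) * exp(-dt / tau_s)
    }
  }
  vapply(times, function(t) {
    t <- min(t, total)
    i <- min(max(findInterval(t, starts, rightmost.closed = TRUE), 1L),
             nrow(segments))
    eqs[i] + (cf_at_start[i] - eqs[i]) * exp(-(t - starts[i]) / tau_s)
  }, numeric(1))
}

#' Simulate a whole sensor experiment
#'
#' Generates the ground-truth concentration dynamics for a protocol
#' (piecewise first-order transients toward the steady-state transport
#' prediction of each segment), renders a frame per channel at every
#' sampling time, and returns frames, a manifest and the ground truth
#' side by side.  The capillary ground truth is the protocol's commanded
#' concentration (reservoir dilution is out of scope); the filtrate
#' never exceeds the running capillary concentration.
#'
#' @param protocol An [experiment_protocol()].
#' @param geom,fluid See [steady_state_prediction()].
#' @param tracers Named list of [tracer()]s keyed by LED channel.
#' @param curves Named list of ground-truth [calibration_curve()]s keyed
#'   by LED channel.
#' @param truth_mask A single [illumination_mask()], or a named list per
#'   channel.
#' @param rois An [roi_set()].
#' @param noise A [noise_model()]; its seed makes the whole experiment
#'   reproducible.
#' @param tau_s Transient time constant, s.
#' @param background_au Stray-light offset passed to [render_frame()].
#' @return A list with elements `frames` (named list of
#'   [sensor_frame()]s, names `{cycle:05d}_{channel}`), `manifest`
#'   (`data.frame`: `filename`, `channel`, `timestamp_s`), `truth`
#'   (`data.frame`: `time_s`, `channel`, `capillary_concentration`,
#'   `filtrate_concentration`, `diffusion_percent`) and `backgrounds`
#'   (named list of background frames per channel).
#' @export
simulate_experiment <- function(protocol, geom, fluid, tracers, curves,
                                truth_mask, rois, noise = noise_model(),
                                tau_s = 120, background_au = 0) {
  chans <- names(tracers)
  if (is.null(chans) || !setequal(chans, names(curves))) {
    stop("`tracers` and `curves` must be named lists over the same channels",
         call. = FALSE)
  }
  chans <- intersect(c("cyan", "amber"), chans)
  masks <- if (inherits(truth_mask, "illumination_mask")) {
    stats::setNames(rep(list(truth_mask), length(chans)), chans)
  } else truth_mask
  seg_of <- function(ch) {
    if (is.data.frame(protocol$segments)) protocol$segments
    else protocol$segments[[ch]]
  }
  cf0_of <- function(ch) {
    x <- protocol$initial_filtrate_mg_ml
    if (length(x) == 1L && is.null(names(x))) as.numeric(x)
    else as.numeric(x[[ch]])
  }
  total <- max(vapply(chans, function(ch) sum(seg_of(ch)$duration_s),
                      numeric(1)))
  times <- seq(0, total, by = protocol$sampling_period_s)

  run <- function() {
    truth <- list()
    frames <- list()
    manifest <- list()
    backgrounds <- list()
    for (ch in chans) {
      backgrounds[[ch]] <- render_background_frame(
        masks[[ch]], noise, channel = ch, background_au = background_au,
        seed = NULL)
    }
    for (ch in chans) {
      seg <- seg_of(ch)
      starts <- cumsum(c(0, seg$duration_s))
      cap <- vapply(times, function(t) {
        i <- findInterval(min(t, sum(seg$duration_s)), starts,
                          rightmost.closed = TRUE)
        seg$c0_mg_ml[min(max(i, 1L), nrow(seg))]
      }, numeric(1))
      fil <- truth_trajectory(seg, times, cf0_of(ch), geom, fluid,
                              tracers[[ch]], tau_s)
      c_init <- seg$c0_mg_ml[1]
      truth[[ch]] <- data.frame(
        time_s = times, channel = ch,
        capillary_concentration = cap,
        filtrate_concentration = fil,
        diffusion_percent = if (c_init > 0) 100 * fil / c_init
                            else NA_real_,
        stringsAsFactors = FALSE)
    }
    for (k in seq_along(times)) {
      for (ch in chans) {
        tr <- truth[[ch]]
        fr <- render_frame(tr$capillary_concentration[k],
                           tr$filtrate_concentration[k],
                           curves[[ch]], masks[[ch]], rois, noise,
                           timestamp = times[k],
                           background_au = background_au, seed = NULL)
        nm <- sprintf("%05d_%s", k - 1L, ch)
        frames[[nm]] <- fr
        manifest[[length(manifest) + 1L]] <- data.frame(
          filename = paste0(nm, ".png"), channel = ch,
          timestamp_s = times[k], stringsAsFactors = FALSE)
      }
    }
    list(frames = frames,
         manifest = do.call(rbind, manifest),
         truth = do.call(rbind, unname(truth)),
         backgrounds = backgrounds)
  }
  with_local_seed(noise$seed, run())
}

#' Generate a synthetic calibration dataset
#'
#' Replicate intensities drawn as `eval_4pl(truth, x) + N(0, sigma)`,
#' emulating the replicate dilution-series measurements used to
#' calibrate the physical sensor.
#'
#' @param truth_curve The ground-truth [calibration_curve()].
#' @param concentrations At least 5 distinct positive concentrations,
#'   mg/mL; the reference serial dilution spans 0.0001 to 5 mg/mL.
#' @param replicates Replicates per concentration, `>= 1`.
#' @param noise A [noise_model()]; only the Gaussian term applies.
#' @return A [calibration_dataset()].
#' @export
generate_calibration_dataset <- function(truth_curve, concentrations,
                                         replicates = 3,
                                         noise = noise_model()) {
  if (replicates < 1) stop("need at least 1 replicate", call. = FALSE)
  conc <- rep(concentrations, each = replicates)
  rep_idx <- rep(seq_len(replicates), length(concentrations))
  ints <- with_local_seed(noise$seed, {
    eval_4pl(truth_curve, conc) +
      stats::rnorm(length(conc), 0, noise$gaussian_sigma)
  })
  calibration_dataset(conc, ints, rep_idx)
}
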