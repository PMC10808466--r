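#' Parse a flowrate with units to mL/s
#'
#' Accepts a number (already mL/s) or a string like `"8 uL/min"`,
#' `"100ul/min"`, `"1.5 mL/min"`, `"2e-4 mL/s"`.  Recognized volume
#' units: uL, mL, L (case-insensitive, `u` for micro); time units: s,
#' min, h.
#'
#' @param x Numeric or string flowrate.
#' @return Flowrate in mL/s.
#' @export
parse_flowrate <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- trimws(tolower(x))
  m <- regmatches(s, regexec(
    "^([0-9.eE+-]+)\\s*(ul|ml|l)\\s*/\\s*(s|sec|min|h|hr)$", s))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse flowrate '%s' (expected e.g. '8 uL/min')",
                 x), call. = FALSE)
  }
  val <- as.numeric(m[2])
  vol <- switch(m[3], ul = 1e-3, ml = 1, l = 1e3)
  tim <- switch(m[4], s = 1, sec = 1, min = 60, h = 3600, hr = 3600)
  val * vol / tim
}

#' Write / read an 8-bit grayscale frame as PNG
#'
#' Frames travel as 8-bit grayscale PNG files named
#' `{cycle:05d}_{channel}.png`, with channel and timestamp carried by a
#' manifest CSV (the PNG container itself stores only pixels).
#'
#' @param frame An 8-bit [sensor_frame()].
#' @param path Output `.png` path.
#' @return `write_frame_png()` returns `path` invisibly;
#'   `read_frame_png()` returns a [sensor_frame()].
#' @export
write_frame_png <- function(frame, path) {
  if (!isTRUE(attr(frame, "quantized"))) {
    stop("only 8-bit frames are written to PNG; float frames stay in memory",
         call. = FALSE)
  }
  png::writePNG(unclass(frame) / 255, target = path)
  invisible(path)
}

#' @rdname write_frame_png
#' @param led_channel,timestamp Metadata to attach (normally from the
#'   manifest).
#' @export
read_frame_png <- function(path, led_channel, timestamp = 0) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]   # tolerate gray+alpha
  sensor_frame(round(px * 255), led_channel = led_channel,
               timestamp = timestamp, quantized = TRUE)
}

#' Write a frame set with its manifest
#'
#' @param frames Named list of frames as produced by
#'   [simulate_experiment()].
#' @param manifest `data.frame` with `filename`, `channel`,
#'   `timestamp_s`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_frames <- function(frames, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(manifest))) {
    nm <- sub("\\.png$", "", manifest$filename[i])
    write_frame_png(frames[[nm]], file.path(dir, manifest$filename[i]))
  }
  mpath <- file.path(dir, "manifest.csv")
  write_csv9(manifest, mpath)
  invisible(mpath)
}

#' Read a frame stream from a manifest
#'
#' @param manifest_path Path to a manifest CSV (`filename`, `channel`,
#'   `timestamp_s`); frame files are resolved relative to it.
#' @return Named list of [sensor_frame()]s in manifest order.
#' @export
read_frames <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("filename", "channel", "timestamp_s")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dir <- dirname(manifest_path)
  frames <- list()
  for (i in seq_len(nrow(man))) {
    if (is.na(man$timestamp_s[i]) || !nzchar(man$channel[i])) {
      stop(sprintf("malformed manifest row %d", i), call. = FALSE)
    }
    f <- file.path(dir, man$filename[i])
    if (!file.exists(f)) {
      stop(sprintf("manifest row %d: missing frame file '%s'", i,
                   man$filename[i]), call. = FALSE)
    }
    nm <- sub("\\.png$", "", man$filename[i])
    frames[[nm]] <- read_frame_png(f, man$channel[i], man$timestamp_s[i])
  }
  frames
}

# CSV writer with the package's fixed numeric format: 9 significant
# digits, UTF-8, LF line endings.
write_csv9 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "", formatC(x, digits = 9, format = "g"))
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con, sep = "\n")
  if (nrow(out)) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = ","))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write / read an analyzed time series as CSV
#'
#' Column order is fixed and documented in [analyze_timeseries()];
#' numbers are written with 9 significant digits, LF endings.
#'
#' @param series A `barrier_timeseries` data.frame.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_timeseries()` returns the
#'   `barrier_timeseries`.
#' @export
write_timeseries <- function(series, path) {
  write_csv9(as.data.frame(series), path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("barrier_timeseries", "data.frame")
  df
}

#' Serialize / load a calibration curve as JSON
#'
#' @param curve A [calibration_curve()].
#' @param path JSON path.
#' @return `path` invisibly; `read_calibration_curve()` returns the
#'   curve.
#' @export
write_calibration_curve <- function(curve, path) {
  obj <- unclass(curve)
  obj$param_ci95 <- list(lower = unname(curve$param_ci95["lower", ]),
                         upper = unname(curve$param_ci95["upper", ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_calibration_curve
#' @export
read_calibration_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ci <- matrix(NA_real_, 2, 4,
               dimnames = list(c("lower", "upper"), c("a", "b", "c", "d")))
  if (!is.null(obj$param_ci95)) {
    lo <- unlist(obj$param_ci95$lower)
    up <- unlist(obj$param_ci95$upper)
    if (!is.null(lo)) ci["lower", ] <- as.numeric(lo)
    if (!is.null(up)) ci["upper", ] <- as.numeric(up)
  }
  null2na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  calibration_curve(a = obj$a, b = obj$b, c = obj$c, d = obj$d,
                    channel_label = obj$channel_label,
                    r_squared = null2na(obj$r_squared),
                    se_regression = null2na(obj$se_regression),
                    param_ci95 = ci)
}

#' Write / read an illumination mask as plain-text TSV
#'
#' Stored as a tab-separated float matrix (no binary image container is
#' used for the float-valued mask).
#'
#' @param mask An [illumination_mask()].
#' @param path Output `.tsv` path.
#' @return `path` invisibly; `read_illumination_mask()` returns the
#'   mask.
#' @export
write_illumination_mask <- function(mask, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# illumination_mask channel=",
                    attr(mask, "channel")), con, sep = "\n")
  m <- unclass(mask)
  writeLines(apply(m, 1, function(r) {
    paste(formatC(r, digits = 12, format = "g"), collapse = "\t")
  }), con, sep = "\n")
  invisible(path)
}

#' @rdname write_illumination_mask
#' @export
read_illumination_mask <- function(path) {
  lines <- readLines(path)
  ch <- sub("^# illumination_mask channel=", "", lines[1])
  m <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  illumination_mask(m, channel = ch)
}

#' Read a calibration dataset from CSV
#'
#' Expected columns: `concentration_mg_per_ml`, `replicate`,
#' `intensity_au`.
#'
#' @param path CSV path.
#' @return A [calibration_dataset()].
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_mg_per_ml", "replicate", "intensity_au")
  if (!all(need %in% names(df))) {
    stop("calibration CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  calibration_dataset(df$concentration_mg_per_ml, df$intensity_au,
                      df$replicate)
}

#' @rdname read_calibration_csv
#' @param dataset A [calibration_dataset()].
#' @export
write_calibration_csv <- function(dataset, path) {
  write_csv9(data.frame(concentration_mg_per_ml = dataset$concentration,
                        replicate = dataset$replicate,
                        intensity_au = dataset$intensity), path)
}

required_config_fields <- list(
  geometry = c("channel_width_w_cm", "channel_height_h_cm",
               "capillary_height_cm", "membrane_thickness_um",
               "exposed_area_A_cm2", "capillary_volume_Vc_ml",
               "filtrate_volume_Vf_ml"),
  fluid = character(0),
  tracers = character(0))

#' Load and validate a run configuration
#'
#' Configurations are JSON or YAML with sections `geometry`, `fluid`,
#' `tracers` (a named list per tracer with `molecular_weight_g_mol`,
#' `permeability_kappa_um2`, `dye_channel`), optional `rois`,
#' `schedule`, `seed` and `operating` (whose `flowrate` accepts unit
#' strings such as `"8 uL/min"`).  Missing fluid fields take the
#' package defaults (water at 37 C); missing geometry is an error.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list of class `run_config` with `geometry`
#'   ([chip_geometry()]), `fluid` ([fluid_properties()]), `tracers`
#'   (named list of [tracer()] keyed by dye channel), plus any `rois`,
#'   `schedule`, `operating` and `seed` entries, units normalized.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw$geometry)) {
    stop("config schema violation: missing section 'geometry'",
         call. = FALSE)
  }
  miss <- setdiff(required_config_fields$geometry, names(raw$geometry))
  if (length(miss)) {
    stop("config schema violation: geometry missing field(s) ",
         paste(miss, collapse = ", "),
         " (units are part of the field names, e.g. channel_width_w_cm)",
         call. = FALSE)
  }
  geom <- do.call(chip_geometry,
                  raw$geometry[required_config_fields$geometry])
  fluid <- do.call(fluid_properties,
                   if (is.null(raw$fluid)) list() else raw$fluid)
  tracers <- list()
  if (!is.null(raw$tracers)) {
    for (nm in names(raw$tracers)) {
      t <- raw$tracers[[nm]]
      for (f in c("molecular_weight_g_mol", "permeability_kappa_um2")) {
        if (is.null(t[[f]])) {
          stop(sprintf(
            "config schema violation: tracer '%s' missing field '%s'",
            nm, f), call. = FALSE)
        }
      }
      ch <- if (is.null(t$dye_channel)) "cyan" else t$dye_channel
      tracers[[ch]] <- tracer(nm, t$molecular_weight_g_mol,
                              t$permeability_kappa_um2, dye_channel = ch)
    }
  }
  rois <- NULL
  if (!is.null(raw$rois)) {
    mk <- function(r) roi_rect(r$row_start, r$row_end, r$col_start,
                               r$col_end)
    rois <- roi_set(mk(raw$rois$capillary), mk(raw$rois$filtrate))
  }
  operating <- NULL
  if (!is.null(raw$operating)) {
    operating <- raw$operating
    if (!is.null(operating$flowrate)) {
      operating$flowrate_ml_s <- parse_flowrate(operating$flowrate)
    }
  }
  structure(list(geometry = geom, fluid = fluid, tracers = tracers,
                 rois = rois, schedule = raw$schedule,
                 operating = operating,
                 seed = if (is.null(raw$seed)) NULL
                        else as.integer(raw$seed)),
            class = "run_config")
}

#' Path to the bundled default chip configuration
#'
#' The shipped geometry is a documented approximation: membrane
#' thickness, layer heights and the serial-dilution span come from the
#' reference device description, while the channel width is
#' back-calculated from the device's reported wall shear stress at
#' 100 uL/min (see the methods vignette).  It is a synthetic stand-in
#' for the fabrication design files, which are not bundled.
#'
#' @return Path to `chip_default.json` inside the installed package.
#' @export
default_chip_config <- function() {
  system.file("extdata", "chip_default.json", package = "gfbsense",
              mustWork = TRUE)
}
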