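#' Sensor frame
#'
#' A single grayscale image from the chip sensor: a numeric matrix of pixel
#' intensities (arbitrary units, AU) tagged with the LED excitation channel
#' that produced it and the acquisition time.  Frames are ingested as 8-bit
#' (values 0--255) but become plain floats the moment any processing step
#' (background subtraction, flat-field correction) touches them; nothing is
#' ever re-quantized back to 8-bit.
#'
#' @param pixels Numeric matrix of pixel intensities.  For a freshly ingested
#'   frame all values must lie in `[0, 255]`.
#' @param led_channel Excitation channel identifier, e.g. `"cyan"` (490 nm,
#'   FITC) or `"amber"` (590 nm, Texas Red).
#' @param timestamp Seconds since the start of the acquisition.
#' @param quantized Logical; `TRUE` for raw 8-bit data straight off the
#'   sensor, `FALSE` for float frames produced by processing steps.
#'
#' @return An object of class `sensor_frame`: the pixel matrix with
#'   `led_channel`, `timestamp` and `quantized` attributes.
#' @export
sensor_frame <- function(pixels, led_channel, timestamp = 0,
                         quantized = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels)) stop("`pixels` must not contain NA", call. = FALSE)
  if (quantized && (min(pixels) < 0 || max(pixels) > 255)) {
    stop("ingested 8-bit pixel values must lie in [0, 255]", call. = FALSE)
  }
  if (!is.character(led_channel) || length(led_channel) != 1L) {
    stop("`led_channel` must be a single string", call. = FALSE)
  }
  structure(pixels,
            led_channel = led_channel,
            timestamp = as.numeric(timestamp),
            quantized = isTRUE(quantized),
            class = c("sensor_frame", "matrix", "array"))
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf("<sensor_frame %d x %d, channel = %s, t = %gs, %s>\n",
              nrow(x), ncol(x), attr(x, "led_channel"),
              attr(x, "timestamp"),
              if (isTRUE(attr(x, "quantized"))) "8-bit" else "float"))
  invisible(x)
}

frame_channel <- function(frame) attr(frame, "led_channel")
frame_time <- function(frame) attr(frame, "timestamp")

#' Rectangular region of interest
#'
#' Pixel rectangles use 0-based, half-open indexing
#' `[row_start, row_end) x [col_start, col_end)`, the convention of the
#' acquisition software; helpers convert to R's 1-based closed ranges
#' internally.
#'
#' @param row_start,row_end,col_start,col_end Integer pixel bounds
#'   (half-open, 0-based).
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(row_start, row_end, col_start, col_end) {
  b <- c(row_start = row_start, row_end = row_end,
         col_start = col_start, col_end = col_end)
  if (any(b != floor(b)) || any(b < 0)) {
    stop("ROI bounds must be non-negative integers", call. = FALSE)
  }
  if (row_end <= row_start || col_end <= col_start) {
    stop("ROI rectangle is empty: end bounds must exceed start bounds",
         call. = FALSE)
  }
  structure(as.list(b), class = "roi_rect")
}

roi_rows <- function(roi) seq.int(roi$row_start + 1L, roi$row_end)
roi_cols <- function(roi) seq.int(roi$col_start + 1L, roi$col_end)
roi_npix <- function(roi) {
  (roi$row_end - roi$row_start) * (roi$col_end - roi$col_start)
}

roi_in_bounds <- function(roi, frame) {
  roi$row_end <= nrow(frame) && roi$col_end <= ncol(frame)
}

roi_overlap <- function(a, b) {
  rows <- a$row_start < b$row_end && b$row_start < a$row_end
  cols <- a$col_start < b$col_end && b$col_start < a$col_end
  rows && cols
}

#' Capillary / filtrate ROI pair
#'
#' The two imaging squares of the chip: the capillary channel (tracer
#' source, upstream of the membrane) and the filtrate channel (downstream).
#' The rectangles must be non-empty and non-overlapping; bounds against a
#' particular frame shape are checked where frames are consumed.
#'
#' @param capillary,filtrate [roi_rect()] rectangles.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(capillary, filtrate) {
  stopifnot(inherits(capillary, "roi_rect"), inherits(filtrate, "roi_rect"))
  if (roi_overlap(capillary, filtrate)) {
    stop("capillary and filtrate ROIs must not overlap", call. = FALSE)
  }
  structure(list(capillary = capillary, filtrate = filtrate),
            class = "roi_set")
}
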