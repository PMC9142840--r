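#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
NULL

# Canonical channel order used throughout: autofluorescence first, harmonics after.
NLOI_CHANNELS <- c("2PF", "3PF", "SHG", "THG")

#' Construct a multimodal NLOI frame
#'
#' A frame holds one co-registered set of single-plane intensity rasters from
#' up to four nonlinear contrasts (2PF, 3PF, SHG, THG), together with the
#' physical pixel size and the acquisition time within a series. Rasters are
#' numeric matrices indexed `[row, col]` with the origin at the top-left;
#' the physical position of a pixel is its 0-based index times
#' `pixel_size_um`.
#'
#' @param channels Named list of non-negative numeric matrices. Names must be
#'   drawn from `"2PF"`, `"3PF"`, `"SHG"`, `"THG"`; all matrices must share
#'   the same dimensions.
#' @param pixel_size_um Positive pixel pitch in micrometres per pixel.
#' @param time_min Acquisition time in minutes since the start of the series.
#' @param frame_id Optional text label.
#'
#' @return An object of class `multimodal_frame`.
#' @export
multimodal_frame <- function(channels, pixel_size_um, time_min = 0,
                             frame_id = "frame") {
  if (!is.list(channels) || length(channels) == 0L) {
    stop("`channels` must be a non-empty named list of matrices", call. = FALSE)
  }
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every channel must be named", call. = FALSE)
  }
  bad <- setdiff(nm, NLOI_CHANNELS)
  if (length(bad) > 0L) {
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(NLOI_CHANNELS, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(nm)) stop("duplicated channel names", call. = FALSE)
  channels <- lapply(channels, function(m) {
    if (!is.matrix(m)) stop("each channel must be a matrix", call. = FALSE)
    storage.mode(m) <- "double"
    m
  })
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all channel rasters must share identical dimensions", call. = FALSE)
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(time_min) || length(time_min) != 1L || time_min < 0) {
    stop("`time_min` must be a single non-negative number", call. = FALSE)
  }
  # store in canonical order for reproducible serialization
  channels <- channels[intersect(NLOI_CHANNELS, nm)]
  structure(
    list(channels = channels,
         pixel_size_um = as.numeric(pixel_size_um),
         time_min = as.numeric(time_min),
         frame_id = as.character(frame_id)),
    class = "multimodal_frame"
  )
}

#' @export
print.multimodal_frame <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<multimodal_frame> ", x$frame_id, "\n", sep = "")
  cat("  channels: ", paste(names(x$channels), collapse = ", "), "\n", sep = "")
  cat(sprintf("  size: %d x %d px (%.1f x %.1f um), pixel %.4g um, t = %.3g min\n",
              d[1], d[2], d[1] * x$pixel_size_um, d[2] * x$pixel_size_um,
              x$pixel_size_um, x$time_min))
  invisible(x)
}

#' @export
dim.multimodal_frame <- function(x) dim(x$channels[[1]])

#' Extract one channel raster from a frame
#'
#' @param frame A [multimodal_frame()].
#' @param channel Channel name, one of `"2PF"`, `"3PF"`, `"SHG"`, `"THG"`.
#' @return A numeric matrix.
#' @export
frame_channel <- function(frame, channel) {
  stopifnot(inherits(frame, "multimodal_frame"))
  if (!channel %in% names(frame$channels)) {
    stop("channel '", channel, "' not present in frame (has: ",
         paste(names(frame$channels), collapse = ", "), ")", call. = FALSE)
  }
  frame$channels[[channel]]
}

#' Channel names present in a frame
#' @param frame A [multimodal_frame()].
#' @return Character vector of channel names.
#' @export
frame_channels <- function(frame) names(frame$channels)

#' Convert a frame to a long tibble of pixel values
#'
#' One row per pixel per channel, with 0-based pixel indices and physical
#' coordinates in micrometres. Mainly useful for ggplot2-based display and
#' ad-hoc dplyr summaries.
#'
#' @param x A [multimodal_frame()].
#' @param ... Unused.
#' @return A tibble with columns `channel`, `row`, `col`, `x_um`, `y_um`,
#'   `intensity`.
#' @export
tidy.multimodal_frame <- function(x, ...) {
  d <- dim(x)
  purrr::map_dfr(names(x$channels), function(ch) {
    m <- x$channels[[ch]]
    tibble::tibble(
      channel = ch,
      row = rep(seq_len(d[1]) - 1L, times = d[2]),
      col = rep(seq_len(d[2]) - 1L, each = d[1]),
      intensity = as.vector(m)
    )
  }) |>
    dplyr::mutate(x_um = .data$col * x$pixel_size_um,
                  y_um = .data$row * x$pixel_size_um)
}
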