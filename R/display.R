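#' Saturating contrast adjustment
#'
#' Rescales a raster to `[0, 1]` after saturating the brightest pixels:
#' with `saturation_fraction = f`, the `(1 - f)` quantile `q` (linear
#' interpolation) is computed, values are clipped to `q`, and the clipped
#' raster is rescaled linearly from `[min, q]` to `[0, 1]`. The common
#' display convention of saturating the top 5% of intensities corresponds
#' to `f = 0.05`. The result is invariant to positive affine rescaling of
#' the input.
#'
#' @param raster Numeric matrix.
#' @param saturation_fraction Fraction of top-intensity pixels to saturate,
#'   in `[0, 1)`. Default 0.05.
#' @return A matrix with values in `[0, 1]`. A constant input yields an
#'   all-zero matrix with a warning, since the rescale is undefined.
#' @export
adjust_contrast <- function(raster, saturation_fraction = 0.05) {
  stopifnot(is.matrix(raster), length(raster) > 0)
  if (!is.numeric(saturation_fraction) || saturation_fraction < 0 ||
      saturation_fraction >= 1) {
    stop("`saturation_fraction` must be in [0, 1)", call. = FALSE)
  }
  lo <- min(raster)
  q <- stats::quantile(raster, probs = 1 - saturation_fraction,
                       names = FALSE, type = 7)
  if (q <= lo) {
    warning("constant raster: contrast rescale undefined, returning zeros")
    return(array(0, dim = dim(raster)))
  }
  out <- (pmin(raster, q) - lo) / (q - lo)
  out
}

#' Merge channels into a pseudo-colored RGB display image
#'
#' Each channel is independently contrast-adjusted with
#' [adjust_contrast()], tinted with its assigned color, and the tinted
#' layers are summed and clipped to `[0, 1]` — the standard additive
#' overlay used to present multimodal images.
#'
#' @param frame A [multimodal_frame()].
#' @param color_map Named list or vector mapping channel names to colors
#'   (any form `grDevices::col2rgb()` accepts). Default assigns green to
#'   2PF, cyan to 3PF, magenta to SHG and yellow to THG, restricted to the
#'   channels present.
#' @param saturation_fraction Passed to [adjust_contrast()].
#' @return An object of class `display_image` with fields `rgb`
#'   (rows x cols x 3 array in `[0, 1]`), `channel_color_map`, and
#'   `saturation_fraction`.
#' @export
merge_pseudocolor <- function(frame, color_map = NULL,
                              saturation_fraction = 0.05) {
  stopifnot(inherits(frame, "multimodal_frame"))
  if (is.null(color_map)) {
    default_map <- c("2PF" = "green", "3PF" = "cyan",
                     "SHG" = "magenta", "THG" = "yellow")
    color_map <- as.list(default_map[frame_channels(frame)])
  }
  color_map <- as.list(color_map)
  absent <- setdiff(names(color_map), frame_channels(frame))
  if (length(absent) > 0L) {
    stop("color_map names absent channel(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  d <- dim(frame)
  rgb <- array(0, dim = c(d[1], d[2], 3))
  for (ch in names(color_map)) {
    tint <- grDevices::col2rgb(color_map[[ch]])[, 1] / 255
    layer <- withCallingHandlers(
      adjust_contrast(frame_channel(frame, ch), saturation_fraction),
      warning = function(w) {
        if (grepl("constant raster", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    for (k in 1:3) rgb[, , k] <- rgb[, , k] + layer * tint[k]
  }
  rgb[rgb > 1] <- 1
  structure(
    list(rgb = rgb, channel_color_map = color_map,
         saturation_fraction = saturation_fraction),
    class = "display_image"
  )
}

#' @export
print.display_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<display_image> %d x %d px, channels: %s\n", d[1], d[2],
              paste(names(x$channel_color_map), collapse = ", ")))
  invisible(x)
}

#' Plot a display image with ggplot2
#'
#' @param object A `display_image`.
#' @param ... Unused.
#' @return A ggplot object rendering the RGB raster.
#' @export
autoplot.display_image <- function(object, ...) {
  d <- dim(object$rgb)
  hex <- grDevices::rgb(object$rgb[, , 1], object$rgb[, , 2],
                        object$rgb[, , 3])
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    fill = hex
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
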