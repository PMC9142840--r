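#' Read a multimodal frame from a multi-page TIFF
#'
#' Channels are stored as TIFF pages in the order declared by the metadata
#' sidecar (never guessed from pixel content). The sidecar is a JSON file
#' with fields `channels` (array of channel names, one per page),
#' `pixel_size_um`, and optionally `time_min`, `fov_um`, and
#' `intensity_unit` (scalar or one per channel; stored integer sample
#' values are multiplied by it). If `pixel_size_um` is absent it is
#' derived as `fov_um / n_pixels`; if both are absent reading fails.
#' TIFF samples of any integer bit depth are accepted and promoted to
#' double. A [write_frame()] / `read_frame()` round trip is bit-exact for
#' integer-valued rasters below 2^32 (the realistic detector-count case)
#' and quantized at 2^-32 relative precision otherwise.
#'
#' @param path Path to a TIFF file.
#' @param metadata Either a path to a JSON sidecar, or a named list with the
#'   sidecar fields. Defaults to `<path without extension>.json` when that
#'   file exists.
#' @return A [multimodal_frame()].
#' @export
read_frame <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- resolve_metadata(path, metadata)
  if (is.null(meta$channels)) {
    stop("metadata must declare `channels` (page order)", call. = FALSE)
  }
  channels_decl <- as.character(unlist(meta$channels))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channels_decl)) {
    stop("TIFF has ", length(pages), " page(s) but metadata declares ",
         length(channels_decl), " channel(s)", call. = FALSE)
  }
  units <- meta$intensity_unit %||% 1
  units <- rep_len(as.numeric(unlist(units)), length(pages))
  rasters <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      stop("expected single-channel pages; got an RGB page", call. = FALSE)
    }
    storage.mode(p) <- "double"
    # undo signed wrap of 32-bit samples (NA is INT_MIN, i.e. 2^31)
    p[is.na(p)] <- -2^31
    p[p < 0] <- p[p < 0] + 2^32
    p * units[i]
  })
  names(rasters) <- channels_decl
  px <- meta$pixel_size_um
  if (is.null(px)) {
    if (is.null(meta$fov_um)) {
      stop("metadata supplies neither `pixel_size_um` nor `fov_um`",
           call. = FALSE)
    }
    px <- as.numeric(meta$fov_um)[1] / nrow(rasters[[1]])
  }
  multimodal_frame(
    channels = rasters,
    pixel_size_um = as.numeric(px),
    time_min = as.numeric(meta$time_min %||% 0),
    frame_id = as.character(meta$frame_id %||%
                              tools::file_path_sans_ext(basename(path)))
  )
}

resolve_metadata <- function(path, metadata) {
  if (is.list(metadata)) return(metadata)
  sidecar <- if (is.character(metadata)) metadata else
    paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) {
    stop("no metadata sidecar found for ", path, " (looked for ", sidecar, ")",
         call. = FALSE)
  }
  jsonlite::read_json(sidecar, simplifyVector = TRUE)
}

#' Write a multimodal frame to a multi-page TIFF plus JSON sidecar
#'
#' Pages are written in the frame's canonical channel order
#' (2PF, 3PF, SHG, THG; absent channels skipped) as 32-bit integer
#' samples. Each channel stores `round(x / intensity_unit)` with the
#' per-channel `intensity_unit` recorded in the sidecar
#' `<path without extension>.json` alongside the channel order, pixel
#' size, and acquisition time. The unit is 1 for integer-valued rasters
#' (making the round trip bit-exact) and `max(x) / (2^32 - 1)` otherwise.
#'
#' @param frame A [multimodal_frame()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "multimodal_frame"))
  full <- 2^32 - 1
  units <- vapply(frame$channels, function(m) {
    mx <- max(m)
    if (mx <= full && all(abs(m - round(m)) < 1e-9)) 1 else mx / full
  }, numeric(1))
  pages <- purrr::map2(frame$channels, units,
                       function(m, u) round(m / u) / full)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L,
                  reduce = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(channels = names(frame$channels),
         pixel_size_um = frame$pixel_size_um,
         time_min = frame$time_min,
         frame_id = frame$frame_id,
         intensity_unit = unname(units)),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a label mask as a 16-bit single-channel TIFF
#'
#' @param mask A [segmentation_mask()] or integer matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  labels <- if (inherits(mask, "segmentation_mask")) mask$labels else mask
  if (max(labels) > 65535L) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Export a pseudo-colored display image as PNG
#'
#' @param display A `display_image` from [merge_pseudocolor()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_display_png <- function(display, path) {
  stopifnot(inherits(display, "display_image"))
  png::writePNG(display$rgb, path)
  invisible(path)
}
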