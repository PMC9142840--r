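#' Construct a segmentation mask
#'
#' A labeled-region raster (0 = background) applied identically to all
#' channels of a frame. Labels are canonicalized to a contiguous
#' `1..n_labels` range, preserving region identity by increasing original
#' label value.
#'
#' @param labels Non-negative integer-valued matrix.
#' @param source Provenance tag: `"external"` (third-party segmenter),
#'   `"builtin"` ([segment_blobs()]), or `"ground_truth"` (synthetic).
#' @return A `segmentation_mask`: list with `labels`, `n_labels`, `source`.
#' @export
segmentation_mask <- function(labels,
                              source = c("external", "builtin",
                                         "ground_truth")) {
  source <- match.arg(source)
  stopifnot(is.matrix(labels))
  if (any(abs(labels - round(labels)) > 1e-9) || any(labels < 0)) {
    stop("mask must be a non-negative integer raster", call. = FALSE)
  }
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  old <- sort(unique(labels[labels > 0L]))
  if (length(old) > 0L && !identical(old, seq_along(old))) {
    lut <- integer(max(old))
    lut[old] <- seq_along(old)
    pos <- labels > 0L
    labels[pos] <- lut[labels[pos]]
  }
  structure(list(labels = labels, n_labels = length(old), source = source),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d px, %d label(s), source: %s\n",
              nrow(x$labels), ncol(x$labels), x$n_labels, x$source))
  invisible(x)
}

#' Read a label mask from a single-channel integer TIFF
#'
#' Ingests masks exported by an external segmenter. Labels are
#' canonicalized to contiguous `1..n`; a binary (0/1) mask is first split
#' into connected components (4-connectivity) so each blob gets its own
#' label.
#'
#' @param path Path to a single-channel TIFF with integer values.
#' @return A [segmentation_mask()] with `source = "external"`.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) {
    stop("mask must be single-channel, got multi-channel TIFF", call. = FALSE)
  }
  if (is.double(m) && any(abs(m - round(m)) > 1e-6)) {
    stop("mask TIFF is not integer-valued", call. = FALSE)
  }
  m <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  vals <- unique(m[m > 0L])
  if (length(vals) == 1L && vals == 1L) {
    m <- label_components(m > 0L)
  }
  segmentation_mask(m, source = "external")
}

# 4-connected component labeling of a logical matrix (via EBImage).
label_components <- function(binary) {
  lab <- EBImage::bwlabel(binary * 1)
  matrix(as.integer(lab), nrow(binary), ncol(binary))
}

#' Segment bright blobs in a single-channel raster
#'
#' A deterministic classical segmenter for cell-like blobs, intended for
#' synthetic fixtures and quick looks (an external learned segmenter
#' remains the tool of choice for real tissue): Gaussian smoothing with a
#' FWHM of a quarter of the expected diameter, Otsu threshold,
#' 4-connected components, removal of components smaller than 25% of the
#' expected blob area, then a distance-transform watershed (maxima
#' neighborhood at the expected radius) to split merged blobs.
#'
#' @param raster Non-constant numeric matrix (conventionally the 2PF
#'   channel, where cell bodies are brightest).
#' @param estimated_diameter_um Expected blob diameter in micrometres.
#' @param pixel_size_um Pixel pitch in micrometres per pixel.
#' @return A [segmentation_mask()] with `source = "builtin"`.
#' @export
segment_blobs <- function(raster, estimated_diameter_um, pixel_size_um) {
  stopifnot(is.matrix(raster), estimated_diameter_um > 0, pixel_size_um > 0)
  rng <- range(raster)
  if (rng[1] == rng[2]) {
    stop("constant raster cannot be segmented", call. = FALSE)
  }
  diam_px <- estimated_diameter_um / pixel_size_um
  norm <- (raster - rng[1]) / (rng[2] - rng[1])
  sigma <- max(0.5, diam_px / 4 / (2 * sqrt(2 * log(2))))  # FWHM = diam/4
  sm <- matrix(EBImage::gblur(norm, sigma = sigma), nrow(raster), ncol(raster))
  sm[sm < 0] <- 0
  sm[sm > 1] <- 1
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  binary <- sm > thr
  # blobs are a bright minority on background; when the threshold leaves
  # most of the image "foreground" there is no blob/background contrast
  # (featureless noise, smooth gradients) and nothing to segment
  if (mean(binary) > 0.35) {
    return(segmentation_mask(matrix(0L, nrow(raster), ncol(raster)),
                             source = "builtin"))
  }
  lab <- label_components(binary)
  min_area <- 0.25 * pi * (diam_px / 2)^2
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  binary2 <- matrix(lab %in% keep & lab > 0L, nrow(lab), ncol(lab))
  if (!any(binary2)) {
    return(segmentation_mask(matrix(0L, nrow(raster), ncol(raster)),
                             source = "builtin"))
  }
  dm <- EBImage::distmap(EBImage::Image(binary2 * 1))
  ws <- EBImage::watershed(dm, tolerance = 1,
                           ext = max(1L, as.integer(round(diam_px / 2))))
  ws <- matrix(as.integer(ws), nrow(raster), ncol(raster))
  # watershed may create slivers; re-apply the size floor
  sizes2 <- tabulate(ws[ws > 0L])
  drop <- which(sizes2 < min_area)
  if (length(drop) > 0L) ws[ws %in% drop] <- 0L
  segmentation_mask(ws, source = "builtin")
}

#' Collect per-label, per-channel pixel values under a mask
#'
#' Applies one mask identically to every channel of a frame: each labeled
#' region contributes exactly the same pixel set in every channel, and
#' background pixels are excluded.
#'
#' @param frame A [multimodal_frame()].
#' @param mask A [segmentation_mask()] (or label matrix) with the same
#'   dimensions as the frame.
#' @return A long tibble with columns `label`, `channel`, `intensity`;
#'   zero rows when the mask has no labels.
#' @export
apply_mask <- function(frame, mask) {
  stopifnot(inherits(frame, "multimodal_frame"))
  labels <- if (inherits(mask, "segmentation_mask")) mask$labels else mask
  if (!all(dim(labels) == dim(frame))) {
    stop("mask shape ", paste(dim(labels), collapse = "x"),
         " does not match frame shape ", paste(dim(frame), collapse = "x"),
         call. = FALSE)
  }
  fg <- which(labels > 0L)
  if (length(fg) == 0L) {
    return(tibble::tibble(label = integer(0), channel = character(0),
                          intensity = numeric(0)))
  }
  purrr::map_dfr(frame_channels(frame), function(ch) {
    tibble::tibble(label = as.integer(labels[fg]), channel = ch,
                   intensity = frame$channels[[ch]][fg])
  }) |>
    dplyr::arrange(.data$label, .data$channel)
}

#' Per-label, per-channel summary statistics under a mask
#'
#' Convenience wrapper over [apply_mask()] summarizing each region.
#'
#' @inheritParams apply_mask
#' @return A tibble with one row per label and channel: `label`,
#'   `channel`, `n`, `mean`, `median`, `sd`, `p25`, `p75`, `iqr`.
#' @export
mask_channel_stats <- function(frame, mask) {
  apply_mask(frame, mask) |>
    dplyr::group_by(.data$label, .data$channel) |>
    dplyr::group_modify(~ summarize_distribution(.x$intensity)) |>
    dplyr::ungroup()
}
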