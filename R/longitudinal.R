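# Longitudinal analysis of frame sequences: intensity decay, redox-ratio
# trajectories, and lateral drift.

check_series <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 2)
  stopifnot(all(vapply(frames, inherits, logical(1), "multimodal_frame")))
  times <- vapply(frames, function(f) f$time_min, numeric(1))
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  times
}

#' Per-channel mean intensity and percent change over a series
#'
#' For every channel present in all frames, computes the frame mean and
#' the percent change relative to the first frame,
#' `100 * (mean_t - mean_0) / mean_0` — the standard way of tracking
#' intensity decay during tissue degradation. By default the mean runs
#' over all pixels of the frame (frame averages); restricting to
#' mask-positive pixels is available via `masks`.
#'
#' @param frames List of [multimodal_frame()]s with strictly increasing
#'   `time_min`.
#' @param masks Optional list of [segmentation_mask()]s, one per frame;
#'   means are then taken over mask-positive pixels only.
#' @return A tibble with columns `frame`, `time_min`, `channel`,
#'   `mean_intensity`, `pct_change`. A channel whose t = 0 mean is zero
#'   gets `NA` percent change (with a warning); other channels are
#'   unaffected.
#' @export
intensity_trajectory <- function(frames, masks = NULL) {
  times <- check_series(frames)
  if (!is.null(masks)) {
    stopifnot(length(masks) == length(frames))
  }
  chans <- Reduce(intersect, lapply(frames, frame_channels))
  if (length(chans) == 0L) stop("no common channels", call. = FALSE)
  out <- purrr::map_dfr(seq_along(frames), function(k) {
    f <- frames[[k]]
    sel <- if (is.null(masks)) NULL else {
      labs <- if (inherits(masks[[k]], "segmentation_mask"))
        masks[[k]]$labels else masks[[k]]
      labs > 0L
    }
    tibble::tibble(
      frame = k, time_min = times[k], channel = chans,
      mean_intensity = vapply(chans, function(ch) {
        m <- frame_channel(f, ch)
        if (is.null(sel)) mean(m) else mean(m[sel])
      }, numeric(1)))
  })
  base <- out |>
    dplyr::filter(.data$frame == 1L) |>
    dplyr::select("channel", mean_0 = "mean_intensity")
  if (any(base$mean_0 == 0)) {
    warning("channel(s) with zero mean at t = 0: ",
            paste(base$channel[base$mean_0 == 0], collapse = ", "),
            "; percent change undefined (NA)")
  }
  out |>
    dplyr::left_join(base, by = "channel") |>
    dplyr::mutate(pct_change = ifelse(.data$mean_0 == 0, NA_real_,
                                      100 * (.data$mean_intensity - .data$mean_0) /
                                        .data$mean_0)) |>
    dplyr::select(-"mean_0")
}

#' Redox-ratio trajectory over a series
#'
#' Per-frame distribution summaries of the pixelwise optical redox ratio,
#' either over the whole frame (all valid pixels) or restricted to
#' segmentation masks, plus rank-based comparisons between selected
#' timepoints (default: first, middle, and last frame, the usual
#' start/middle/end reporting scheme).
#'
#' @param frames List of [multimodal_frame()]s (2PF and 3PF required).
#' @param masks Optional list of [segmentation_mask()]s, one per frame.
#' @param denom_threshold Validity floor passed to [orr_map()].
#' @param compare_at Integer frame indices to compare (default
#'   first/middle/last); `NULL` to skip comparisons.
#' @return An `orr_trajectory` object: list with `summary` (tibble, one
#'   row per frame with the [summarize_distribution()] columns),
#'   `comparison` (a [compare_groups()] result or NULL), `compare_at`,
#'   and `masked` (logical).
#' @export
orr_trajectory <- function(frames, masks = NULL, denom_threshold = 0,
                           compare_at = NULL) {
  times <- check_series(frames)
  if (!is.null(masks) && length(masks) != length(frames)) {
    stop("need one mask per frame (got ", length(masks), " masks for ",
         length(frames), " frames)", call. = FALSE)
  }
  vals <- purrr::map(seq_along(frames), function(k) {
    m <- orr_map(frames[[k]], denom_threshold)
    orr_values(m, mask = if (is.null(masks)) NULL else masks[[k]])
  })
  summary <- purrr::map_dfr(seq_along(frames), function(k) {
    dplyr::bind_cols(tibble::tibble(frame = k, time_min = times[k]),
                     summarize_distribution(vals[[k]]))
  })
  if (is.null(compare_at)) {
    compare_at <- unique(c(1L, as.integer(ceiling(length(frames) / 2)),
                           length(frames)))
  }
  comparison <- NULL
  if (length(compare_at) >= 2) {
    grp <- vals[compare_at]
    names(grp) <- sprintf("t%g", times[compare_at])
    comparison <- compare_groups(grp)
  }
  structure(list(summary = summary, comparison = comparison,
                 compare_at = compare_at, masked = !is.null(masks)),
            class = "orr_trajectory")
}

#' @export
print.orr_trajectory <- function(x, ...) {
  cat(sprintf("<orr_trajectory> %d frames (%s pixels)\n",
              nrow(x$summary), if (x$masked) "masked" else "whole-frame"))
  print(x$summary)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' @export
tidy.orr_trajectory <- function(x, ...) x$summary

#' @export
glance.orr_trajectory <- function(x, ...) {
  s <- x$summary
  tibble::tibble(n_frames = nrow(s),
                 orr_start = s$mean[1], orr_end = s$mean[nrow(s)],
                 iqr_start = s$iqr[1], iqr_end = s$iqr[nrow(s)],
                 masked = x$masked,
                 comparison_p = if (is.null(x$comparison)) NA_real_ else
                   x$comparison$p)
}

#' Plot a redox-ratio trajectory
#'
#' @param object An `orr_trajectory`.
#' @param ... Unused.
#' @return A ggplot of mean ORR over time with an IQR ribbon.
#' @export
autoplot.orr_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$time_min, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "ORR") +
    ggplot2::theme_minimal()
}

# Parabolic (three-point quadratic) sub-sample peak refinement.
parabolic_offset <- function(m1, c0, p1) {
  denom <- m1 - 2 * c0 + p1
  if (denom == 0) return(0)
  off <- 0.5 * (m1 - p1) / denom
  max(-0.5, min(0.5, off))
}

#' Estimate lateral drift between two frames
#'
#' Phase correlation (normalized cross-power spectrum) with parabolic
#' sub-pixel refinement on one shared channel, converted to micrometres.
#' The returned vector maps reference coordinates onto moving
#' coordinates: if the scene content moved by +d, the estimate is +d.
#' The default channel is SHG, whose structural contrast decays least
#' during tissue degradation.
#'
#' @param reference,moving Two [multimodal_frame()]s of identical shape
#'   and pixel size.
#' @param channel Channel used for registration (default `"SHG"`).
#' @return Named numeric vector `c(dx_um, dy_um)` (x along columns,
#'   y up, consistent with the generator's drift convention).
#' @export
estimate_drift <- function(reference, moving, channel = "SHG") {
  stopifnot(inherits(reference, "multimodal_frame"),
            inherits(moving, "multimodal_frame"))
  if (!all(dim(reference) == dim(moving))) {
    stop("frames have different shapes", call. = FALSE)
  }
  if (reference$pixel_size_um != moving$pixel_size_um) {
    stop("frames have different pixel sizes", call. = FALSE)
  }
  a <- frame_channel(reference, channel)
  b <- frame_channel(moving, channel)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate correlation: constant '", channel, "' channel",
         call. = FALSE)
  }
  nr <- nrow(a); nc <- ncol(a)
  hr <- 0.5 * (1 - cos(2 * pi * (0:(nr - 1)) / (nr - 1)))
  hc <- 0.5 * (1 - cos(2 * pi * (0:(nc - 1)) / (nc - 1)))
  w <- hr %o% hc
  fa <- stats::fft((a - mean(a)) * w)
  fb <- stats::fft((b - mean(b)) * w)
  cross <- fa * Conj(fb)
  mag <- Mod(cross)
  eps <- 1e-12 * max(mag)
  r <- Re(stats::fft(cross / (mag + eps), inverse = TRUE)) / (nr * nc)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) if (i - 1 > n / 2) i - 1 - n else i - 1
  idx <- function(i, n) ((i - 1) %% n) + 1
  dr <- wrap(pk[1], nr)
  dc <- wrap(pk[2], nc)
  off_r <- parabolic_offset(r[idx(pk[1] - 1, nr), pk[2]], r[pk[1], pk[2]],
                            r[idx(pk[1] + 1, nr), pk[2]])
  off_c <- parabolic_offset(r[pk[1], idx(pk[2] - 1, nc)], r[pk[1], pk[2]],
                            r[pk[1], idx(pk[2] + 1, nc)])
  # peak of ifft(F_ref * conj(F_mov)) sits at minus the content shift
  shift_row <- -(dr + off_r)
  shift_col <- -(dc + off_c)
  # content shift (+col, +row-down) -> (x, y-up) physical drift
  px <- reference$pixel_size_um
  c(dx_um = unname(shift_col) * px, dy_um = -unname(shift_row) * px)
}

#' Full longitudinal report for a frame series
#'
#' Bundles the per-channel intensity trajectory, whole-frame and
#' (optionally) masked redox-ratio trajectories, and per-frame drift
#' relative to the first frame.
#'
#' @param frames List of [multimodal_frame()]s.
#' @param masks Optional list of [segmentation_mask()]s, one per frame.
#' @param denom_threshold Passed to [orr_map()].
#' @param drift_channel Channel for [estimate_drift()] (default SHG, with
#'   fallback to the first common channel if SHG is absent).
#' @param compare_at Frame indices for ORR timepoint comparisons.
#' @return A `time_series_result`: list with `times_min`, `intensity`
#'   (tibble), `orr_whole` and `orr_masked` (`orr_trajectory` or NULL),
#'   and `drift` (tibble with `frame`, `time_min`, `drift_x_um`,
#'   `drift_y_um`).
#' @export
analyze_series <- function(frames, masks = NULL, denom_threshold = 0,
                           drift_channel = "SHG", compare_at = NULL) {
  times <- check_series(frames)
  chans <- Reduce(intersect, lapply(frames, frame_channels))
  # drift needs structural contrast: fall back from the requested channel
  # to the first channel that is non-constant in the reference frame
  usable <- chans[vapply(chans, function(ch) {
    stats::sd(frame_channel(frames[[1]], ch)) > 0
  }, logical(1))]
  if (!drift_channel %in% usable) drift_channel <- usable[1]
  intensity <- intensity_trajectory(frames)
  orr_whole <- if (all(c("2PF", "3PF") %in% chans)) {
    orr_trajectory(frames, denom_threshold = denom_threshold,
                   compare_at = compare_at)
  }
  orr_masked <- if (!is.null(masks) && all(c("2PF", "3PF") %in% chans)) {
    orr_trajectory(frames, masks = masks, denom_threshold = denom_threshold,
                   compare_at = compare_at)
  }
  drift <- purrr::map_dfr(seq_along(frames), function(k) {
    d <- if (length(usable) == 0L) c(dx_um = NA_real_, dy_um = NA_real_)
    else if (k == 1L) c(dx_um = 0, dy_um = 0)
    else estimate_drift(frames[[1]], frames[[k]], channel = drift_channel)
    tibble::tibble(frame = k, time_min = times[k],
                   drift_x_um = unname(d[1]), drift_y_um = unname(d[2]))
  })
  structure(list(times_min = times, intensity = intensity,
                 orr_whole = orr_whole, orr_masked = orr_masked,
                 drift = drift, drift_channel = drift_channel),
            class = "time_series_result")
}

#' @export
print.time_series_result <- function(x, ...) {
  cat(sprintf("<time_series_result> %d frames over %.3g min\n",
              length(x$times_min), max(x$times_min)))
  final <- dplyr::filter(x$intensity, .data$frame == max(.data$frame))
  for (j in seq_len(nrow(final))) {
    cat(sprintf("  %s: %+.1f%%\n", final$channel[j], final$pct_change[j]))
  }
  d <- x$drift[nrow(x$drift), ]
  cat(sprintf("  final drift: (%.2f, %.2f) um [%s]\n",
              d$drift_x_um, d$drift_y_um, x$drift_channel))
  invisible(x)
}

#' @export
tidy.time_series_result <- function(x, ...) {
  x$intensity |>
    dplyr::left_join(x$drift, by = c("frame", "time_min"))
}

#' @export
glance.time_series_result <- function(x, ...) {
  final <- dplyr::filter(x$intensity, .data$frame == max(.data$frame))
  wide <- stats::setNames(final$pct_change,
                          paste0("pct_change_", final$channel))
  out <- tibble::tibble(n_frames = length(x$times_min),
                        duration_min = max(x$times_min))
  dplyr::bind_cols(out, tibble::as_tibble(as.list(wide)),
                   tibble::tibble(
                     drift_total_um = sqrt(sum(unlist(
                       x$drift[nrow(x$drift), c("drift_x_um", "drift_y_um")])^2)),
                     orr_start = if (is.null(x$orr_whole)) NA_real_ else
                       x$orr_whole$summary$mean[1],
                     orr_end = if (is.null(x$orr_whole)) NA_real_ else
                       x$orr_whole$summary$mean[nrow(x$orr_whole$summary)]))
}

#' Plot per-channel percent intensity change over time
#'
#' @param object A `time_series_result`.
#' @param ... Unused.
#' @return A ggplot line chart, one line per channel.
#' @export
autoplot.time_series_result <- function(object, ...) {
  ggplot2::ggplot(object$intensity,
                  ggplot2::aes(x = .data$time_min, y = .data$pct_change,
                               color = .data$channel)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "mean intensity change (%)") +
    ggplot2::theme_minimal()
}
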