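#' Pixel-wise optical redox ratio map
#'
#' The optical redox ratio is `ORR = 2PF / (2PF + 3PF)`, the label-free
#' analogue of `FAD / (FAD + NAD(P)H)`; lower values indicate relatively
#' more reduced, glycolytic metabolism. A pixel is valid when
#' `2PF + 3PF > denom_threshold`; elsewhere the ratio is undefined (NA).
#' The default threshold of 0 keeps every pixel with any fluorescence;
#' raising it guards against detector offset pulling background pixels
#' toward ORR = 0.5.
#'
#' @param frame A [multimodal_frame()] with 2PF and 3PF channels.
#' @param denom_threshold Non-negative validity floor on `2PF + 3PF`.
#' @return An `orr_map`: list with `orr` (matrix, NA where invalid),
#'   `valid` (logical matrix), `pixel_size_um`, `time_min`.
#' @export
orr_map <- function(frame, denom_threshold = 0) {
  stopifnot(inherits(frame, "multimodal_frame"), denom_threshold >= 0)
  missing_ch <- setdiff(c("2PF", "3PF"), frame_channels(frame))
  if (length(missing_ch) > 0L) {
    stop("frame lacks channel(s) required for ORR: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  p2 <- frame_channel(frame, "2PF")
  p3 <- frame_channel(frame, "3PF")
  denom <- p2 + p3
  valid <- denom > denom_threshold
  orr <- matrix(NA_real_, nrow(p2), ncol(p2))
  orr[valid] <- p2[valid] / denom[valid]
  structure(list(orr = orr, valid = valid,
                 pixel_size_um = frame$pixel_size_um,
                 time_min = frame$time_min),
            class = "orr_map")
}

#' @export
print.orr_map <- function(x, ...) {
  cat(sprintf("<orr_map> %d x %d px, %d valid (%.1f%%)\n",
              nrow(x$orr), ncol(x$orr), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Extract valid ORR pixel values
#'
#' @param map An [orr_map()].
#' @param mask Optional [segmentation_mask()] or label matrix; when given,
#'   only valid pixels with label > 0 are returned (or a specific label
#'   via `label`).
#' @param label Optional single label to restrict to.
#' @return Numeric vector of ORR values.
#' @export
orr_values <- function(map, mask = NULL, label = NULL) {
  stopifnot(inherits(map, "orr_map"))
  sel <- map$valid
  if (!is.null(mask)) {
    labels <- if (inherits(mask, "segmentation_mask")) mask$labels else mask
    stopifnot(all(dim(labels) == dim(map$orr)))
    sel <- sel & (if (is.null(label)) labels > 0 else labels == label)
  }
  map$orr[sel]
}

#' Summarize a distribution of values
#'
#' Mean, median, standard deviation, 25th/75th percentiles (linear
#' interpolation convention) and the interquartile range
#' `IQR = p75 - p25`, as used for pixel-level redox-ratio distributions.
#'
#' @param values Numeric vector (or an [orr_map()], in which case its
#'   valid pixels are summarized).
#' @param ... Passed to methods.
#' @return A one-row tibble with columns `n`, `mean`, `median`, `sd`,
#'   `p25`, `p75`, `iqr`.
#' @export
summarize_distribution <- function(values, ...) {
  UseMethod("summarize_distribution")
}

#' @rdname summarize_distribution
#' @export
summarize_distribution.default <- function(values, ...) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize", call. = FALSE)
  qs <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    median = stats::median(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    p25 = qs[1], p75 = qs[2],
    iqr = qs[2] - qs[1]
  )
}

#' @rdname summarize_distribution
#' @param mask,label Optional mask restriction, see [orr_values()].
#' @export
summarize_distribution.orr_map <- function(values, mask = NULL,
                                           label = NULL, ...) {
  summarize_distribution(orr_values(values, mask, label))
}

#' Per-channel mean intensity profile of a region
#'
#' The mean intensity of every channel over a common pixel set — the
#' quantity behind radar-plot comparisons of tissue regions (e.g.,
#' fibrotic liver shows a prominent SHG mean from its collagen content).
#'
#' @param frame A [multimodal_frame()].
#' @param region Optional logical matrix, [segmentation_mask()], or label
#'   matrix; non-background pixels define the region. `NULL` uses the
#'   whole frame.
#' @return A tibble with columns `channel` and `mean_intensity`.
#' @export
channel_profile <- function(frame, region = NULL) {
  stopifnot(inherits(frame, "multimodal_frame"))
  if (is.null(region)) {
    sel <- NULL
  } else {
    m <- if (inherits(region, "segmentation_mask")) region$labels else region
    stopifnot(all(dim(m) == dim(frame)))
    sel <- if (is.logical(m)) m else m > 0
    if (!any(sel)) stop("empty region", call. = FALSE)
  }
  tibble::tibble(
    channel = frame_channels(frame),
    mean_intensity = unname(vapply(frame$channels, function(ch) {
      if (is.null(sel)) mean(ch) else mean(ch[sel])
    }, numeric(1)))
  )
}

#' Rank-based comparison of two or more groups
#'
#' Tie-corrected Kruskal-Wallis test with the chi-squared approximation;
#' a difference is called significant when p <= 0.05 (the convention
#' "p over 0.05 is not significant"). With three or more groups all
#' pairwise two-group tests are also computed, reported both raw and
#' Holm-adjusted since pairwise p-values are often quoted without a
#' stated multiplicity correction.
#'
#' @param groups A named or unnamed list of numeric vectors (at least 2).
#' @param alpha Significance level (default 0.05).
#' @return A `group_comparison`: list with `H`, `p`, `significant`,
#'   `n_groups`, and `pairwise` (tibble, or NULL for 2 groups).
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  pooled <- unlist(groups, use.names = FALSE)
  if (all(lengths(groups) == 1L) && length(unique(pooled)) == 1L) {
    stop("degenerate comparison: single identical observations",
         call. = FALSE)
  }
  if (length(unique(pooled)) == 1L) {
    # all pooled values identical: H = 0 by definition, no evidence
    kw <- list(statistic = c("Kruskal-Wallis chi-squared" = 0), p.value = 1)
  } else {
    kw <- stats::kruskal.test(groups)
  }
  pairwise <- NULL
  if (length(groups) > 2L) {
    idx <- utils::combn(length(groups), 2)
    pairwise <- purrr::map_dfr(seq_len(ncol(idx)), function(j) {
      i1 <- idx[1, j]; i2 <- idx[2, j]
      sub <- list(groups[[i1]], groups[[i2]])
      p <- if (length(unique(unlist(sub))) == 1L) 1 else
        stats::kruskal.test(sub)$p.value
      tibble::tibble(group1 = names(groups)[i1],
                     group2 = names(groups)[i2],
                     p_raw = p)
    })
    pairwise$p_holm <- stats::p.adjust(pairwise$p_raw, method = "holm")
    pairwise$significant_raw <- pairwise$p_raw <= alpha
    pairwise$significant_holm <- pairwise$p_holm <= alpha
  }
  structure(list(H = unname(kw$statistic), p = kw$p.value,
                 significant = kw$p.value <= alpha,
                 alpha = alpha, n_groups = length(groups),
                 group_sizes = lengths(groups), pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Kruskal-Wallis H = %.4f, p = %.4g (%s)\n",
              x$H, x$p,
              if (x$significant) "significant" else "not significant"))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (raw / Holm):\n")
    for (j in seq_len(nrow(x$pairwise))) {
      cat(sprintf("    %s vs %s: p = %.4g / %.4g\n",
                  x$pairwise$group1[j], x$pairwise$group2[j],
                  x$pairwise$p_raw[j], x$pairwise$p_holm[j]))
    }
  }
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) {
    tibble::tibble(group1 = NA_character_, group2 = NA_character_,
                   p_raw = x$p, p_holm = x$p,
                   significant_raw = x$significant,
                   significant_holm = x$significant)[0, ]
  } else {
    x$pairwise
  }
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(H = x$H, p = x$p, significant = x$significant,
                 n_groups = x$n_groups)
}

#' Plot an ORR map
#'
#' @param object An [orr_map()].
#' @param ... Unused.
#' @return A ggplot raster of the redox ratio (invalid pixels blank).
#' @export
autoplot.orr_map <- function(object, ...) {
  d <- dim(object$orr)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    orr = as.vector(object$orr)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$orr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "ORR") +
    ggplot2::theme_void()
}

#' Radar-style channel profile plot
#'
#' Polar line plot of per-channel mean intensities, optionally for
#' several regions at once.
#'
#' @param profiles A tibble from [channel_profile()], or a named list of
#'   such tibbles (one per region).
#' @return A ggplot object.
#' @export
plot_channel_profile <- function(profiles) {
  if (inherits(profiles, "data.frame")) profiles <- list(region = profiles)
  df <- purrr::imap_dfr(profiles, function(p, nm) {
    dplyr::mutate(p, region = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel,
                                   y = .data$mean_intensity,
                                   group = .data$region,
                                   color = .data$region)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(y = "mean intensity") +
    ggplot2::theme_minimal()
}
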