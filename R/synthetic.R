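# Synthetic multichannel NLOI scenes with exact ground truth.
#
# Geometry convention used by generators and analysis alike: x runs along
# matrix columns, y runs *up* (i.e., against matrix rows), so an angle
# theta in [0, 180) measured counterclockwise from +x matches the usual
# mathematical orientation convention. Fiber angles are undirected
# (mod 180 degrees), matching the inversion ambiguity of harmonic imaging.

#' Orientation models for synthetic fiber scenes
#'
#' Constructors describing how fiber angles (degrees, undirected, in
#' `[0, 180)`) are drawn: a single fixed angle, a von Mises distribution on
#' the axial circle (mean `mu_deg`, concentration `kappa`), or the uniform
#' distribution.
#'
#' @param theta0_deg,mu_deg Angle in `[0, 180)` degrees.
#' @param kappa Non-negative von Mises concentration; 0 is uniform.
#' @return An orientation model object for [fiber_scene()].
#' @export
orientation_fixed <- function(theta0_deg) {
  stopifnot(theta0_deg >= 0, theta0_deg < 180)
  structure(list(kind = "fixed", theta0_deg = theta0_deg),
            class = "orientation_model")
}

#' @rdname orientation_fixed
#' @export
orientation_von_mises <- function(mu_deg, kappa) {
  stopifnot(mu_deg >= 0, mu_deg < 180, kappa >= 0)
  structure(list(kind = "von_mises", mu_deg = mu_deg, kappa = kappa),
            class = "orientation_model")
}

#' @rdname orientation_fixed
#' @export
orientation_uniform <- function() {
  structure(list(kind = "uniform"), class = "orientation_model")
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution
# on [0, 2*pi); used on doubled angles to sample axial orientations.
sample_von_mises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f)))) %% (2 * pi)
    }
  }
  out
}

sample_orientations <- function(model, n) {
  switch(model$kind,
    fixed = rep(model$theta0_deg, n),
    von_mises = (sample_von_mises(n, 2 * model$mu_deg * pi / 180,
                                  model$kappa) / 2) * 180 / pi,
    uniform = stats::runif(n, 0, 180),
    stop("unknown orientation model", call. = FALSE)
  )
}

#' Configure a synthetic fibrous SHG scene
#'
#' Describes a field of straight fiber segments (anti-aliased capsules)
#' whose orientations are drawn from a configurable angular model,
#' emulating collagen textures ranging from strongly co-aligned bundles
#' to a dense random network.
#'
#' @param image_size_px Image size in pixels (scalar for square, or a
#'   length-2 vector `c(rows, cols)`).
#' @param pixel_size_um Pixel pitch, micrometres per pixel.
#' @param n_fibers Number of fiber segments.
#' @param orientation An orientation model from [orientation_fixed()],
#'   [orientation_von_mises()], or [orientation_uniform()].
#' @param fiber_width_um,fiber_length_um Fiber width and length in
#'   micrometres (each at least one pixel).
#' @param background_level Constant background intensity added to the
#'   rendered raster.
#' @param seed Integer seed making the scene reproducible.
#' @return A `fiber_scene_config` for [generate_fiber_image()].
#' @export
fiber_scene <- function(image_size_px = 256, pixel_size_um = 0.7,
                        n_fibers = 60, orientation = orientation_uniform(),
                        fiber_width_um = 2, fiber_length_um = 60,
                        background_level = 0, seed = 1L) {
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2L)
  stopifnot(all(image_size_px >= 8), pixel_size_um > 0, n_fibers >= 1,
            inherits(orientation, "orientation_model"),
            fiber_width_um >= pixel_size_um,
            fiber_length_um >= pixel_size_um,
            background_level >= 0)
  diag_um <- sqrt(sum((image_size_px * pixel_size_um)^2))
  if (fiber_length_um > diag_um) {
    stop("fiber_length_um exceeds the image diagonal (", round(diag_um, 1),
         " um)", call. = FALSE)
  }
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, n_fibers = as.integer(n_fibers),
                 orientation = orientation, fiber_width_um = fiber_width_um,
                 fiber_length_um = fiber_length_um,
                 background_level = background_level, seed = as.integer(seed)),
            class = "fiber_scene_config")
}

# Additively render one anti-aliased capsule (segment with round caps) into
# `img`. Intensity ramps linearly over one pixel at the boundary.
render_capsule <- function(img, cx, cy, theta_deg, len_px, width_px) {
  th <- theta_deg * pi / 180
  ux <- cos(th); uy <- sin(th)          # y up
  hl <- len_px / 2
  hw <- width_px / 2
  nr <- nrow(img); nc <- ncol(img)
  pad <- hw + 1.5
  x0 <- cx - abs(ux) * hl - pad; x1 <- cx + abs(ux) * hl + pad
  y0 <- cy - abs(uy) * hl - pad; y1 <- cy + abs(uy) * hl + pad
  cols <- max(1L, floor(x0)):min(nc, ceiling(x1))
  rows_y <- max(1L, floor(nr - y1)):min(nr, ceiling(nr - y0))
  if (length(cols) == 0L || length(rows_y) == 0L) return(img)
  px <- outer(rep(1, length(rows_y)), cols) - cx
  py <- (nr - outer(rows_y, rep(1, length(cols)))) - cy   # y up
  t_par <- pmin(hl, pmax(-hl, px * ux + py * uy))
  dx <- px - t_par * ux
  dy <- py - t_par * uy
  dist <- sqrt(dx^2 + dy^2)
  a <- pmin(1, pmax(0, hw + 0.5 - dist))
  img[rows_y, cols] <- img[rows_y, cols] + a
  img
}

#' Generate a synthetic SHG fiber image with ground truth
#'
#' Renders `n_fibers` anti-aliased straight segments at angles drawn from
#' the configured orientation model; overlapping fibers add. The ground
#' truth records every sampled angle, so orientation-analysis results can
#' be checked against the exact generating distribution.
#'
#' @param config A [fiber_scene()] configuration.
#' @return A list with `shg` (numeric matrix) and `ground_truth`
#'   (list with `angles_deg`, `centers_px`, and the config).
#' @export
generate_fiber_image <- function(config) {
  stopifnot(inherits(config, "fiber_scene_config"))
  withr::with_seed(config$seed, {
    n <- config$n_fibers
    d <- config$image_size_px
    angles <- sample_orientations(config$orientation, n)
    cx <- stats::runif(n, 1, d[2])
    cy <- stats::runif(n, 1, d[1])
    img <- matrix(0, d[1], d[2])
    len_px <- config$fiber_length_um / config$pixel_size_um
    wid_px <- config$fiber_width_um / config$pixel_size_um
    for (i in seq_len(n)) {
      img <- render_capsule(img, cx[i], cy[i], angles[i], len_px, wid_px)
    }
    img <- img + config$background_level
    list(shg = img,
         ground_truth = list(angles_deg = angles,
                             centers_px = cbind(x = cx, y = cy),
                             config = config))
  })
}

#' Configure a synthetic cell scene with known per-cell redox ratios
#'
#' Describes a field of non-overlapping round cells whose 2PF and 3PF
#' interior intensities are chosen so every interior pixel of cell *i*
#' satisfies `2PF / (2PF + 3PF) = orr_targets[i]` exactly. THG appears
#' only on cell membranes and lipid-droplet boundaries; droplets
#' additionally carry a 3PF-bright interior, emulating their appearance
#' in liver autofluorescence.
#'
#' @param image_size_px Image size in pixels (scalar or `c(rows, cols)`).
#' @param pixel_size_um Pixel pitch, micrometres per pixel.
#' @param n_cells Number of cells; `orr_targets` must have this length.
#' @param orr_targets Per-cell optical redox ratios in `(0, 1]`.
#' @param cell_radius_um Cell radius (default 5, i.e. 10 um diameter,
#'   a typical hepatocyte scale).
#' @param total_pf_brightness Sum 2PF + 3PF at every interior pixel
#'   (arbitrary detector units).
#' @param n_lipid_droplets Number of lipid droplets placed in the
#'   background (THG ring, 3PF-filled interior).
#' @param droplet_radius_um Lipid droplet radius.
#' @param membrane_thg_level THG intensity on membranes and droplet rings.
#' @param membrane_thickness_um Membrane annulus thickness.
#' @param seed Integer seed.
#' @return A `cell_scene_config` for [generate_cell_scene()].
#' @export
cell_scene <- function(image_size_px = 200, pixel_size_um = 0.5,
                       n_cells = 5,
                       orr_targets = rep(0.85, n_cells),
                       cell_radius_um = 5, total_pf_brightness = 100,
                       n_lipid_droplets = 0, droplet_radius_um = 1.5,
                       membrane_thg_level = 50,
                       membrane_thickness_um = 0.75, seed = 1L) {
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2L)
  stopifnot(all(image_size_px >= 8), pixel_size_um > 0, n_cells >= 0,
            length(orr_targets) == n_cells,
            all(orr_targets > 0), all(orr_targets <= 1),
            cell_radius_um > 0, total_pf_brightness > 0,
            n_lipid_droplets >= 0, membrane_thg_level >= 0)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 orr_targets = as.numeric(orr_targets),
                 cell_radius_um = cell_radius_um,
                 total_pf_brightness = total_pf_brightness,
                 n_lipid_droplets = as.integer(n_lipid_droplets),
                 droplet_radius_um = droplet_radius_um,
                 membrane_thg_level = membrane_thg_level,
                 membrane_thickness_um = membrane_thickness_um,
                 seed = as.integer(seed)),
            class = "cell_scene_config")
}

# Uniform rejection placement of non-overlapping disks; at most `max_attempts`
# draws per disk.
place_disks <- function(n, radius_px, d, existing = NULL,
                        max_attempts = 10000L) {
  centers <- existing
  placed <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- stats::runif(1, radius_px + 2, d[2] - radius_px - 1)
      y <- stats::runif(1, radius_px + 2, d[1] - radius_px - 1)
      all_c <- rbind(centers, placed)
      if (is.null(all_c) || nrow(all_c) == 0L ||
          all(sqrt((all_c[, 1] - x)^2 + (all_c[, 2] - y)^2) >
                all_c[, 3] + radius_px + 1)) {
        placed <- rbind(placed, c(x, y, radius_px))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", n, " non-overlapping objects in ",
           max_attempts, " attempts each", call. = FALSE)
    }
  }
  placed
}

# Hard-edged disk membership masks: interior and membrane annulus.
disk_masks <- function(d, cx, cy, r_px, thick_px) {
  px <- outer(rep(1, d[1]), seq_len(d[2])) - cx
  py <- (d[1] - outer(seq_len(d[1]), rep(1, d[2])))  - cy
  dist <- sqrt(px^2 + py^2)
  list(interior = dist <= (r_px - thick_px),
       membrane = dist > (r_px - thick_px) & dist <= r_px)
}

#' Generate a four-channel cell scene with exact ground-truth redox ratios
#'
#' Produces a noise-free [multimodal_frame()] in which every interior
#' pixel of cell *i* has `2PF = orr_i * B` and `3PF = (1 - orr_i) * B`
#' (`B` = `total_pf_brightness`), so the pixelwise optical redox ratio is
#' exactly `orr_i`. THG is nonzero only on cell membranes and lipid
#' droplet rings; SHG is zero (no fibrous component). The returned label
#' mask marks cell interiors 1..n_cells, background 0.
#'
#' @param config A [cell_scene()] configuration.
#' @return A list with `frame` (a [multimodal_frame()]) and `ground_truth`
#'   (list with `orr`, `label_mask`, `cell_centers_px`, and the config).
#' @export
generate_cell_scene <- function(config) {
  stopifnot(inherits(config, "cell_scene_config"))
  withr::with_seed(config$seed, {
    d <- config$image_size_px
    r_px <- config$cell_radius_um / config$pixel_size_um
    thick_px <- max(1, config$membrane_thickness_um / config$pixel_size_um)
    ch <- list("2PF" = matrix(0, d[1], d[2]),
               "3PF" = matrix(0, d[1], d[2]),
               "SHG" = matrix(0, d[1], d[2]),
               "THG" = matrix(0, d[1], d[2]))
    labels <- matrix(0L, d[1], d[2])
    cells <- if (config$n_cells > 0) place_disks(config$n_cells, r_px, d)
             else matrix(numeric(0), ncol = 3)
    B <- config$total_pf_brightness
    for (i in seq_len(config$n_cells)) {
      mk <- disk_masks(d, cells[i, 1], cells[i, 2], r_px, thick_px)
      orr <- config$orr_targets[i]
      ch[["2PF"]][mk$interior] <- orr * B
      ch[["3PF"]][mk$interior] <- (1 - orr) * B
      ch[["THG"]][mk$membrane] <- config$membrane_thg_level
      labels[mk$interior] <- i
    }
    if (config$n_lipid_droplets > 0) {
      dr_px <- config$droplet_radius_um / config$pixel_size_um
      drops <- place_disks(config$n_lipid_droplets, dr_px, d, existing = cells)
      for (j in seq_len(nrow(drops))) {
        mk <- disk_masks(d, drops[j, 1], drops[j, 2], dr_px,
                         min(thick_px, dr_px / 2))
        ch[["3PF"]][mk$interior] <- B
        ch[["THG"]][mk$membrane] <- config$membrane_thg_level
      }
    } else {
      drops <- matrix(numeric(0), ncol = 3)
    }
    frame <- multimodal_frame(ch, pixel_size_um = config$pixel_size_um,
                              time_min = 0, frame_id = "synthetic-cells")
    list(frame = frame,
         ground_truth = list(orr = config$orr_targets,
                             label_mask = labels,
                             cell_centers_px = cells,
                             droplet_centers_px = drops,
                             config = config))
  })
}

#' Photon and detector noise model
#'
#' Shot noise is modeled as Poisson counting at `photon_scale` expected
#' photons per unit intensity (so an intensity of 1 averages
#' `photon_scale` detected photons), followed by additive Gaussian read
#' noise and a constant detector offset, with clipping at zero.
#'
#' @param photon_scale Expected photons at unit intensity; larger means
#'   less relative shot noise. Imaging practice puts the floor for
#'   reliable redox-ratio work at around 40 photons.
#' @param read_noise_sd Gaussian read noise standard deviation (intensity
#'   units).
#' @param offset Constant detector offset added after noise.
#' @return A `noise_model` object for [apply_noise()].
#' @export
noise_model <- function(photon_scale = 40, read_noise_sd = 0, offset = 0) {
  stopifnot(photon_scale > 0, read_noise_sd >= 0, offset >= 0)
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 offset = offset),
            class = "noise_model")
}

#' Apply photon and detector noise to a raster
#'
#' Computes `Poisson(photon_scale * x) / photon_scale +
#' Gaussian(0, read_noise_sd) + offset`, clipped at zero. Deterministic
#' under a fixed seed.
#'
#' @param raster Non-negative numeric matrix.
#' @param model A [noise_model()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A matrix of the same dimensions.
#' @export
apply_noise <- function(raster, model = noise_model(), seed = NULL) {
  stopifnot(inherits(model, "noise_model"), is.matrix(raster))
  if (any(raster < 0)) stop("input raster has negative pixels", call. = FALSE)
  noisify <- function() {
    n <- length(raster)
    counts <- stats::rpois(n, lambda = model$photon_scale * as.vector(raster))
    out <- counts / model$photon_scale
    if (model$read_noise_sd > 0) out <- out + stats::rnorm(n, 0, model$read_noise_sd)
    out <- out + model$offset
    out[out < 0] <- 0
    matrix(out, nrow(raster), ncol(raster))
  }
  if (is.null(seed)) noisify() else withr::with_seed(seed, noisify())
}

#' Per-channel decay, drift, and drug-response model for time series
#'
#' Each channel's mean intensity decays linearly in time from 1 at t = 0
#' to `1 - decay_fractions[channel]` at `duration_min` (the simplest curve
#' consistent with endpoint percentages reported for degrading tissue).
#' The field of view translates by `drift_um_total` cumulatively (linear
#' in time). An optional staurosporine-style response multiplies the 3PF
#' channel by a piecewise-linear factor rising from 1 to `1 + amplitude`
#' at `rise_end_min` and returning to 1 at the series end, reproducing
#' the transient NAD(P)H increase seen after an apoptosis inducer.
#'
#' @param decay_fractions Named numeric vector in `[0, 1)`, names among
#'   the channel names; total fractional intensity decrease over the
#'   series for each channel.
#' @param duration_min Series duration in minutes.
#' @param n_frames Number of frames (>= 2), uniformly spaced in time.
#' @param drift_um_total Length-2 numeric `c(dx, dy)` total lateral drift
#'   in micrometres (x along columns, y up).
#' @param sts_response Either `NULL` or `list(amplitude =, rise_end_min =)`.
#' @return A `decay_model` object for [simulate_time_series()].
#' @export
decay_model <- function(decay_fractions = c("2PF" = 0.25, "3PF" = 0.60,
                                            "SHG" = 0.30, "THG" = 0.65),
                        duration_min = 62, n_frames = 8,
                        drift_um_total = c(0, 0), sts_response = NULL) {
  stopifnot(all(names(decay_fractions) %in% NLOI_CHANNELS),
            all(decay_fractions >= 0), all(decay_fractions < 1),
            duration_min > 0, n_frames >= 2, length(drift_um_total) == 2)
  if (!is.null(sts_response)) {
    stopifnot(is.list(sts_response),
              !is.null(sts_response$amplitude),
              !is.null(sts_response$rise_end_min),
              sts_response$rise_end_min > 0,
              sts_response$rise_end_min < duration_min)
  }
  structure(list(decay_fractions = decay_fractions,
                 duration_min = duration_min, n_frames = as.integer(n_frames),
                 drift_um_total = as.numeric(drift_um_total),
                 sts_response = sts_response),
            class = "decay_model")
}

sts_factor <- function(t, duration, sts) {
  if (is.null(sts)) return(rep(1, length(t)))
  a <- sts$amplitude
  tr <- sts$rise_end_min
  ifelse(t <= tr, 1 + a * t / tr, 1 + a * (duration - t) / (duration - tr))
}

# Sub-pixel translation by bilinear interpolation with periodic boundary
# conditions; content moves by (dx, dy) with x along columns and y up.
# Wrap-around emulates statistically stationary tissue entering the field
# of view as other tissue leaves it, and keeps frame means exactly equal
# to the pre-drift means.
translate_raster <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  # source coordinates: output pixel (r, c) samples input at
  # col c - dx and row r + dy (y up means +dy shifts content up, i.e.,
  # towards smaller row indices).
  cs <- seq_len(nc) - dx
  rs <- seq_len(nr) + dy
  c0 <- floor(cs); r0 <- floor(rs)
  fc <- cs - c0; fr <- rs - r0
  at <- function(ri, ci) {
    m[((ri - 1) %% nr) + 1L, ((ci - 1) %% nc) + 1L]
  }
  wr <- matrix(fr, nr, nc)
  wc <- matrix(fc, nr, nc, byrow = TRUE)
  at(r0, c0) * (1 - wr) * (1 - wc) +
    at(r0 + 1L, c0) * wr * (1 - wc) +
    at(r0, c0 + 1L) * (1 - wr) * wc +
    at(r0 + 1L, c0 + 1L) * wr * wc
}

#' Simulate a longitudinal imaging series from a base scene
#'
#' Starting from a noise-free base frame, each output frame at time t has
#' every channel scaled by its decay trajectory, the whole scene
#' translated by the cumulative drift (sub-pixel bilinear interpolation
#' with periodic boundaries, emulating stationary tissue entering the
#' field of view as other tissue leaves), the 3PF channel additionally
#' modulated by the staurosporine response when configured, and finally
#' noised when a noise model is supplied. The ground truth records, per
#' frame, the applied per-channel scale factors, the expected channel
#' means (scale factor times base mean, exact for noise-free output), and
#' the imposed drift.
#'
#' @param base A noise-free [multimodal_frame()] (e.g., from
#'   [generate_cell_scene()]).
#' @param decay A [decay_model()].
#' @param noise Optional [noise_model()]; `NULL` for noise-free output.
#' @param seed Integer seed controlling the noise draws.
#' @return A list with `frames` (list of [multimodal_frame()]s with
#'   increasing `time_min`) and `ground_truth` (tibble with one row per
#'   frame and channel: `frame`, `time_min`, `channel`, `scale_factor`,
#'   `expected_mean`, `drift_x_um`, `drift_y_um`).
#' @export
simulate_time_series <- function(base, decay = decay_model(), noise = NULL,
                                 seed = 1L) {
  stopifnot(inherits(base, "multimodal_frame"),
            inherits(decay, "decay_model"))
  times <- seq(0, decay$duration_min, length.out = decay$n_frames)
  chans <- frame_channels(base)
  fr <- decay$decay_fractions
  base_means <- vapply(base$channels, mean, numeric(1))
  d <- dim(base)
  drift_frac <- times / decay$duration_min
  gt <- NULL
  frames <- vector("list", decay$n_frames)
  for (k in seq_along(times)) {
    t <- times[k]
    dx_um <- decay$drift_um_total[1] * drift_frac[k]
    dy_um <- decay$drift_um_total[2] * drift_frac[k]
    dx_px <- dx_um / base$pixel_size_um
    dy_px <- dy_um / base$pixel_size_um
    if (abs(dx_px) >= d[2] || abs(dy_px) >= d[1]) {
      stop("drift pushes the scene fully out of frame", call. = FALSE)
    }
    sts_k <- sts_factor(t, decay$duration_min, decay$sts_response)
    out_ch <- list()
    factors <- numeric(length(chans))
    names(factors) <- chans
    for (ch in chans) {
      frac <- if (ch %in% names(fr)) fr[[ch]] else 0
      f_decay <- 1 - frac * t / decay$duration_min
      f <- unname(f_decay) * if (ch == "3PF") sts_k else 1
      factors[ch] <- f
      raster <- base$channels[[ch]] * f
      if (dx_px != 0 || dy_px != 0) {
        raster <- translate_raster(raster, dx_px, dy_px)
      }
      if (!is.null(noise)) {
        raster <- apply_noise(raster, noise,
                              seed = seed + 1000L * k + match(ch, NLOI_CHANNELS))
      }
      out_ch[[ch]] <- raster
    }
    frames[[k]] <- multimodal_frame(out_ch, base$pixel_size_um,
                                    time_min = t,
                                    frame_id = sprintf("%s_t%03d",
                                                       base$frame_id, k))
    gt <- dplyr::bind_rows(gt, tibble::tibble(
      frame = k, time_min = t, channel = chans,
      scale_factor = unname(factors),
      expected_mean = unname(factors) * unname(base_means[chans]),
      drift_x_um = dx_um, drift_y_um = dy_um))
  }
  list(frames = frames, ground_truth = gt)
}
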