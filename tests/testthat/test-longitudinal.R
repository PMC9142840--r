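make_series <- function(decay, noise = NULL, seed = 1, scene_seed = 4,
                        size = 120, n_cells = 3,
                        orr = c(0.7, 0.8, 0.9), droplets = 2,
                        pixel_size_um = 0.5, with_shg = TRUE) {
  if (with_shg) {
    cf <- combined_frame(size = size, pixel_size_um = pixel_size_um,
                         n_cells = n_cells, orr = orr, droplets = droplets,
                         scene_seed = scene_seed)
  } else {
    sc <- generate_cell_scene(cell_scene(image_size_px = size,
                                         pixel_size_um = pixel_size_um,
                                         n_cells = n_cells,
                                         orr_targets = orr,
                                         n_lipid_droplets = droplets,
                                         seed = scene_seed))
    cf <- list(frame = sc$frame, scene = sc)
  }
  list(scene = cf$scene, frame = cf$frame,
       series = simulate_time_series(cf$frame, decay, noise, seed = seed))
}

test_that("identical frames give zero percent change everywhere", {
  dm <- decay_model(decay_fractions = c("2PF" = 0, "3PF" = 0, "SHG" = 0,
                                        "THG" = 0),
                    duration_min = 10, n_frames = 3)
  s <- make_series(dm)
  tr <- intensity_trajectory(s$series$frames)
  expect_true(all(tr$pct_change[is.finite(tr$pct_change)] == 0))
})

test_that("noise-free decay fractions are recovered exactly", {
  dm <- decay_model(decay_fractions = c("2PF" = 0.25, "3PF" = 0.60,
                                        "SHG" = 0.30, "THG" = 0.65),
                    duration_min = 62, n_frames = 5)
  s <- make_series(dm)
  tr <- intensity_trajectory(s$series$frames)
  final <- tr[tr$frame == 5, ]
  got <- setNames(final$pct_change, final$channel)
  expect_equal(got[c("2PF", "3PF", "SHG", "THG")],
               c("2PF" = -25, "3PF" = -60, "SHG" = -30, "THG" = -65),
               tolerance = 1e-9)
  expect_true(all(tr$pct_change[tr$frame == 1] == 0))
})

test_that("decay recovery tolerates shot noise at the 40-photon scale", {
  dm <- decay_model(decay_fractions = c("2PF" = 0.25, "3PF" = 0.60,
                                        "SHG" = 0.30, "THG" = 0.65),
                    duration_min = 62, n_frames = 5)
  s <- make_series(dm, noise = noise_model(photon_scale = 40), seed = 21,
                   size = 150)
  tr <- intensity_trajectory(s$series$frames)
  final <- tr[tr$frame == 5, ]
  got <- setNames(final$pct_change, final$channel)
  want <- c("2PF" = -25, "3PF" = -60, "SHG" = -30, "THG" = -65)
  expect_true(all(abs(got[names(want)] - want) < 5))
})

test_that("a zero-mean channel yields NA without poisoning the others", {
  # a bare cell scene carries no SHG signal
  dm <- decay_model(decay_fractions = c("2PF" = 0.2), duration_min = 10,
                    n_frames = 3)
  s <- make_series(dm, with_shg = FALSE)
  expect_warning(tr <- intensity_trajectory(s$series$frames), "SHG")
  expect_true(all(is.na(tr$pct_change[tr$channel == "SHG" & tr$frame > 1])))
  expect_true(all(is.finite(tr$pct_change[tr$channel == "2PF"])))
})

test_that("faster 3PF decay drives the ORR trajectory strictly upward", {
  dm <- decay_model(decay_fractions = c("2PF" = 0.25, "3PF" = 0.60,
                                        "SHG" = 0.30, "THG" = 0.65),
                    duration_min = 62, n_frames = 6)
  s <- make_series(dm, droplets = 0)
  ot <- orr_trajectory(s$series$frames)
  expect_true(all(diff(ot$summary$mean) > 0))
})

test_that("the drug-response series dips and recovers at the programmed time", {
  dm <- decay_model(decay_fractions = c("2PF" = 0.25, "3PF" = 0.60,
                                        "SHG" = 0.30, "THG" = 0.65),
                    duration_min = 60, n_frames = 13,
                    sts_response = list(amplitude = 0.8, rise_end_min = 30))
  s <- make_series(dm, droplets = 0)
  ot <- orr_trajectory(s$series$frames)
  turning_frame <- which.min(abs(ot$summary$time_min - 30))
  dip <- which.min(ot$summary$mean)
  expect_lte(abs(dip - turning_frame), 1)
  expect_true(all(diff(ot$summary$mean[1:dip]) < 0))
  expect_true(all(diff(ot$summary$mean[dip:nrow(ot$summary)]) > 0))
})

test_that("a static series has constant ORR summaries", {
  dm <- decay_model(decay_fractions = c("2PF" = 0, "3PF" = 0, "SHG" = 0,
                                        "THG" = 0),
                    duration_min = 10, n_frames = 3)
  s <- make_series(dm)
  ot <- orr_trajectory(s$series$frames)
  expect_equal(ot$summary$mean, rep(ot$summary$mean[1], 3), tolerance = 1e-12)
  expect_equal(ot$summary$iqr, rep(ot$summary$iqr[1], 3), tolerance = 1e-12)
})

test_that("masked and whole-frame ORR trajectories are both available", {
  dm <- decay_model(duration_min = 62, n_frames = 4)
  s <- make_series(dm, droplets = 3)
  masks <- replicate(4, segmentation_mask(s$scene$ground_truth$label_mask,
                                          source = "ground_truth"),
                     simplify = FALSE)
  whole <- orr_trajectory(s$series$frames)
  masked <- orr_trajectory(s$series$frames, masks = masks)
  expect_false(whole$masked)
  expect_true(masked$masked)
  # masked pooling excludes droplet pixels, so the two differ
  expect_false(isTRUE(all.equal(whole$summary$mean, masked$summary$mean)))
  # timepoint comparison defaults to first/middle/last
  expect_equal(masked$compare_at, c(1L, 2L, 4L))
  expect_s3_class(masked$comparison, "group_comparison")
  expect_error(orr_trajectory(s$series$frames, masks = masks[1:2]),
               "one mask per frame")
})

test_that("drift estimation is exact for self-comparison and sub-pixel otherwise", {
  dm <- decay_model(decay_fractions = c("2PF" = 0), duration_min = 10,
                    n_frames = 2, drift_um_total = c(14.7, 0))
  s <- make_series(dm, size = 150, pixel_size_um = 0.35, scene_seed = 6)
  f1 <- s$series$frames[[1]]
  f2 <- s$series$frames[[2]]

  self <- estimate_drift(f1, f1, channel = "2PF")
  expect_equal(unname(self), c(0, 0), tolerance = 1e-9)

  d <- estimate_drift(f1, f2, channel = "2PF")
  expect_lt(abs(d["dx_um"] - 14.7), 0.5 * 0.35)   # within half a pixel
  expect_lt(abs(d["dy_um"]), 0.5 * 0.35)

  # antisymmetry
  rev <- estimate_drift(f2, f1, channel = "2PF")
  expect_equal(unname(rev), -unname(d), tolerance = 0.35 / 2)

  flat <- multimodal_frame(list("2PF" = matrix(1, 150, 150)), 0.35)
  expect_error(estimate_drift(flat, flat, channel = "2PF"), "degenerate")
})

test_that("drift survives shot noise to within a pixel", {
  dm <- decay_model(decay_fractions = c("2PF" = 0), duration_min = 10,
                    n_frames = 2, drift_um_total = c(14.7, 0))
  s <- make_series(dm, noise = noise_model(photon_scale = 40), seed = 33,
                   size = 150, pixel_size_um = 0.35, scene_seed = 6)
  d <- estimate_drift(s$series$frames[[1]], s$series$frames[[2]],
                      channel = "2PF")
  expect_lt(abs(d["dx_um"] - 14.7), 0.35)
  expect_lt(abs(d["dy_um"]), 0.35)
})

test_that("the full series report recovers decay, drift, and ORR jointly", {
  dm <- decay_model(decay_fractions = c("2PF" = 0.25, "3PF" = 0.60,
                                        "SHG" = 0.30, "THG" = 0.65),
                    duration_min = 62, n_frames = 5,
                    drift_um_total = c(15, 0))
  s <- make_series(dm, size = 180, pixel_size_um = 0.35, scene_seed = 8,
                   droplets = 0)
  # the scene drifts, so each timepoint is segmented independently
  masks <- lapply(s$series$frames, function(f) {
    segment_blobs(frame_channel(f, "2PF"), estimated_diameter_um = 10,
                  pixel_size_um = 0.35)
  })
  res <- analyze_series(s$series$frames, masks = masks,
                        drift_channel = "2PF")
  expect_s3_class(res, "time_series_result")
  # drift at the last frame close to the imposed 15 um in x
  last <- res$drift[res$drift$frame == 5, ]
  expect_lt(abs(last$drift_x_um - 15), 0.5 * 0.35)
  # decay is approximate because drift moves content past the frame edge
  final <- res$intensity[res$intensity$frame == 5, ]
  got <- setNames(final$pct_change, final$channel)
  expect_lt(abs(got["3PF"] - (-60)), 5)
  expect_lt(abs(got["2PF"] - (-25)), 5)
  td <- tidy(res)
  expect_true(all(c("pct_change", "drift_x_um") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_frames, 5)
})

test_that("series inputs are validated", {
  fr <- multimodal_frame(list("2PF" = matrix(1, 8, 8)), 0.5, time_min = 0)
  fr2 <- multimodal_frame(list("2PF" = matrix(1, 8, 8)), 0.5, time_min = 0)
  expect_error(intensity_trajectory(list(fr, fr2)), "strictly increasing")
  expect_error(intensity_trajectory(list(fr)), "length")
})
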