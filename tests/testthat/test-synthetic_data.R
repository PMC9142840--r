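test_that("fixed-orientation scenes record exactly the requested angle", {
  cfg <- fiber_scene(image_size_px = 128, n_fibers = 50,
                     orientation = orientation_fixed(30),
                     fiber_length_um = 40, seed = 3)
  res <- generate_fiber_image(cfg)
  expect_true(all(res$ground_truth$angles_deg == 30))
  expect_equal(length(res$ground_truth$angles_deg), 50)
  expect_true(all(res$shg >= 0))
})

test_that("von Mises orientations concentrate around the requested mean", {
  cfg <- fiber_scene(image_size_px = 128, n_fibers = 500,
                     orientation = orientation_von_mises(45, 8),
                     fiber_length_um = 40, seed = 11)
  a <- generate_fiber_image(cfg)$ground_truth$angles_deg
  expect_lt(abs(axial_mean_deg(a) - 45), 2)
  expect_true(all(a >= 0 & a < 180))
})

test_that("uniform orientations pass a Rayleigh uniformity check", {
  cfg <- fiber_scene(image_size_px = 128, n_fibers = 1000,
                     orientation = orientation_uniform(),
                     fiber_length_um = 40, seed = 5)
  a <- generate_fiber_image(cfg)$ground_truth$angles_deg
  # Rayleigh test on doubled angles; do not reject uniformity at alpha 0.01
  phi <- 2 * a * pi / 180
  n <- length(phi)
  rbar2 <- mean(cos(phi))^2 + mean(sin(phi))^2
  z <- n * rbar2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  expect_gt(p, 0.01)
})

test_that("fiber config validation rejects impossible geometry", {
  expect_error(fiber_scene(image_size_px = 64, pixel_size_um = 0.5,
                           fiber_length_um = 500),
               "diagonal")
  expect_error(orientation_fixed(180))
  expect_error(orientation_von_mises(45, -1))
})

test_that("cell scenes encode the requested redox ratio exactly", {
  # symmetric case: ORR 0.5 means equal 2PF and 3PF everywhere inside
  one <- generate_cell_scene(cell_scene(image_size_px = 80, n_cells = 1,
                                        orr_targets = 0.5, seed = 2))
  inside <- one$ground_truth$label_mask == 1
  expect_gt(sum(inside), 0)
  expect_equal(frame_channel(one$frame, "2PF")[inside],
               frame_channel(one$frame, "3PF")[inside])

  sc <- generate_cell_scene(cell_scene(image_size_px = 150, n_cells = 3,
                                       orr_targets = c(0.72, 0.86, 0.94),
                                       seed = 3))
  p2 <- frame_channel(sc$frame, "2PF")
  p3 <- frame_channel(sc$frame, "3PF")
  for (i in 1:3) {
    px <- sc$ground_truth$label_mask == i
    expect_equal(mean(p2[px] / (p2[px] + p3[px])),
                 sc$ground_truth$orr[i], tolerance = 1e-12)
  }
  # THG only on membranes: no interior pixel carries THG
  thg <- frame_channel(sc$frame, "THG")
  expect_true(all(thg[sc$ground_truth$label_mask > 0] == 0))
})

test_that("an empty cell scene is background only", {
  sc <- generate_cell_scene(cell_scene(image_size_px = 64, n_cells = 0,
                                       orr_targets = numeric(0), seed = 1))
  expect_true(all(sc$ground_truth$label_mask == 0))
  expect_true(all(frame_channel(sc$frame, "2PF") == 0))
})

test_that("lipid droplets carry THG rings and 3PF interiors outside cells", {
  sc <- generate_cell_scene(cell_scene(image_size_px = 120, n_cells = 2,
                                       orr_targets = c(0.8, 0.9),
                                       n_lipid_droplets = 3, seed = 8))
  thg <- frame_channel(sc$frame, "THG")
  p3 <- frame_channel(sc$frame, "3PF")
  bg <- sc$ground_truth$label_mask == 0
  expect_gt(sum(thg[bg] > 0), 0)       # droplet rings in background
  expect_gt(sum(p3[bg] > 0), 0)        # droplet interiors in background
})

test_that("noise statistics follow the Poisson-plus-Gaussian model", {
  r <- matrix(1, 100, 100)
  nm <- noise_model(photon_scale = 40, offset = 0.2)
  out <- apply_noise(r, nm, seed = 6)
  se <- sqrt(1 / 40) / 100             # sd of the mean of 10^4 pixels
  expect_lt(abs(mean(out) - 1.2), 3 * se)
  # near-noiseless limit
  big <- apply_noise(r, noise_model(photon_scale = 1e6), seed = 6)
  expect_lt(max(abs(big - 1)), 0.01)
  # determinism and error handling
  expect_identical(apply_noise(r, nm, seed = 9), apply_noise(r, nm, seed = 9))
  expect_error(apply_noise(matrix(-1, 2, 2), nm, seed = 1), "negative")
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- fiber_scene(image_size_px = 96, n_fibers = 20, seed = 42,
                     fiber_length_um = 30)
  expect_identical(generate_fiber_image(cfg), generate_fiber_image(cfg))
  cs <- cell_scene(image_size_px = 96, n_cells = 4,
                   orr_targets = c(0.7, 0.8, 0.9, 0.95), seed = 42)
  expect_identical(generate_cell_scene(cs), generate_cell_scene(cs))
})

test_that("a static series reproduces the base frame", {
  sc <- generate_cell_scene(cell_scene(image_size_px = 80, n_cells = 2,
                                       orr_targets = c(0.8, 0.9), seed = 4))
  dm <- decay_model(decay_fractions = c("2PF" = 0, "3PF" = 0,
                                        "SHG" = 0, "THG" = 0),
                    duration_min = 10, n_frames = 3)
  ser <- simulate_time_series(sc$frame, dm)
  for (f in ser$frames) expect_equal(f$channels, sc$frame$channels)
})

test_that("decay endpoints hit the configured fractions exactly", {
  cf <- combined_frame(size = 100, n_cells = 3, orr = c(0.7, 0.8, 0.9),
                       droplets = 2, scene_seed = 4)
  dm <- decay_model(decay_fractions = c("2PF" = 0.25, "3PF" = 0.60,
                                        "SHG" = 0.30, "THG" = 0.65),
                    duration_min = 62, n_frames = 5)
  ser <- simulate_time_series(cf$frame, dm)
  last <- ser$frames[[5]]
  base_means <- vapply(cf$frame$channels, mean, numeric(1))
  got <- vapply(last$channels, mean, numeric(1))
  expect_equal(unname(got / base_means),
               c(0.75, 0.40, 0.70, 0.35), tolerance = 1e-12)
  # ground truth records the same expectation
  gt5 <- ser$ground_truth[ser$ground_truth$frame == 5, ]
  expect_equal(gt5$expected_mean, unname(got[gt5$channel]), tolerance = 1e-12)
})

test_that("imposed drift is recorded in pixels as configured", {
  sc <- generate_cell_scene(cell_scene(image_size_px = 150,
                                       pixel_size_um = 0.35, n_cells = 2,
                                       orr_targets = c(0.8, 0.9), seed = 6))
  dm <- decay_model(decay_fractions = c("2PF" = 0), duration_min = 10,
                    n_frames = 10, drift_um_total = c(15, 0))
  ser <- simulate_time_series(sc$frame, dm)
  gt <- ser$ground_truth[ser$ground_truth$frame == 10 &
                           ser$ground_truth$channel == "2PF", ]
  expect_equal(gt$drift_x_um / 0.35, 15 / 0.35, tolerance = 1e-12)
  expect_equal(gt$drift_x_um / 0.35, 42.857, tolerance = 1e-3)
})

test_that("decay trajectories are monotone except the STS-driven 3PF bump", {
  sc <- generate_cell_scene(cell_scene(image_size_px = 100, n_cells = 3,
                                       orr_targets = c(0.7, 0.8, 0.9),
                                       seed = 4))
  dm <- decay_model(duration_min = 60, n_frames = 13,
                    sts_response = list(amplitude = 0.8, rise_end_min = 30))
  ser <- simulate_time_series(sc$frame, dm)
  gt <- ser$ground_truth
  for (ch in c("2PF", "SHG", "THG")) {
    tr <- gt$scale_factor[gt$channel == ch]
    expect_true(all(diff(tr) <= 1e-12))
  }
  p3 <- gt$scale_factor[gt$channel == "3PF"]
  peak <- which.max(p3)
  expect_equal(gt$time_min[gt$channel == "3PF"][peak], 30)
  expect_true(all(diff(p3[1:peak]) > 0))
  expect_true(all(diff(p3[peak:length(p3)]) < 0))
})

test_that("excessive drift is rejected", {
  sc <- generate_cell_scene(cell_scene(image_size_px = 64, n_cells = 1,
                                       orr_targets = 0.8, seed = 2))
  dm <- decay_model(duration_min = 10, n_frames = 2,
                    drift_um_total = c(1000, 0))
  expect_error(simulate_time_series(sc$frame, dm), "out of frame")
})
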