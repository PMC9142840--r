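test_that("frame construction enforces shape, naming, and value invariants", {
  m <- matrix(1, 8, 8)
  f <- multimodal_frame(list("2PF" = m, SHG = m * 2), 0.5, time_min = 3)
  expect_s3_class(f, "multimodal_frame")
  expect_equal(dim(f), c(8L, 8L))
  expect_setequal(frame_channels(f), c("2PF", "SHG"))

  expect_error(multimodal_frame(list(FOO = m), 0.5), "unknown channel")
  expect_error(multimodal_frame(list("2PF" = m, "3PF" = matrix(1, 4, 4)), 0.5),
               "identical dimensions")
  expect_error(multimodal_frame(list("2PF" = m - 2), 0.5), "non-negative")
  expect_error(multimodal_frame(list("2PF" = m), -1), "positive")
  expect_error(multimodal_frame(list(), 0.5), "non-empty")
})

test_that("write/read round trip is exact for integer counts and keeps metadata", {
  set.seed(41)
  ch <- list("2PF" = matrix(rpois(120, 80), 10, 12),
             "3PF" = matrix(rpois(120, 30), 10, 12),
             "SHG" = matrix(rpois(120, 55), 10, 12),
             "THG" = matrix(rpois(120, 10), 10, 12))
  fr <- multimodal_frame(ch, pixel_size_um = 0.35, time_min = 27,
                         frame_id = "roundtrip")
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame(fr, path)
  fr2 <- read_frame(path)
  expect_identical(fr2$channels, fr$channels)
  expect_identical(fr2$pixel_size_um, 0.35)
  expect_identical(fr2$time_min, 27)
  expect_identical(fr2$frame_id, "roundtrip")
})

test_that("non-integer intensities survive the round trip to high precision", {
  ch <- list(SHG = matrix(runif(64) * 3.7, 8, 8))
  fr <- multimodal_frame(ch, 0.7)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame(fr, path)
  fr2 <- read_frame(path)
  expect_lt(max(abs(fr2$channels$SHG - ch$SHG)), 1e-8)
})

test_that("pixel size derives from a declared field of view", {
  # 600 x 600 px declared as a 210 um field of view -> 0.35 um/px
  m <- matrix(rpois(600 * 600, 20), 600, 600)
  fr <- multimodal_frame(list(SHG = m), pixel_size_um = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame(fr, path)
  fr2 <- read_frame(path, metadata = list(channels = "SHG", fov_um = 210))
  expect_equal(fr2$pixel_size_um, 0.35)
})

test_that("reading fails cleanly on metadata problems", {
  m <- matrix(rpois(64, 9), 8, 8)
  fr <- multimodal_frame(list(SHG = m), 0.5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame(fr, path)
  expect_error(read_frame(path, metadata = list(channels = c("SHG", "THG"))),
               "declares 2 channel")
  expect_error(read_frame(path, metadata = list(channels = "SHG")),
               "pixel_size_um")
  expect_error(read_frame(path, metadata = list(pixel_size_um = 1)),
               "channels")
  # single declared channel works; others simply absent
  fr3 <- read_frame(path, metadata = list(channels = "SHG",
                                          pixel_size_um = 0.5))
  expect_identical(frame_channels(fr3), "SHG")
})

test_that("contrast saturation follows the linear-interpolation quantile rule", {
  r <- matrix(1:100, 10, 10)
  out <- adjust_contrast(r, 0.05)
  # the 95th-percentile clip saturates at least ceil(0.05 * N) pixels
  expect_gte(sum(out == 1), ceiling(0.05 * 100))
  expect_true(all(out[r >= 96] == 1))
  expect_gte(min(out[r == 95]), 0.999)
  # brute-force quantile: everything at or above q maps to 1, below stays < 1
  q <- oracle_percentile(as.vector(r), 0.95)
  expect_true(all((out == 1) == (r >= q)))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("zero saturation is a pure min-max rescale", {
  set.seed(7)
  r <- matrix(runif(81, 2, 9), 9, 9)
  out <- adjust_contrast(r, 0)
  expect_equal(sum(out == 1), 1)          # only the max saturates
  expect_equal(out, (r - min(r)) / (max(r) - min(r)))
})

test_that("constant rasters warn and return zeros", {
  expect_warning(out <- adjust_contrast(matrix(5, 4, 4), 0.05), "constant")
  expect_true(all(out == 0))
})

test_that("contrast adjustment is idempotent and affine-invariant", {
  set.seed(13)
  r <- matrix(rgamma(400, 2), 20, 20)
  once <- adjust_contrast(r, 0.05)
  expect_equal(adjust_contrast(once, 0), once, tolerance = 1e-12)
  # positive affine rescale of the input changes nothing
  expect_equal(adjust_contrast(3.2 * r + 11, 0.05), once, tolerance = 1e-12)
})

test_that("pseudo-color merge tints, combines additively, and clips", {
  m <- matrix(rpois(64, 40), 8, 8)
  fr <- multimodal_frame(list("2PF" = m), 0.5)
  disp <- merge_pseudocolor(fr, color_map = list("2PF" = "green"))
  expect_s3_class(disp, "display_image")
  expect_true(all(disp$rgb[, , 1] == 0) && all(disp$rgb[, , 3] == 0))
  expect_true(all(disp$rgb >= 0 & disp$rgb <= 1))

  # disjoint supports never co-light a pixel
  a <- matrix(0, 8, 8); a[1:4, ] <- rpois(32, 50) + 1
  b <- matrix(0, 8, 8); b[5:8, ] <- rpois(32, 50) + 1
  fr2 <- multimodal_frame(list("2PF" = a, "3PF" = b), 0.5)
  disp2 <- merge_pseudocolor(fr2, color_map = list("2PF" = "red",
                                                   "3PF" = "green"))
  overlap <- sum(disp2$rgb[, , 1] > 0 & disp2$rgb[, , 2] > 0)
  expect_identical(overlap, 0L)

  # all-zero frame -> all-zero display (constant-raster warning absorbed)
  fr0 <- multimodal_frame(list("2PF" = matrix(0, 8, 8)), 0.5)
  expect_true(all(merge_pseudocolor(fr0)$rgb == 0))

  expect_error(merge_pseudocolor(fr, color_map = list(THG = "blue")),
               "absent")
})

test_that("display images export to PNG", {
  fr <- multimodal_frame(list(SHG = matrix(rpois(64, 20), 8, 8)), 0.5)
  disp <- merge_pseudocolor(fr)
  path <- withr::local_tempfile(fileext = ".png")
  write_display_png(disp, path)
  back <- png::readPNG(path)
  expect_equal(dim(back)[1:2], c(8L, 8L))
})
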