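test_that("TIFF and PNG round trips preserve camera units at all bit depths", {
  tmp <- withr::local_tempdir()
  for (bits in c(8L, 16L)) {
    maxv <- 2^bits - 1
    set.seed(bits)
    px <- matrix(sample(0:maxv, 64 * 64, replace = TRUE), 64, 64)
    img <- gray_image(px, exposure_ms = 50, bit_depth = bits)
    exts <- if (bits == 8L) c("tif", "png") else "tif"
    for (ext in exts) {
      p <- file.path(tmp, paste0("rt", bits, ".", ext))
      write_image(img, p)
      back <- read_image(p, exposure_ms = 50)
      expect_identical(unname(back$pixels), unname(px * 1.0))
      expect_equal(back$bit_depth, bits)
    }
  }
  # PNG containers are 8-bit; deeper data is refused rather than degraded
  img16 <- gray_image(matrix(30000, 4, 4), exposure_ms = 10, bit_depth = 16)
  expect_error(write_image(img16, file.path(tmp, "x.png")), "8-bit")
})

test_that("constant 16-bit image reads back with metadata attached", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  write_image(gray_image(matrix(100, 64, 64), exposure_ms = 50), tmp)
  img <- read_image(tmp, exposure_ms = 50, pixel_size_um = 0.5)
  expect_equal(min(img$pixels), 100)
  expect_equal(max(img$pixels), 100)
  expect_equal(img$exposure_ms, 50)
  expect_equal(img$pixel_size_um, 0.5)
})

test_that("metadata never alters pixels; contract violations raise named errors", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  write_image(gray_image(matrix(0:24, 5, 5), exposure_ms = 10), tmp)
  a <- read_image(tmp, exposure_ms = 10)
  b <- read_image(tmp, exposure_ms = 250)
  expect_identical(a$pixels, b$pixels)

  rgb <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), rgb)
  expect_error(read_image(rgb, exposure_ms = 10), "not single-channel")
  expect_error(read_image("no/such/file.tif", exposure_ms = 10), "unreadable")
  expect_error(gray_image(matrix(0, 2, 2), exposure_ms = 0), "exposure")
  expect_error(gray_image(matrix(0, 2, 2), exposure_ms = -5), "exposure")
})

test_that("12-in-16-bit data warn (not fail) only when values exceed the stated depth", {
  expect_silent(gray_image(matrix(4000, 2, 2), exposure_ms = 1, bit_depth = 12))
  expect_warning(gray_image(matrix(5000, 2, 2), exposure_ms = 1, bit_depth = 12),
                 "bit_depth")
})

test_that("label maps compact to contiguous 0..K", {
  lab <- label_map(matrix(c(0L, 7L, 7L, 0L, 3L, 0L, 9L, 9L, 0L), 3))
  cl <- compact_labels(lab)
  expect_setequal(unique(as.integer(cl)), 0:3)
  expect_equal(n_labels(cl), 3L)
  # relabeling preserves region structure
  expect_equal(as.integer(table(as.integer(lab)[lab > 0])),
               as.integer(table(as.integer(cl)[cl > 0])))
})

test_that("overlay: empty map reproduces the rescaled base; particles add outlines and glyphs", {
  tmp <- withr::local_tempdir()
  px <- matrix(seq(0, 1000, length.out = 40 * 40), 40, 40)
  img <- gimg(px)
  p0 <- file.path(tmp, "empty.png")
  write_overlay(img, label_map(matrix(0L, 40, 40)), p0)
  arr <- png::readPNG(p0)
  base <- (px - min(px)) / diff(range(px))
  expect_equal(max(abs(arr[, , 1] - base)), 0, tolerance = 1 / 254)
  expect_equal(arr[, , 1], arr[, , 2])  # gray: channels equal

  # one disk: at least one outline pixel differs from base
  m <- matrix(0L, 40, 40); m[disk_mask(8, 40)] <- 1L
  p1 <- file.path(tmp, "one.png")
  write_overlay(img, label_map(m), p1)
  arr1 <- png::readPNG(p1)
  expect_gt(sum(abs(arr1[, , 2] - arr1[, , 1]) > 0.2), 0)

  # three particles: three distinct digit glyph clusters, magenta colored
  m3 <- matrix(0L, 60, 60)
  m3[disk_mask(6, 60, centre = c(12, 12))] <- 1L
  m3[disk_mask(6, 60, centre = c(12, 45))] <- 2L
  m3[disk_mask(6, 60, centre = c(45, 30))] <- 3L
  p3 <- file.path(tmp, "three.png")
  write_overlay(gimg(matrix(100, 60, 60) + diag(60)), label_map(m3), p3)
  arr3 <- png::readPNG(p3)
  # glyph pixels inside each disk interior (away from the outline)
  glyphs <- arr3[, , 1] > 0.9 & arr3[, , 2] < 0.1
  for (k in 1:3) {
    centre <- list(c(12, 12), c(12, 45), c(45, 30))[[k]]
    local <- glyphs[centre[1] + (-3:3), centre[2] + (-3:3)]
    expect_gt(sum(local), 0)
  }
  expect_error(write_overlay(img, label_map(matrix(0L, 10, 10)), p0),
               "shape mismatch")
})

test_that("measurement CSV is deterministic, ordered, and round-trips to 6 significant digits", {
  tmp <- withr::local_tempdir()
  rows <- data.frame(
    condition = c("b", "a", "a"), bead_id = c(1L, 2L, 1L),
    area_px = c(300, 310, 320), circularity = c(0.91, 0.97, 1 / 3),
    mean_intensity_raw = c(500.123456, 2.5, pi * 100),
    mean_intensity_corrected = c(480.2, 1.5, 300.00001),
    intensity_per_ms = c(4.802, 0.015, 3.0000001))
  p1 <- file.path(tmp, "m1.csv"); p2 <- file.path(tmp, "m2.csv")
  write_measurements(rows, p1)
  write_measurements(rows, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_measurements(p1)
  expect_equal(nrow(back), 3L)
  expect_equal(back$condition, c("a", "a", "b"))       # sorted
  expect_equal(back$bead_id, c(1L, 2L, 1L))
  ord <- rows[order(rows$condition, rows$bead_id), ]
  for (col in names(rows)[3:7])
    expect_equal(back[[col]], signif(ord[[col]], 6), tolerance = 1e-6)
  expect_error(write_measurements(rows[0, ], file.path(tmp, "e.csv")),
               "empty")
})
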