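make_disk_scene <- function(value, blank = 0, exposure = 100) {
  px <- paint_disk(matrix(0, 90, 90), c(45, 45), 20, value)
  lab <- label_map(matrix(as.integer(px > 0), 90, 90))
  list(img = gimg(px, exposure_ms = exposure), lab = lab)
}

test_that("bead means, blank subtraction and exposure normalization", {
  s <- make_disk_scene(500)
  m0 <- measure_beads(s$img, s$lab, blank_autofluorescence = 0)
  expect_equal(m0$mean_intensity_raw, 500)
  expect_equal(m0$mean_intensity_corrected, 500)
  expect_equal(m0$intensity_per_ms, 5.0)

  m1 <- measure_beads(s$img, s$lab, blank_autofluorescence = 100)
  expect_equal(m1$mean_intensity_corrected, 400)
  expect_equal(m1$intensity_per_ms, 4.0)
  expect_false(m1$floored)

  # blank larger than signal floors at 0 with the flag set
  m2 <- measure_beads(s$img, s$lab, blank_autofluorescence = 600)
  expect_equal(m2$mean_intensity_corrected, 0)
  expect_true(m2$floored)

  # invariant: per-ms is exactly corrected / exposure
  expect_equal(m1$intensity_per_ms,
               m1$mean_intensity_corrected / s$img$exposure_ms)
})

test_that("halo bead mean matches the area-weighted analytic integral", {
  # I(r) = 200 + 300 * (r/R): area-weighted mean = 200 + 300 * 2/3 = 400
  n <- 201; R <- 90
  g <- expand.grid(r = 1:n, c = 1:n)
  d <- sqrt((g$r - 101)^2 + (g$c - 101)^2)
  px <- matrix(0, n, n)
  inside <- d <= R
  px[as.matrix(g)[inside, ]] <- 200 + 300 * (d[inside] / R)
  lab <- label_map(matrix(as.integer(inside), n, n))
  m <- measure_beads(gimg(px), lab)
  expect_equal(m$mean_intensity_raw, 400, tolerance = 0.02)
})

test_that("saturated beads are flagged and excluded by default", {
  px <- paint_disk(matrix(0, 60, 120), c(30, 30), 10, 255)
  px <- paint_disk(px, c(30, 90), 10, 100)
  img <- gimg(px, bit_depth = 8)
  lab <- label_components(px > 0)
  excl <- measure_beads(img, lab)
  expect_equal(nrow(excl), 1L)
  flag <- measure_beads(img, lab, saturation_policy = "flag")
  expect_equal(nrow(flag), 2L)
  expect_equal(sum(flag$saturated), 1L)
})

test_that("lysate input: exposure normalization and mock correction", {
  mk <- function(mean, exp) gimg(matrix(mean, 50, 50), exposure_ms = exp)
  expect_equal(as.numeric(measure_lysate_input(mk(600, 100), mk(100, 100))), 5.0)
  # differing exposures are normalized before subtraction
  expect_equal(as.numeric(measure_lysate_input(mk(600, 200), mk(100, 100))), 2.0)
  # lysate == mock -> 0, not flagged (exactly zero)
  expect_equal(as.numeric(measure_lysate_input(mk(100, 100), mk(100, 100))), 0)
  # below mock -> floored with warning
  expect_warning(v <- measure_lysate_input(mk(90, 100), mk(100, 100)),
                 "floored")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "floored"))
})

test_that("affinity formula and normalizer arithmetic", {
  mk_cond <- function(per_ms, prey, bait) {
    meas <- data.frame(bead_id = seq_along(per_ms), area_px = 300,
                       mean_intensity_raw = per_ms * 100,
                       mean_intensity_corrected = per_ms * 100,
                       intensity_per_ms = per_ms,
                       floored = FALSE, saturated = FALSE)
    assay_condition("c", meas, bait_input = bait, prey_input_per_ms = prey,
                    exposure_ms = 100)
  }
  expect_equal(ibrp_affinity(mk_cond(100, 1, 1))$affinity_mean, 100)
  expect_equal(ibrp_affinity(mk_cond(200, 2, 2))$affinity_mean, 50)
  r <- ibrp_affinity(mk_cond(c(8, 10, 12), 2, 1))
  expect_equal(r$affinity_mean, 5)
  expect_equal(r$affinity_sd, sd(c(4, 5, 6)))
  expect_equal(r$n, 3L)
  expect_error(ibrp_affinity(mk_cond(100, 0, 1)), "prey")
  expect_error(ibrp_affinity(mk_cond(100, 1, -2)), "bait")

  # recomputing the summary from per-bead values reproduces it exactly
  expect_identical(r$affinity_mean, mean(r$per_bead))
  expect_identical(r$affinity_sd, sd(r$per_bead))
  expect_identical(r$n, length(r$per_bead))
})

test_that("relative affinities scale the maximum to exactly 100", {
  mk <- function(m, s = 1) structure(
    list(condition_id = "x", affinity_mean = m, affinity_sd = s, n = 5L,
         per_bead = rep(m, 5), relative_affinity = NA_real_,
         relative_sd = NA_real_), class = "affinity_result")
  r <- relative_affinities(list(mk(50), mk(100), mk(25)))
  expect_equal(vapply(r, `[[`, 1, "relative_affinity"), c(50, 100, 25))
  r2 <- relative_affinities(list(mk(2, 0.5), mk(4, 1)))
  expect_equal(vapply(r2, `[[`, 1, "relative_affinity"), c(50, 100))
  expect_equal(vapply(r2, `[[`, 1, "relative_sd"), c(12.5, 25))
  expect_equal(relative_affinities(list(mk(7)))[[1]]$relative_affinity, 100)
  expect_error(relative_affinities(list(mk(0), mk(0))), "zero")
})

test_that("snr is bead mean over background SD, with dilated exclusion zone", {
  set.seed(5)
  n <- 200
  px <- matrix(rnorm(n * n, 0, 100), n, n)
  mask <- disk_mask(20, n, centre = c(60, 60)) |
    disk_mask(20, n, centre = c(140, 140))
  px[mask] <- 400
  lab <- label_components(mask)
  img <- gimg(px)
  got <- snr(img, lab)
  expect_equal(got, 4.0, tolerance = 0.1)
  # pure rescaling leaves SNR unchanged
  img2 <- gimg(px * 3)
  expect_equal(snr(img2, lab), got, tolerance = 1e-9)
  # noiseless background errors
  flat <- gimg(paint_disk(matrix(0, 80, 80), c(40, 40), 10, 100))
  flat_lab <- label_components(flat$pixels > 0)
  expect_error(snr(flat, flat_lab), "zero background variance")
})
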