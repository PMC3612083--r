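small_spec <- function(...) {
  args <- list(image_shape = c(300, 300), n_beads = 8, seed = 3)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(scene_spec, args)
}

test_that("empty and noiseless scenes render exactly as specified", {
  sp <- small_spec(n_beads = 0, noise_sd = 0, background_level = 120,
                   illumination = list(type = "planar", amplitude = 60))
  sc <- render_scene(sp)
  want <- 120 + matrix(60 * (rep(1:300, each = 300) - 1) / 299, 300,
                       byrow = FALSE)
  expect_equal(sc$image$pixels, round(want), tolerance = 0)
  expect_equal(n_labels(sc$truth$labels), 0L)

  # one uniform bead, no noise/illumination: mean over true mask is exact
  sp1 <- small_spec(n_beads = 1, noise_sd = 0, background_level = 0,
                    base_intensity = 250, diameter_cv = 0)
  sc1 <- render_scene(sp1, quantize = FALSE)
  lab <- sc1$truth$labels
  expect_equal(mean(sc1$image$pixels[lab == 1]), 250)
  expect_equal(sc1$truth$beads$true_mean_intensity, 250)
})

test_that("ground truth is self-consistent for uniform and halo profiles", {
  for (prof in c("uniform", "halo")) {
    sp <- small_spec(n_beads = 5, noise_sd = 0, background_level = 0,
                     intensity_profile = prof)
    sc <- render_scene(sp, quantize = FALSE)
    lab <- unclass(sc$truth$labels)
    tb <- sc$truth$beads
    expect_equal(n_labels(sc$truth$labels), 5L)
    for (k in tb$label)
      expect_equal(mean(sc$image$pixels[lab == k]),
                   tb$true_mean_intensity[k], tolerance = 1e-12)
    # halo beads are rim-bright: mean exceeds the center intensity
    if (prof == "halo")
      expect_true(all(tb$true_mean_intensity > sp$base_intensity))
  }
})

test_that("rendering is deterministic and respects the seed", {
  a <- render_scene(small_spec(noise_sd = 30))
  b <- render_scene(small_spec(noise_sd = 30))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(unclass(a$truth$labels), unclass(b$truth$labels))
  c <- render_scene(small_spec(noise_sd = 30, seed = 4))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("generated noise hits the requested signal-to-noise regime", {
  # bead signal 200 over noise SD 50 -> SNR 4 (measured on the unclipped
  # float render with ground-truth masks)
  sp <- scene_spec(image_shape = c(400, 400), n_beads = 6,
                   base_intensity = 200, background_level = 0,
                   noise_sd = 50, seed = 8)
  sc <- render_scene(sp, quantize = FALSE)
  got <- snr(sc$image, sc$truth$labels)
  expect_equal(got, 4.0, tolerance = 0.2)
})

test_that("impossible packing raises an error naming the achievable count", {
  sp <- scene_spec(image_shape = c(150, 150), n_beads = 50, seed = 1)
  expect_error(render_scene(sp), "beads cannot be placed")
})

test_that("touching pairs merge into one component and are split by watershed", {
  sp <- scene_spec(image_shape = c(400, 400), n_beads = 6,
                   touching_fraction = 1, noise_sd = 0,
                   background_level = 0, diameter_cv = 0, seed = 2)
  sc <- render_scene(sp)
  mask <- sc$image$pixels > 100
  ncomp <- n_labels(label_components(mask))
  expect_lt(ncomp, 6L)             # pairs touch
  nsplit <- n_labels(watershed_split(mask))
  expect_equal(nsplit, 6L)         # watershed recovers all beads
})

test_that("assay series: noiseless single-bead recovery is exact and scaling is linear", {
  sc <- scene_spec(image_shape = c(240, 240), noise_sd = 0,
                   background_level = 0, diameter_cv = 0)
  ser <- simulate_assay_series(affinity_true = 0.02, bait_inputs = 2,
                               prey_inputs = 3, exposure_ms = 100,
                               bead_cv = 0, n_beads = 1, scene = sc,
                               lysate_noise_sd = 0, mock_level = 1,
                               seed = 5)
  cd <- ser$conditions[[1]]
  lab <- cd$truth$labels
  raw_mean <- mean(cd$image$pixels[lab == 1])
  per_ms <- raw_mean / cd$exposure_ms
  prey <- as.numeric(measure_lysate_input(cd$lysate_img, ser$mock_img))
  aff <- per_ms / (prey * cd$bait_input)
  expect_equal(aff, 0.02, tolerance = 0.005)   # to quantization

  # doubling the true affinity doubles the bead intensity
  ser2 <- simulate_assay_series(affinity_true = 0.04, bait_inputs = 2,
                                prey_inputs = 3, exposure_ms = 100,
                                bead_cv = 0, n_beads = 1, scene = sc,
                                lysate_noise_sd = 0, mock_level = 1,
                                seed = 5)
  cd2 <- ser2$conditions[[1]]
  raw2 <- mean(cd2$image$pixels[cd2$truth$labels == 1])
  expect_equal(raw2 / raw_mean, 2, tolerance = 0.01)
})

test_that("assay series ground truth scales with both inputs", {
  sc <- scene_spec(image_shape = c(300, 300), noise_sd = 0,
                   background_level = 0, diameter_cv = 0)
  ser <- simulate_assay_series(affinity_true = 0.01,
                               bait_inputs = c(3, 9), prey_inputs = c(1, 6),
                               exposure_ms = 100, bead_cv = 0, n_beads = 3,
                               scene = sc, lysate_noise_sd = 0, seed = 6)
  means <- vapply(ser$conditions, function(cd)
    mean(cd$truth$beads$true_mean_intensity), numeric(1))
  pred <- 0.01 * ser$grid$bait * ser$grid$prey * 100
  expect_equal(means, pred, tolerance = 1e-9)
})
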