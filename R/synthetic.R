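#' Specification of a synthetic bead field
#'
#' Describes one synthetic micrograph of glutathione-agarose beads carrying
#' fluorescent prey, emulating the assay's imaging conditions: a 1040 x 1392
#' px field at 0.5 um/px (a 0.7 x 0.5 mm field of view), 50-200 beads per
#' field, bead diameters around 30 um (homogeneous fill) or 90 um
#' (peripheral-bright "halo" profile, from limited prey diffusion into large
#' beads), additive low-frequency illumination gradients, Gaussian camera
#' noise, and a fraction of beads placed as touching pairs.
#'
#' Bead diameters are drawn from a normal distribution with 10 percent CV
#' (truncated at 3 SD), so the size filter is exercised realistically.
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_size_um pixel size at the sample plane.
#' @param n_beads target bead count.
#' @param bead_diameter_um nominal bead diameter (30 for small beads, 90 for
#'   large).
#' @param diameter_cv coefficient of variation of bead diameters.
#' @param intensity_profile \code{"uniform"} (constant disk) or
#'   \code{"halo"} (intensity rising linearly from center to rim).
#' @param halo_ratio rim/center intensity ratio for the halo profile.
#' @param base_intensity bead signal above background, camera units. For the
#'   halo profile this is the center intensity.
#' @param background_level constant background (camera bias + ambient),
#'   camera units.
#' @param illumination \code{list(type = "none"|"planar"|"vignette",
#'   amplitude = <camera units>)}: a left-to-right linear tilt or a radial
#'   falloff toward the corners.
#' @param noise_sd SD of additive Gaussian camera noise. The default
#'   (\code{base_intensity / 4}) reproduces the hardest reported operating
#'   regime of the assay, signal-to-noise ~ 4.
#' @param touching_fraction fraction of beads placed as touching pairs.
#' @param exposure_ms exposure metadata attached to the render.
#' @param bit_depth camera bit depth for quantization.
#' @param seed integer seed; identical spec + seed give bit-identical
#'   images.
#' @return A list of class \code{scene_spec}.
#' @export
scene_spec <- function(image_shape = c(1040, 1392),
                       pixel_size_um = 0.5,
                       n_beads = 100,
                       bead_diameter_um = 30,
                       diameter_cv = 0.10,
                       intensity_profile = c("uniform", "halo"),
                       halo_ratio = 3,
                       base_intensity = 200,
                       background_level = 200,
                       illumination = list(type = "none", amplitude = 0),
                       noise_sd = base_intensity / 4,
                       touching_fraction = 0,
                       exposure_ms = 100,
                       bit_depth = 16,
                       seed = 1L) {
  intensity_profile <- match.arg(intensity_profile)
  stopifnot(n_beads >= 0, noise_sd >= 0,
            touching_fraction >= 0, touching_fraction <= 1,
            pixel_size_um > 0, bead_diameter_um > 0)
  structure(list(image_shape = image_shape, pixel_size_um = pixel_size_um,
                 n_beads = n_beads, bead_diameter_um = bead_diameter_um,
                 diameter_cv = diameter_cv,
                 intensity_profile = intensity_profile,
                 halo_ratio = halo_ratio,
                 base_intensity = base_intensity,
                 background_level = background_level,
                 illumination = illumination,
                 noise_sd = noise_sd,
                 touching_fraction = touching_fraction,
                 exposure_ms = exposure_ms,
                 bit_depth = bit_depth, seed = as.integer(seed)),
            class = "scene_spec")
}

# Place n bead centers (with per-bead radii) in the field: no overlap except
# designated touching pairs, all beads fully interior. Returns a data frame
# center_r, center_c, radius_px, pair_id (NA for singletons).
place_beads <- function(nr, nc, radii, touching_fraction) {
  n <- length(radii)
  if (n == 0L)
    return(data.frame(center_r = numeric(), center_c = numeric(),
                      radius_px = numeric(), pair_id = integer()))
  n_pairs <- floor(touching_fraction * n / 2)
  placed_r <- numeric(0); placed_c <- numeric(0); placed_rad <- numeric(0)
  pair_id <- rep(NA_integer_, n)
  order_rad <- radii  # place in given order
  i <- 1L; tries_total <- 0L; max_tries <- 2000L * n
  while (i <= n) {
    rad <- order_rad[i]
    as_pair <- (i %% 2L == 0L) && (i / 2L <= n_pairs)
    ok <- FALSE
    for (t in seq_len(2000L)) {
      tries_total <- tries_total + 1L
      if (as_pair) {
        # attach to the previous bead at ~90% of the sum of radii
        ang <- runif(1, 0, 2 * pi)
        d <- 0.9 * (rad + placed_rad[i - 1L])
        cr <- placed_r[i - 1L] + d * sin(ang)
        cc <- placed_c[i - 1L] + d * cos(ang)
      } else {
        cr <- runif(1, rad + 2, nr - rad - 1)
        cc <- runif(1, rad + 2, nc - rad - 1)
      }
      if (cr < rad + 2 || cr > nr - rad - 1 ||
          cc < rad + 2 || cc > nc - rad - 1) next
      if (length(placed_r)) {
        dd <- sqrt((placed_r - cr)^2 + (placed_c - cc)^2)
        lim <- placed_rad + rad + 3
        if (as_pair) lim[i - 1L] <- 0   # partner may touch
        if (any(dd < lim)) next
      }
      ok <- TRUE
      break
    }
    if (!ok && !as_pair) {
      # dart throwing can jam well below the packing limit; scan a jittered
      # grid of candidate centers before declaring the field full
      step <- max(2, rad / 2)
      cand <- if (nr - rad - 1 >= rad + 2 && nc - rad - 1 >= rad + 2) {
        expand.grid(r = seq(rad + 2, nr - rad - 1, by = step),
                    c = seq(rad + 2, nc - rad - 1, by = step))
      } else data.frame(r = numeric(), c = numeric())
      if (nrow(cand)) cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      for (j in seq_len(nrow(cand))) {
        cr <- cand$r[j] + runif(1, -1, 1)
        cc <- cand$c[j] + runif(1, -1, 1)
        if (cr < rad + 2 || cr > nr - rad - 1 ||
            cc < rad + 2 || cc > nc - rad - 1) next
        dd <- sqrt((placed_r - cr)^2 + (placed_c - cc)^2)
        if (all(dd >= placed_rad + rad + 3)) { ok <- TRUE; break }
      }
    }
    if (!ok)
      stop("beads cannot be placed: field accommodates only ", i - 1L,
           " of ", n, call. = FALSE)
    placed_r[i] <- cr; placed_c[i] <- cc; placed_rad[i] <- rad
    if (as_pair) { pair_id[i] <- i %/% 2L; pair_id[i - 1L] <- i %/% 2L }
    i <- i + 1L
  }
  data.frame(center_r = placed_r, center_c = placed_c,
             radius_px = placed_rad, pair_id = pair_id)
}

#' Render a synthetic bead micrograph with exact ground truth
#'
#' Builds the pixel raster \code{background + illumination + bead signal +
#' Gaussian noise}, quantized and clipped to the camera bit depth (set
#' \code{quantize = FALSE} to obtain the unclipped floating-point render,
#' useful when the analytic noise statistics must be preserved exactly).
#' The uniform profile renders each bead as a constant disk; the halo
#' profile as \code{I(r) = I_c + (I_rim - I_c) * (r/R)}, intensity rising
#' linearly from center to rim.
#'
#' @param spec a [scene_spec()].
#' @param quantize round and clip pixel values to the bit depth.
#' @return A list with \code{image} (a [gray_image()]) and \code{truth}
#'   (list: \code{labels}, a [label_map()] assigning each bead's true
#'   pixels; \code{beads}, data frame with center, radius and exact mean
#'   signal intensity over the bead's pixels; \code{spec} echoed back).
#' @export
render_scene <- function(spec, quantize = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  rad_nom <- spec$bead_diameter_um / 2 / spec$pixel_size_um
  n <- spec$n_beads
  radii <- if (n > 0) {
    sdr <- spec$diameter_cv * rad_nom
    r <- rnorm(n, rad_nom, sdr)
    pmin(pmax(r, rad_nom - 3 * sdr), rad_nom + 3 * sdr)
  } else numeric(0)
  beads <- place_beads(nr, nc, radii, spec$touching_fraction)

  signal <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc)
  # nearest-center ownership where touching pairs overlap
  dist_own <- matrix(Inf, nr, nc)
  true_mean <- numeric(nrow(beads))
  for (k in seq_len(nrow(beads))) {
    cr <- beads$center_r[k]; cc <- beads$center_c[k]; R <- beads$radius_px[k]
    r1 <- max(1L, floor(cr - R)); r2 <- min(nr, ceiling(cr + R))
    c1 <- max(1L, floor(cc - R)); c2 <- min(nc, ceiling(cc + R))
    rr <- r1:r2; ccs <- c1:c2
    d <- sqrt(outer((rr - cr)^2, (ccs - cc)^2, "+"))
    inside <- d <= R
    prof <- if (spec$intensity_profile == "uniform") {
      matrix(spec$base_intensity, length(rr), length(ccs))
    } else {
      ic <- spec$base_intensity
      ic + (spec$halo_ratio * ic - ic) * (d / R)
    }
    sub_lab <- labels[rr, ccs]
    sub_sig <- signal[rr, ccs]
    sub_own <- dist_own[rr, ccs]
    claim <- inside & (d < sub_own)
    sub_lab[claim] <- k
    sub_sig[claim] <- prof[claim]
    sub_own[claim] <- d[claim]
    labels[rr, ccs] <- sub_lab
    signal[rr, ccs] <- sub_sig
    dist_own[rr, ccs] <- sub_own
  }
  for (k in seq_len(nrow(beads)))
    true_mean[k] <- if (any(labels == k)) mean(signal[labels == k]) else NA

  illum <- matrix(0, nr, nc)
  if (spec$illumination$type == "planar") {
    illum <- matrix(spec$illumination$amplitude *
                      (col(illum) - 1) / (nc - 1), nr, nc)
  } else if (spec$illumination$type == "vignette") {
    d2 <- outer((seq_len(nr) - (nr + 1) / 2)^2,
                (seq_len(nc) - (nc + 1) / 2)^2, "+")
    illum <- spec$illumination$amplitude * (1 - d2 / max(d2))
  }

  px <- spec$background_level + illum + signal
  if (spec$noise_sd > 0)
    px <- px + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  if (quantize) {
    px <- pmin(pmax(round(px), 0), 2^spec$bit_depth - 1)
  }
  img <- gray_image(px, exposure_ms = spec$exposure_ms,
                    bit_depth = spec$bit_depth,
                    pixel_size_um = spec$pixel_size_um)
  truth_beads <- cbind(beads,
                       data.frame(label = seq_len(nrow(beads)),
                                  true_mean_intensity = true_mean))
  list(image = img,
       truth = list(labels = label_map(labels), beads = truth_beads,
                    spec = spec))
}

#' Simulate a full assay series over a bait x prey input grid
#'
#' Generates the image set of a multi-condition pull-down in which the true
#' expected bead intensity per millisecond equals
#' \code{affinity_true * bait * prey} -- the linear input-output regime the
#' assay operates in. Per-bead brightness varies lognormally with the stated
#' CV (beads differ in bait loading and packing). Each condition gets a bead
#' field plus a lysate-well image (mean fluorescence \code{prey * exposure +
#' mock autofluorescence}) and a shared mock-lysate image. The default grid
#' is the assay's characterization design: bait inputs 3, 6 and 9 ug/ul
#' crossed with four prey levels spanning a 6-fold range.
#'
#' @param affinity_true the true affinity constant (camera units per ms per
#'   unit prey per unit bait).
#' @param bait_inputs,prey_inputs input grids (positive).
#' @param exposure_ms bead-image exposure, single value or one per
#'   condition, or \code{NULL} (default) to pick each condition's exposure
#'   so the expected bead intensity lands at \code{target_intensity} --
#'   mirroring how exposure times are adapted per condition at the
#'   microscope to fill the camera's dynamic range. The affinity statistic
#'   must undo exactly this variation, so the default exercises it.
#' @param target_intensity expected bead intensity (camera units) under
#'   auto-exposure.
#' @param bead_cv lognormal per-bead intensity CV.
#' @param n_beads beads per condition field.
#' @param scene template [scene_spec()] for field geometry, background,
#'   noise and bead size (intensity fields are overridden per condition).
#' @param lysate_shape pixel size of lysate/mock well images.
#' @param mock_level mock-lysate autofluorescence per ms (camera units/ms).
#' @param lysate_noise_sd noise SD of the lysate images.
#' @param seed master seed; per-condition seeds are derived from it.
#' @return A list of class \code{assay_series}: \code{conditions} (each with
#'   \code{condition_id}, \code{bait_input}, \code{prey_input_true},
#'   \code{exposure_ms}, \code{image}, \code{truth}, \code{lysate_img}),
#'   \code{mock_img}, and the generating parameters.
#' @export
simulate_assay_series <- function(affinity_true,
                                  bait_inputs = c(3, 6, 9),
                                  prey_inputs = c(1, 2, 4, 6),
                                  exposure_ms = NULL,
                                  target_intensity = 2000,
                                  bead_cv = 0.15,
                                  n_beads = 100,
                                  scene = scene_spec(),
                                  lysate_shape = c(128, 128),
                                  mock_level = 1,
                                  lysate_noise_sd = 20,
                                  seed = 1L) {
  stopifnot(affinity_true > 0, all(bait_inputs > 0), all(prey_inputs > 0))
  grid <- expand.grid(bait = bait_inputs, prey = prey_inputs,
                      KEEP.OUT.ATTRS = FALSE)
  ncond <- nrow(grid)
  exposure_ms <- if (is.null(exposure_ms)) {
    round(target_intensity / (affinity_true * grid$bait * grid$prey), 1)
  } else rep(exposure_ms, length.out = ncond)
  set.seed(seed)
  cond_seeds <- sample.int(2^30, ncond + 1L)

  # shared mock-lysate image; lysate wells are imaged at their own
  # exposure (chosen for their brightness, like at the microscope) --
  # measure_lysate_input() normalizes the difference away
  lysate_target <- 10000
  set.seed(cond_seeds[ncond + 1L])
  mexp <- round(lysate_target / mock_level, 1)
  mock_px <- mock_level * mexp +
    matrix(rnorm(prod(lysate_shape), 0, lysate_noise_sd), lysate_shape[1])
  mock_img <- gray_image(pmax(round(mock_px), 0), exposure_ms = mexp,
                         bit_depth = scene$bit_depth, channel_tag = "GFP")

  conditions <- vector("list", ncond)
  for (ci in seq_len(ncond)) {
    bait <- grid$bait[ci]; prey <- grid$prey[ci]; texp <- exposure_ms[ci]
    sp <- scene
    sp$seed <- cond_seeds[ci]
    sp$n_beads <- n_beads
    mean_per_ms <- affinity_true * bait * prey
    sp$base_intensity <- mean_per_ms * texp
    sp$exposure_ms <- texp
    set.seed(cond_seeds[ci])
    # lognormal per-bead variation with the stated CV, mean 1
    sdlog <- sqrt(log(1 + bead_cv^2))
    bead_factor <- rlnorm(n_beads, -sdlog^2 / 2, sdlog)
    sc <- render_scene_perbead(sp, bead_factor)
    # lysate image of this condition's prey input, at its own exposure
    lexp <- round(lysate_target / (prey + mock_level), 1)
    lys_px <- (prey + mock_level) * lexp +
      matrix(rnorm(prod(lysate_shape), 0, lysate_noise_sd), lysate_shape[1])
    lys <- gray_image(pmax(round(lys_px), 0), exposure_ms = lexp,
                      bit_depth = scene$bit_depth, channel_tag = "GFP")
    conditions[[ci]] <- list(
      condition_id = sprintf("bait%g_prey%g", bait, prey),
      bait_input = bait, prey_input_true = prey,
      exposure_ms = texp, image = sc$image, truth = sc$truth,
      lysate_img = lys)
  }
  structure(list(conditions = conditions, mock_img = mock_img,
                 affinity_true = affinity_true, grid = grid,
                 bead_cv = bead_cv, seed = seed),
            class = "assay_series")
}

# render_scene with a per-bead brightness multiplier (internal to the
# assay-series simulator; reuses placement and rendering of render_scene by
# scaling each bead's profile).
render_scene_perbead <- function(spec, bead_factor) {
  base <- render_scene(spec_noiseless(spec), quantize = FALSE)
  lab <- unclass(base$truth$labels)
  px <- base$image$pixels
  sig <- px - background_field(spec)
  for (k in seq_along(bead_factor)) {
    sel <- lab == k
    sig[sel] <- sig[sel] * bead_factor[k]
  }
  px <- background_field(spec) + sig
  set.seed(spec$seed + 1L)
  if (spec$noise_sd > 0)
    px <- px + matrix(rnorm(length(px), 0, spec$noise_sd), nrow(px))
  px <- pmin(pmax(round(px), 0), 2^spec$bit_depth - 1)
  img <- gray_image(px, exposure_ms = spec$exposure_ms,
                    bit_depth = spec$bit_depth,
                    pixel_size_um = spec$pixel_size_um)
  truth <- base$truth
  truth$beads$true_mean_intensity <-
    truth$beads$true_mean_intensity * bead_factor[truth$beads$label]
  list(image = img, truth = truth)
}

spec_noiseless <- function(spec) { spec$noise_sd <- 0; spec }

background_field <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  illum <- matrix(0, nr, nc)
  if (spec$illumination$type == "planar") {
    illum <- matrix(spec$illumination$amplitude *
                      (col(illum) - 1) / (nc - 1), nr, nc)
  } else if (spec$illumination$type == "vignette") {
    d2 <- outer((seq_len(nr) - (nr + 1) / 2)^2,
                (seq_len(nc) - (nc + 1) / 2)^2, "+")
    illum <- spec$illumination$amplitude * (1 - d2 / max(d2))
  }
  spec$background_level + illum
}
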