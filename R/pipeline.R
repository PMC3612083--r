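#' Full pipeline parameter set
#'
#' One object holding every tunable of the pipeline, with defaults equal to
#' the assay's standard recipe: Gaussian radius 1 px, rolling-ball radius
#' 400 px, automatic (Otsu) threshold, minimum particle area 200 px^2,
#' circularity 0.60-1.00, edge particles excluded, watershed enabled.
#'
#' @param gaussian_radius_px sigma of the denoising Gaussian (px).
#' @param ball_radius_px rolling-ball radius (px).
#' @param threshold_method,threshold_value see [seg_params()].
#' @param min_area_px,circularity_min,circularity_max,exclude_edges,watershed
#'   see [seg_params()].
#' @param blank_autofluorescence scalar blank-bead autofluorescence (camera
#'   units) subtracted from every bead mean.
#' @param saturation_policy \code{"exclude"}, \code{"flag"} or
#'   \code{"ignore"}.
#' @param background_correction \code{"residual"} (default) subtracts the
#'   mean residual background of the corrected image (see
#'   [residual_background()]) from every bead mean; \code{"none"} skips it.
#' @param snr_dilation_px mask dilation for the SNR background region.
#' @return A list of class \code{pipeline_params}.
#' @export
pipeline_params <- function(gaussian_radius_px = 1,
                            ball_radius_px = 400,
                            threshold_method = "otsu",
                            threshold_value = NULL,
                            min_area_px = 200,
                            circularity_min = 0.60,
                            circularity_max = 1.00,
                            exclude_edges = TRUE,
                            watershed = TRUE,
                            blank_autofluorescence = 0,
                            saturation_policy = "exclude",
                            background_correction = c("residual", "none"),
                            snr_dilation_px = 3) {
  background_correction <- match.arg(background_correction)
  structure(list(gaussian_radius_px = gaussian_radius_px,
                 ball_radius_px = ball_radius_px,
                 seg = seg_params(threshold_method, threshold_value,
                                  min_area_px, circularity_min,
                                  circularity_max, exclude_edges, watershed),
                 blank_autofluorescence = blank_autofluorescence,
                 saturation_policy = saturation_policy,
                 background_correction = background_correction,
                 snr_dilation_px = snr_dilation_px),
            class = "pipeline_params")
}

#' Read pipeline parameters from a YAML config file
#'
#' Recognized keys mirror the arguments of [pipeline_params()] (with
#' \code{threshold.method} and \code{threshold.value} nested under
#' \code{threshold:}). Unknown keys raise an error so typos do not silently
#' fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_params()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("gaussian_radius_px", "ball_radius_px", "threshold",
             "min_area_px", "circularity_min", "circularity_max",
             "exclude_edges", "watershed", "blank_autofluorescence",
             "saturation_policy", "background_correction", "snr_dilation_px")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- cfg[setdiff(names(cfg), "threshold")]
  if (!is.null(cfg$threshold)) {
    if (!is.null(cfg$threshold$method))
      args$threshold_method <- cfg$threshold$method
    if (!is.null(cfg$threshold$value))
      args$threshold_value <- cfg$threshold$value
  }
  do.call(pipeline_params, args)
}

#' Write pipeline parameters to a YAML config file
#' @param params a [pipeline_params()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "pipeline_params"))
  cfg <- list(gaussian_radius_px = params$gaussian_radius_px,
              ball_radius_px = params$ball_radius_px,
              threshold = list(method = params$seg$threshold_method,
                               value = params$seg$threshold_value),
              min_area_px = params$seg$min_area_px,
              circularity_min = params$seg$circularity_min,
              circularity_max = params$seg$circularity_max,
              exclude_edges = params$seg$exclude_edges,
              watershed = params$seg$watershed,
              blank_autofluorescence = params$blank_autofluorescence,
              saturation_policy = params$saturation_policy,
              background_correction = params$background_correction,
              snr_dilation_px = params$snr_dilation_px)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Stable hash of a parameter set, for the run log.
config_hash <- function(params) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(params, tmp)
  unname(tools::md5sum(tmp))
}

#' Quantify one bead image end to end
#'
#' Runs the full detection stage on a fluorescence image: Gaussian
#' smoothing, rolling-ball background subtraction, segmentation with
#' watershed and particle filtering, and per-bead intensity measurement with
#' blank-bead correction and exposure normalization.
#'
#' @param img a [gray_image()].
#' @param params a [pipeline_params()].
#' @return A list: \code{measurements} (per-bead data frame),
#'   \code{particles}, \code{labels} (filtered [label_map()]),
#'   \code{rejected}, \code{stage_counts}, \code{threshold},
#'   \code{corrected} (the background-subtracted [gray_image()]).
#' @export
quantify_image <- function(img, params = pipeline_params()) {
  stopifnot(inherits(img, "gray_image"), inherits(params, "pipeline_params"))
  sm <- gaussian_smooth(img, params$gaussian_radius_px)
  bg <- subtract_background(sm, params$ball_radius_px)
  seg <- segment_beads(bg$corrected, params$seg)
  meas <- if (nrow(seg$particles)) {
    local_bg <- if (identical(params$background_correction, "residual"))
      residual_background(bg$corrected, seg$labels, params$snr_dilation_px)
    else 0
    measure_beads(bg$corrected, seg$labels,
                  blank_autofluorescence = params$blank_autofluorescence,
                  saturation_policy = params$saturation_policy,
                  raw_img = img, local_background = local_bg)
  } else {
    data.frame(bead_id = integer(), area_px = integer(),
               mean_intensity_raw = numeric(),
               mean_intensity_corrected = numeric(),
               intensity_per_ms = numeric(),
               floored = logical(), saturated = logical())
  }
  list(measurements = meas, particles = seg$particles, labels = seg$labels,
       rejected = seg$rejected, stage_counts = seg$stage_counts,
       threshold = seg$threshold, corrected = bg$corrected)
}

#' Run the quantification stage over a manifest of images
#'
#' The batch entry point behind the command line. The manifest binds each
#' fluorescence image to its exposure time and condition label (and
#' optionally a manual blank-bead autofluorescence value). Outputs per image:
#' a per-bead CSV, the filtered label map as 16-bit TIFF, an RGB overlay,
#' and a run log recording the config hash, seed, parameter values and the
#' per-stage particle counts (masked, size-, circularity- and edge-filtered
#' -- monotonically non-increasing).
#'
#' @param manifest data frame (or path to a JSON/YAML manifest with an
#'   \code{images} list) with columns \code{path}, \code{exposure_ms},
#'   \code{condition}; optional \code{blank_autofluorescence}.
#' @param params a [pipeline_params()].
#' @param out_dir output directory (created if needed).
#' @param overlay write overlay images.
#' @param seed seed recorded in the log (the quantification stage itself is
#'   deterministic).
#' @return Invisibly, a list with \code{measurements} (combined per-bead
#'   table), \code{per_image} results, and \code{log} (character lines).
#' @export
run_quantify <- function(manifest, params = pipeline_params(),
                         out_dir = ".", overlay = TRUE, seed = 1L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(is.data.frame(manifest),
            all(c("path", "exposure_ms", "condition") %in% names(manifest)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("config_hash: %s", config_hash(params)),
           sprintf("seed: %d", seed),
           sprintf("gaussian_radius_px: %g ball_radius_px: %g",
                   params$gaussian_radius_px, params$ball_radius_px),
           sprintf("min_area_px: %g circularity: [%g, %g] exclude_edges: %s watershed: %s",
                   params$seg$min_area_px, params$seg$circularity_min,
                   params$seg$circularity_max, params$seg$exclude_edges,
                   params$seg$watershed))
  per_image <- list()
  all_meas <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- read_image(row$path, exposure_ms = row$exposure_ms)
    p <- params
    if (!is.null(manifest$blank_autofluorescence) &&
        !is.na(row$blank_autofluorescence))
      p$blank_autofluorescence <- row$blank_autofluorescence
    res <- quantify_image(img, p)
    if (nrow(res$measurements) == 0L)
      stop("no particles retained in image ", row$path, call. = FALSE)
    sc <- res$stage_counts
    log <- c(log, sprintf(
      "image %s condition %s counts masked=%d size_filtered=%d circularity_filtered=%d edge_filtered=%d",
      basename(row$path), row$condition, sc[1], sc[2], sc[3], sc[4]))
    for (j in seq_len(nrow(res$rejected)))
      log <- c(log, sprintf("  rejected label=%d reason=%s",
                            res$rejected$label[j], res$rejected$reason[j]))
    stem <- file.path(out_dir,
                      paste0(row$condition, "_",
                             tools::file_path_sans_ext(basename(row$path))))
    meas <- cbind(condition = row$condition, res$measurements)
    names(meas)[names(meas) == "bead_id"] <- "bead_id"
    tab <- data.frame(condition = meas$condition, bead_id = meas$bead_id,
                      area_px = meas$area_px,
                      circularity = res$particles$circularity[
                        match(meas$bead_id, res$particles$label)],
                      mean_intensity_raw = meas$mean_intensity_raw,
                      mean_intensity_corrected = meas$mean_intensity_corrected,
                      intensity_per_ms = meas$intensity_per_ms)
    write_measurements(tab, paste0(stem, "_beads.csv"))
    write_label_map(res$labels, paste0(stem, "_labels.tif"))
    if (overlay) write_overlay(img, res$labels, paste0(stem, "_overlay.png"))
    per_image[[i]] <- res
    all_meas[[i]] <- tab
  }
  combined <- do.call(rbind, all_meas)
  write_measurements(combined, file.path(out_dir, "all_beads.csv"))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(list(measurements = combined, per_image = per_image, log = log))
}

read_manifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  imgs <- m$images %||% m
  if (is.data.frame(imgs)) return(imgs)
  do.call(rbind, lapply(imgs, function(e) as.data.frame(e)))
}

#' Compute affinities and comparisons from per-bead tables
#'
#' Takes the combined per-bead measurement table and per-condition metadata
#' (bait input, prey input) and produces the affinity summary (absolute and
#' relative, max scaled to 100) plus all pairwise Welch comparisons with
#' fold changes.
#'
#' @param measurements per-bead data frame in the [write_measurements()]
#'   schema (or a CSV path).
#' @param meta data frame with columns \code{condition}, \code{bait_input},
#'   \code{prey_input_per_ms} (either may be 1 when shared across the set).
#' @return A list: \code{affinities} (per-condition data frame),
#'   \code{comparisons} (pairwise data frame, \code{NULL} for a single
#'   condition), \code{results} (the [ibrp_affinity()] objects).
#' @export
run_affinity <- function(measurements, meta) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  stopifnot(all(c("condition", "intensity_per_ms") %in% names(measurements)),
            all(c("condition", "bait_input", "prey_input_per_ms") %in%
                  names(meta)))
  conds <- unique(measurements$condition)
  missing <- setdiff(conds, meta$condition)
  if (length(missing))
    stop("missing metadata for conditions: ",
         paste(missing, collapse = ", "), call. = FALSE)
  results <- lapply(conds, function(cd) {
    mrow <- meta[meta$condition == cd, ][1, ]
    ibrp_affinity(assay_condition(
      condition_id = cd,
      measurements = measurements[measurements$condition == cd, ],
      bait_input = mrow$bait_input,
      prey_input_per_ms = mrow$prey_input_per_ms))
  })
  results <- relative_affinities(results)
  affinities <- do.call(rbind, lapply(results, summarize_condition))
  comparisons <- if (length(results) >= 2L) compare_conditions(results)
  else NULL
  list(affinities = affinities, comparisons = comparisons, results = results)
}
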