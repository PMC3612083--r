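#' Measure per-bead fluorescence
#'
#' For each validated particle, the mean intensity over its member pixels is
#' taken on the background-subtracted fluorescence image, the
#' autofluorescence of blank (bait-free) beads is subtracted as a scalar,
#' and the result is normalized by exposure time. Negative corrected means
#' are floored at 0 and flagged, so weak signals never produce negative
#' affinities while the flooring remains auditable. Beads containing
#' saturated pixels (value \code{2^bit_depth - 1}) break the linearity the
#' assay relies on and are excluded by default.
#'
#' @param corrected_img the background-subtracted [gray_image()] ("image B"
#'   of the mask-generation recipe).
#' @param labels the filtered [label_map()] from [segment_beads()].
#' @param blank_autofluorescence mean autofluorescence of blank beads, in
#'   the same camera units (scalar >= 0). Default 0 (no correction).
#' @param local_background residual background level of the
#'   background-subtracted image (camera units), subtracted from every bead
#'   mean. Rolling-ball subtraction removes the smooth illumination field
#'   but, being a lower envelope, leaves the noise floor sitting a little
#'   above zero; the pipeline estimates this residual from the pixels
#'   outside all bead masks and removes it here, completing the
#'   "corrected by background" step. Default 0.
#' @param saturation_policy \code{"exclude"} (drop saturated beads),
#'   \code{"flag"} (keep, mark) or \code{"ignore"}.
#' @param raw_img optional original [gray_image()] used only to detect
#'   saturation; defaults to \code{corrected_img}.
#' @return Data frame with one row per bead: \code{bead_id},
#'   \code{area_px}, \code{mean_intensity_raw} (mean over member pixels of
#'   the corrected image), \code{mean_intensity_corrected} (after blank-bead
#'   subtraction), \code{intensity_per_ms}
#'   (\code{mean_intensity_corrected / exposure_ms}), \code{floored},
#'   \code{saturated}.
#' @export
measure_beads <- function(corrected_img, labels, blank_autofluorescence = 0,
                          saturation_policy = c("exclude", "flag", "ignore"),
                          raw_img = NULL, local_background = 0) {
  stopifnot(inherits(corrected_img, "gray_image"))
  saturation_policy <- match.arg(saturation_policy)
  if (is.null(corrected_img$exposure_ms) || corrected_img$exposure_ms <= 0)
    stop("missing exposure metadata", call. = FALSE)
  if (blank_autofluorescence < 0)
    stop("`blank_autofluorescence` must be >= 0", call. = FALSE)
  if (!all(dim(labels) == dim(corrected_img$pixels)))
    stop("shape mismatch between image and label map", call. = FALSE)
  lab <- unclass(labels)
  lv <- setdiff(sort(unique(as.integer(lab))), 0L)
  sat_img <- raw_img %||% corrected_img
  satv <- 2^sat_img$bit_depth - 1
  rows <- lapply(lv, function(k) {
    sel <- lab == k
    n <- sum(sel)
    if (n == 0L) stop("particle with zero pixels: label ", k, call. = FALSE)
    raw <- mean(corrected_img$pixels[sel])
    corr <- raw - local_background - blank_autofluorescence
    floored <- corr < 0
    if (floored) corr <- 0
    data.frame(bead_id = k, area_px = n,
               mean_intensity_raw = raw,
               mean_intensity_corrected = corr,
               intensity_per_ms = corr / corrected_img$exposure_ms,
               floored = floored,
               saturated = any(sat_img$pixels[sel] >= satv))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bead_id = integer(), area_px = integer(),
                      mean_intensity_raw = numeric(),
                      mean_intensity_corrected = numeric(),
                      intensity_per_ms = numeric(),
                      floored = logical(), saturated = logical())
  if (saturation_policy == "exclude") out <- out[!out$saturated, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residual background of a background-subtracted image
#'
#' Mean of the corrected image over the pixels outside every particle mask
#' (after dilating the masks by \code{dilation_px}). The rolling-ball
#' background is a lower envelope, so after subtraction the empty field does
#' not average exactly zero; this residual is subtracted from bead means so
#' that bead intensity reflects signal above the local background, not above
#' the noise floor's envelope.
#'
#' @param corrected_img a background-subtracted [gray_image()].
#' @param labels a [label_map()] of bead masks.
#' @param dilation_px mask dilation before taking the complement.
#' @return Mean background level (camera units).
#' @export
residual_background <- function(corrected_img, labels, dilation_px = 3) {
  stopifnot(inherits(corrected_img, "gray_image"))
  lab <- unclass(labels)
  fg <- lab > 0L
  if (!any(!fg)) stop("no background pixels", call. = FALSE)
  brush <- EBImage::makeBrush(2L * dilation_px + 1L, shape = "disc")
  dil <- if (any(fg))
    EBImage::dilate(matrix(as.numeric(fg), nrow(fg)), brush) > 0 else fg
  mean(corrected_img$pixels[!dil])
}

#' Prey input from lysate fluorescence
#'
#' The prey input of a condition is the mean GFP fluorescence of the loaded
#' cell lysate, normalized by exposure time and corrected by the
#' autofluorescence of mock-transfected lysate imaged the same way:
#' \code{mean(lysate)/exposure_lysate - mean(mock)/exposure_mock}. A negative
#' difference is floored at 0 and flagged.
#'
#' @param lysate_img [gray_image()] of the prey-containing lysate well.
#' @param mock_img [gray_image()] of mock-transfected lysate, or \code{NULL}
#'   to skip the correction.
#' @return Single number (camera units per ms), with attribute
#'   \code{"floored"} set \code{TRUE} when the correction went negative.
#' @export
measure_lysate_input <- function(lysate_img, mock_img = NULL) {
  stopifnot(inherits(lysate_img, "gray_image"))
  per_ms <- mean(lysate_img$pixels) / lysate_img$exposure_ms
  mock_per_ms <- 0
  if (!is.null(mock_img)) {
    stopifnot(inherits(mock_img, "gray_image"))
    mock_per_ms <- mean(mock_img$pixels) / mock_img$exposure_ms
  }
  v <- per_ms - mock_per_ms
  floored <- v < 0
  if (floored) {
    warning("lysate input below mock autofluorescence; floored at 0",
            call. = FALSE)
    v <- 0
  }
  structure(v, floored = floored)
}

#' Assemble one assay condition
#'
#' One bait x prey pull-down: the bait input (protein density on beads,
#' semi-quantified externally, in ug/ul or uM -- treated as an opaque
#' positive scalar), the exposure-normalized mock-corrected prey input, and
#' the per-bead measurement table of the condition's bead image. When a
#' comparison set shares the same bait or the same prey, that input may be
#' set to 1, making the affinity relative to it.
#'
#' @param condition_id label for the condition.
#' @param measurements per-bead data frame from [measure_beads()].
#' @param bait_input bait density on beads (> 0 for affinity computation).
#' @param prey_input_per_ms prey input from [measure_lysate_input()] (> 0).
#' @param exposure_ms exposure of the bead image, carried for bookkeeping.
#' @param bait_units free unit tag (\code{"ug/ul"} or \code{"uM"}); compared
#'   across conditions with a warning only.
#' @return A list of class \code{assay_condition}.
#' @export
assay_condition <- function(condition_id, measurements,
                            bait_input = 1, prey_input_per_ms = 1,
                            exposure_ms = NA_real_, bait_units = "ug/ul") {
  if (!is.data.frame(measurements) || nrow(measurements) < 1L)
    stop("condition needs >= 1 bead measurement", call. = FALSE)
  structure(list(condition_id = condition_id,
                 measurements = measurements,
                 bait_input = bait_input,
                 prey_input_per_ms = as.numeric(prey_input_per_ms),
                 exposure_ms = exposure_ms,
                 bait_units = bait_units),
            class = "assay_condition")
}

#' Bead-retained-prey (IBRP) affinity of a condition
#'
#' The assay's interaction statistic: per-bead fluorescence normalized by
#' the three factors that vary between assays but not with binding strength
#' -- exposure time, prey input and bait input. Per bead i,
#' \deqn{a_i = \frac{I_i / t_{exp}}{P \cdot B}}
#' where \eqn{I_i} is the bead's corrected mean intensity, \eqn{t_{exp}} the
#' exposure (ms), \eqn{P} the prey input (lysate fluorescence per ms) and
#' \eqn{B} the bait input. Per-bead values are averaged (rather than
#' averaging intensities first) so the per-bead spread feeds the SD and the
#' t-test; with shared normalizers both orders give the same mean.
#'
#' @param condition an [assay_condition()].
#' @return A list of class \code{affinity_result}: \code{condition_id},
#'   \code{affinity_mean}, \code{affinity_sd} (n-1 denominator), \code{n},
#'   \code{per_bead} (the per-bead affinities), and
#'   \code{relative_affinity} (\code{NA} until set by
#'   [relative_affinities()]).
#' @export
ibrp_affinity <- function(condition) {
  stopifnot(inherits(condition, "assay_condition"))
  if (!is.numeric(condition$bait_input) || condition$bait_input <= 0)
    stop("bait_input must be > 0", call. = FALSE)
  if (!is.numeric(condition$prey_input_per_ms) ||
      condition$prey_input_per_ms <= 0)
    stop("prey_input_per_ms must be > 0", call. = FALSE)
  a <- condition$measurements$intensity_per_ms /
    (condition$prey_input_per_ms * condition$bait_input)
  structure(list(condition_id = condition$condition_id,
                 affinity_mean = mean(a),
                 affinity_sd = if (length(a) > 1L) sd(a) else 0,
                 n = length(a),
                 per_bead = a,
                 relative_affinity = NA_real_,
                 relative_sd = NA_real_),
            class = "affinity_result")
}

#' @export
print.affinity_result <- function(x, ...) {
  cat(sprintf("<affinity_result> %s: %.4g +/- %.4g (n = %d)",
              x$condition_id, x$affinity_mean, x$affinity_sd, x$n))
  if (!is.na(x$relative_affinity))
    cat(sprintf(", relative %.1f", x$relative_affinity))
  cat("\n")
  invisible(x)
}

#' Scale a comparison set of affinities so the maximum is 100
#'
#' Relative affinities are used for plotting and cross-condition comparison:
#' each mean is multiplied by \code{100 / max(means)}, and SDs are scaled by
#' the same factor, so within one comparison set the largest relative
#' affinity is exactly 100.
#'
#' @param results list of [ibrp_affinity()] results.
#' @return The same list with \code{relative_affinity} and
#'   \code{relative_sd} filled in.
#' @export
relative_affinities <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "affinity_result")))
  means <- vapply(results, `[[`, numeric(1), "affinity_mean")
  m <- max(means)
  if (m <= 0) stop("all affinity means are zero", call. = FALSE)
  lapply(results, function(r) {
    # ratio-first form so the maximum lands at exactly 100
    r$relative_affinity <- 100 * (r$affinity_mean / m)
    r$relative_sd <- 100 * (r$affinity_sd / m)
    r
  })
}

#' Signal-to-noise ratio of a bead field
#'
#' The ratio of the mean intensity over all bead pixels to the standard
#' deviation of the background. Background pixels are those outside every
#' particle mask after dilating the masks by \code{dilation_px} (default 3),
#' which keeps the dim halo immediately around beads out of the noise
#' estimate.
#'
#' @param corrected_img a [gray_image()].
#' @param labels a [label_map()] of bead masks (>= 1 particle).
#' @param dilation_px mask dilation before taking the complement.
#' @return The ratio (single number).
#' @export
snr <- function(corrected_img, labels, dilation_px = 3) {
  stopifnot(inherits(corrected_img, "gray_image"))
  lab <- unclass(labels)
  if (!any(lab > 0L)) stop("no particles in label map", call. = FALSE)
  fg <- lab > 0L
  brush <- EBImage::makeBrush(2L * dilation_px + 1L, shape = "disc")
  dil <- EBImage::dilate(matrix(as.numeric(fg), nrow(fg)), brush) > 0
  bgpix <- corrected_img$pixels[!dil]
  if (length(bgpix) < 100L)
    stop("fewer than 100 background pixels", call. = FALSE)
  s <- sd(bgpix)
  if (s == 0) stop("zero background variance", call. = FALSE)
  mean(corrected_img$pixels[fg]) / s
}
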