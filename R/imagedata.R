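#' Grayscale intensity image with acquisition metadata
#'
#' The pipeline's raster container: a 2-D matrix of intensity values in raw
#' camera units (never auto-rescaled to \[0, 1\] -- all normalization,
#' e.g. by exposure time, is explicit and happens downstream), plus the
#' acquisition metadata the quantification stage needs.
#'
#' Coordinates are row-major with origin at the top-left pixel, index
#' \code{[1, 1]} in R. Pixel values read from files satisfy
#' \code{0 <= value <= 2^bit_depth - 1}; synthetic floating-point renders may
#' carry small negative noise excursions until quantized.
#'
#' @param pixels numeric matrix of intensities (camera units).
#' @param exposure_ms exposure time in milliseconds; must be a single value
#'   \code{> 0}.
#' @param bit_depth camera bit depth, one of 8, 12 or 16. 12-bit data stored
#'   in 16-bit containers are accepted; only a max-value sanity check is
#'   performed (with a warning, not an error).
#' @param pixel_size_um physical size of one pixel at the sample plane, in
#'   micrometres, or \code{NULL} if unknown.
#' @param channel_tag free-text channel label, e.g. \code{"GFP"} or
#'   \code{"phase"}.
#'
#' @return An object of class \code{gray_image}: a list with elements
#'   \code{pixels}, \code{height}, \code{width}, \code{bit_depth},
#'   \code{exposure_ms}, \code{pixel_size_um}, \code{channel_tag}.
#' @export
gray_image <- function(pixels, exposure_ms, bit_depth = 16,
                       pixel_size_um = NULL, channel_tag = "GFP") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(exposure_ms) || length(exposure_ms) != 1 ||
      is.na(exposure_ms) || exposure_ms <= 0)
    stop("non-positive exposure: `exposure_ms` must be a single value > 0",
         call. = FALSE)
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("`bit_depth` must be 8, 12 or 16", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (any(pixels > maxv, na.rm = TRUE))
    warning("pixel values exceed 2^bit_depth - 1 = ", maxv,
            "; check bit_depth metadata", call. = FALSE)
  structure(
    list(pixels = pixels,
         height = nrow(pixels), width = ncol(pixels),
         bit_depth = as.integer(bit_depth),
         exposure_ms = as.numeric(exposure_ms),
         pixel_size_um = pixel_size_um,
         channel_tag = channel_tag),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %d-bit, %s ms exposure, channel %s\n",
              x$height, x$width, x$bit_depth,
              format(x$exposure_ms), x$channel_tag))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Integer label raster marking segmented particles
#'
#' A matrix of non-negative integers with the same shape as the image it was
#' derived from: 0 marks background, k >= 1 the pixels of particle k. Labels
#' are kept contiguous (\code{{0..K}}) by [compact_labels()].
#'
#' @param labels integer matrix of labels.
#' @return An object of class \code{label_map} (an integer matrix).
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative", call. = FALSE)
  structure(labels, class = c("label_map", "matrix", "array"))
}

#' Renumber labels to a contiguous 0..K set
#'
#' @param labels a [label_map()] or integer matrix.
#' @return A \code{label_map} whose positive labels are exactly
#'   \code{1..K}, in order of first (column-major) appearance sorted by old
#'   label value.
#' @export
compact_labels <- function(labels) {
  lv <- sort(unique(as.integer(labels)))
  lv <- lv[lv > 0L]
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(lv)) {
    remap <- integer(max(lv))
    remap[lv] <- seq_along(lv)
    pos <- labels > 0L
    out[pos] <- remap[as.integer(labels[pos])]
  }
  label_map(out)
}

#' Number of distinct particles in a label map
#' @param labels a [label_map()].
#' @return Integer count of positive labels.
#' @export
n_labels <- function(labels) length(setdiff(unique(as.integer(labels)), 0L))

#' Read a single-plane grayscale image
#'
#' Reads a grayscale TIFF (or PNG, accepted for test fixtures) and attaches
#' acquisition metadata. Integer pixel data are preserved in camera units --
#' they are never rescaled to \[0, 1\]. Exposure time is supplied by the
#' caller (from the acquisition log or a config file), never parsed from TIFF
#' tags, whose dialects are unreliable.
#'
#' @param path path to a single-plane grayscale TIFF or PNG file.
#' @param exposure_ms exposure time in milliseconds (> 0).
#' @param pixel_size_um optional pixel size in micrometres.
#' @param bit_depth camera bit depth; defaults to the container's bits per
#'   sample (8 or 16). Pass 12 for 12-bit cameras writing 16-bit files.
#' @param channel_tag channel label.
#' @return A [gray_image()].
#' @export
read_image <- function(path, exposure_ms, pixel_size_um = NULL,
                       bit_depth = NULL, channel_tag = "GFP") {
  if (!file.exists(path))
    stop("unreadable file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                   error = function(e) stop("unreadable file: ", path, " (",
                                            conditionMessage(e), ")",
                                            call. = FALSE))
    if (length(dim(px)) == 3L)
      stop("not single-channel grayscale: ", path, call. = FALSE)
    container_bits <- as.integer(attr(px, "bits.per.sample") %||%
                                   (if (max(px) > 255) 16L else 8L))
    attributes(px) <- list(dim = dim(px))
    storage.mode(px) <- "double"
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable file: ", path, " (",
                                             conditionMessage(e), ")",
                                             call. = FALSE))
    if (length(dim(raw)) == 3L)
      stop("not single-channel grayscale: ", path, call. = FALSE)
    # readPNG returns [0,1]; recover camera units from the container depth
    container_bits <- if (any(abs(raw * 255 - round(raw * 255)) > 1e-9))
      16L else 8L
    px <- round(raw * (2^container_bits - 1))
  } else {
    stop("unreadable file: unsupported extension '", ext, "'", call. = FALSE)
  }
  if (is.null(bit_depth)) bit_depth <- container_bits
  if (any(px < 0))
    stop("negative pixel values on read: ", path, call. = FALSE)
  gray_image(px, exposure_ms = exposure_ms, bit_depth = bit_depth,
             pixel_size_um = pixel_size_um, channel_tag = channel_tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a grayscale image to TIFF or PNG
#'
#' Lossless for integer camera units within the stated bit depth:
#' \code{read_image(write_image(x))} reproduces the raster exactly. PNG
#' containers hold 8 bits per sample; deeper data must go to TIFF.
#'
#' @param img a [gray_image()].
#' @param path output path; extension selects TIFF or PNG.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  container_bits <- if (img$bit_depth == 8L) 8L else 16L
  maxv <- 2^container_bits - 1
  px <- pmin(pmax(round(img$pixels), 0), maxv)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / maxv, path, bits.per.sample = container_bits)
  } else if (ext == "png") {
    if (container_bits != 8L)
      stop("PNG output supports 8-bit data only; write a TIFF instead",
           call. = FALSE)
    png::writePNG(px / maxv, path)
  } else stop("unsupported extension '", ext, "'", call. = FALSE)
  invisible(path)
}

#' Write a label map as a 16-bit grayscale TIFF
#'
#' @param labels a [label_map()].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(unclass(labels) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path TIFF path.
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  label_map(px)
}

# ---- overlay rendering -------------------------------------------------

# 3x5 bitmap digit glyphs for burning label numbers into overlays
.digit_font <- local({
  rows <- c(
    "111101101101111", # 0
    "010110010010111", # 1
    "111001111100111", # 2
    "111001111001111", # 3
    "101101111001001", # 4
    "111100111001111", # 5
    "111100111101111", # 6
    "111001001001001", # 7
    "111101111101111", # 8
    "111101111001111") # 9
  lapply(rows, function(r)
    matrix(as.integer(strsplit(r, "")[[1]]) == 1L, nrow = 5, byrow = TRUE))
})

.render_number <- function(canvas_set, n, row, col, nr, nc) {
  digits <- as.integer(strsplit(as.character(n), "")[[1]])
  c0 <- col
  for (d in digits) {
    g <- .digit_font[[d + 1L]]
    for (i in 1:5) for (j in 1:3) {
      if (g[i, j]) {
        ri <- row + i - 3L; ci <- c0 + j - 1L
        if (ri >= 1 && ri <= nr && ci >= 1 && ci <= nc)
          canvas_set <- rbind(canvas_set, c(ri, ci))
      }
    }
    c0 <- c0 + 4L
  }
  canvas_set
}

#' Write an RGB overlay of particle masks on a grayscale image
#'
#' Produces the visual QC image of the pipeline: the grayscale base linearly
#' rescaled to the display range, particle outlines drawn in a contrasting
#' color (magenta by default), and each particle's label number rendered at
#' its centroid.
#'
#' @param img a [gray_image()].
#' @param labels a [label_map()] of the same shape.
#' @param path output path (PNG or TIFF).
#' @param color outline/label color name or hex string.
#' @return \code{path}, invisibly.
#' @export
write_overlay <- function(img, labels, path, color = "magenta") {
  stopifnot(inherits(img, "gray_image"))
  if (!all(dim(labels) == dim(img$pixels)))
    stop("shape mismatch between image and label map", call. = FALSE)
  px <- img$pixels
  rng <- range(px)
  base <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  rgbv <- col2rgb(color)[, 1] / 255
  arr <- array(rep(base, 3L), dim = c(nrow(px), ncol(px), 3L))

  lv <- setdiff(sort(unique(as.integer(labels))), 0L)
  marked <- matrix(0L, 0L, 2L)
  if (length(lv)) {
    # outline = labelled pixels with a 4-neighbour of different label
    lab <- unclass(labels)
    nr <- nrow(lab); nc <- ncol(lab)
    pad <- matrix(-1L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
    ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
    nbdiff <- (pad[1:nr, 2:(nc + 1L)] != ctr) |
      (pad[3:(nr + 2L), 2:(nc + 1L)] != ctr) |
      (pad[2:(nr + 1L), 1:nc] != ctr) |
      (pad[2:(nr + 1L), 3:(nc + 2L)] != ctr)
    outline <- which(ctr > 0L & nbdiff, arr.ind = TRUE)
    marked <- outline
    for (k in lv) {
      pos <- which(lab == k, arr.ind = TRUE)
      marked <- .render_number(marked, k,
                               as.integer(round(mean(pos[, 1]))),
                               as.integer(round(mean(pos[, 2]))), nr, nc)
    }
  }
  if (nrow(marked)) {
    for (ch in 1:3)
      arr[cbind(marked, ch)] <- rgbv[ch]
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(arr, path)
  else tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write the per-bead measurement table as CSV
#'
#' Deterministic output: rows are ordered by condition then bead id, and the
#' same input always produces a byte-identical file.
#'
#' @param rows data frame with columns \code{condition}, \code{bead_id},
#'   \code{area_px}, \code{circularity}, \code{mean_intensity_raw},
#'   \code{mean_intensity_corrected}, \code{intensity_per_ms}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(rows, path) {
  cols <- c("condition", "bead_id", "area_px", "circularity",
            "mean_intensity_raw", "mean_intensity_corrected",
            "intensity_per_ms")
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("empty measurement table", call. = FALSE)
  missing <- setdiff(cols, names(rows))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  rows <- rows[order(rows$condition, rows$bead_id), cols]
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], function(x) signif(x, 9))
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#' @param path CSV path.
#' @return Data frame in the [write_measurements()] schema.
#' @export
read_measurements <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
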