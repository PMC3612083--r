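#' Segmentation parameters
#'
#' The particle-validation settings of the pipeline. Defaults are the
#' standard recipe for this assay: minimum area 200 px^2, circularity
#' 0.60-1.00, beads touching the field border excluded, watershed separation
#' of touching beads enabled.
#'
#' @param threshold_method \code{"otsu"} (automatic, between-class-variance
#'   criterion) or \code{"manual"}.
#' @param threshold_value manual threshold (camera units); foreground is
#'   \code{pixels > value}. Required when \code{threshold_method = "manual"}.
#' @param min_area_px minimum particle area in pixels.
#' @param circularity_min,circularity_max retained circularity range.
#' @param exclude_edges drop particles touching the image border.
#' @param watershed split touching beads along distance-transform ridges.
#' @return A list of class \code{seg_params}.
#' @export
seg_params <- function(threshold_method = c("otsu", "manual"),
                       threshold_value = NULL,
                       min_area_px = 200,
                       circularity_min = 0.60,
                       circularity_max = 1.00,
                       exclude_edges = TRUE,
                       watershed = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "manual" && is.null(threshold_value))
    stop("manual threshold requires `threshold_value`", call. = FALSE)
  stopifnot(min_area_px >= 1,
            circularity_min >= 0, circularity_max <= 1,
            circularity_min <= circularity_max)
  structure(list(threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_area_px = min_area_px,
                 circularity_min = circularity_min,
                 circularity_max = circularity_max,
                 exclude_edges = isTRUE(exclude_edges),
                 watershed = isTRUE(watershed)),
            class = "seg_params")
}

#' Threshold a fluorescence image into candidate bead foreground
#'
#' With \code{method = "otsu"} the threshold maximizing between-class
#' variance of the image histogram (at the image's bit depth) is chosen; with
#' \code{method = "manual"} the foreground is exactly the pixels strictly
#' above \code{value}.
#'
#' @param img a [gray_image()] (normally the background-subtracted image).
#' @param method \code{"otsu"} or \code{"manual"}.
#' @param value manual threshold in camera units.
#' @return A logical matrix, \code{TRUE} = candidate bead foreground. The
#'   threshold used is attached as attribute \code{"threshold"}.
#' @export
threshold_image <- function(img, method = c("otsu", "manual"), value = NULL) {
  stopifnot(inherits(img, "gray_image"))
  method <- match.arg(method)
  px <- img$pixels
  if (method == "manual") {
    if (is.null(value)) stop("manual threshold requires `value`", call. = FALSE)
    thr <- value
  } else {
    if (diff(range(px)) == 0)
      stop("no bimodal separation: image is uniform", call. = FALSE)
    maxv <- 2^img$bit_depth - 1
    levels <- min(2^img$bit_depth, 65536L)
    thr <- EBImage::otsu(px / maxv, range = c(0, 1), levels = levels) * maxv
  }
  structure(px > thr, dim = dim(px), threshold = thr)
}

#' Watershed separation of touching beads
#'
#' Splits connected foreground regions that contain two or more sufficiently
#' separated maxima of the Euclidean distance transform, along the watershed
#' ridge lines of that transform. Maxima shallower than 1 px of
#' distance-transform depth are suppressed (tolerance h = 1), so isolated
#' convex blobs pass through unsplit. Split lines are carved out as 1-px-wide
#' background so downstream per-bead masks do not share pixels.
#'
#' @param mask logical foreground matrix.
#' @return A [label_map()] with one label per (possibly split) bead.
#' @export
watershed_split <- function(mask) {
  mask <- mask & !is.na(mask)
  if (!any(mask)) return(label_map(matrix(0L, nrow(mask), ncol(mask))))
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- matrix(as.integer(ws), nrow(mask))
  # carve 1-px split lines: foreground pixels 8-adjacent to a different label
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  ctr <- lab
  cut <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2 + dr):(nr + 1L + dr), (2 + dc):(nc + 1L + dc)]
    cut <- cut | (ctr > 0L & nb > 0L & nb != ctr)
  }
  # keep the lower-label side so lines are 1 px, not 2
  nbmin <- matrix(Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2 + dr):(nr + 1L + dr), (2 + dc):(nc + 1L + dc)]
    nb[nb == 0L] <- Inf
    nbmin <- pmin(nbmin, nb)
  }
  lab[cut & ctr > nbmin] <- 0L
  compact_labels(label_map(lab))
}

#' Label connected foreground components (8-connectivity)
#'
#' @param mask logical matrix.
#' @return A [label_map()]; labels follow column-major order of first pixels.
#' @export
label_components <- function(mask) {
  m <- matrix(as.logical(mask), nrow(mask))
  m[is.na(m)] <- FALSE
  label_map(cpp_label8(m))
}

#' Circularity of a particle
#'
#' The standard shape descriptor \code{4 * pi * area / perimeter^2}, capped
#' at 1: a perfect circle scores 1, elongated or ragged shapes lower.
#'
#' @param area_px particle area in pixels (> 0).
#' @param perimeter_px particle perimeter in pixels (> 0).
#' @return Circularity in \[0, 1\].
#' @export
circularity_of <- function(area_px, perimeter_px) {
  if (any(area_px <= 0) || any(perimeter_px <= 0))
    stop("area and perimeter must be positive", call. = FALSE)
  pmin(1, 4 * pi * area_px / perimeter_px^2)
}

# Moore (8-neighbour) boundary tracing of one labelled object within `lab`.
# Returns counts of straight and diagonal chain steps of the outer boundary.
trace_boundary_steps <- function(lab, k) {
  pos <- which(lab == k, arr.ind = TRUE)
  r0 <- range(pos[, 1]); c0 <- range(pos[, 2])
  nr <- r0[2] - r0[1] + 3L; nc <- c0[2] - c0[1] + 3L
  m <- matrix(FALSE, nr, nc)
  m[cbind(pos[, 1] - r0[1] + 2L, pos[, 2] - c0[1] + 2L)] <- TRUE
  start <- which(m)[1]
  sr <- (start - 1L) %% nr + 1L; sc <- (start - 1L) %/% nr + 1L
  # clockwise neighbour ring starting East
  offs <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  diagstep <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  cur <- c(sr, sc)
  backtrack <- 5L   # entered scanning from the West
  n_straight <- 0L; n_diag <- 0L
  repeat {
    found <- FALSE
    for (step in 0:7) {
      i <- ((backtrack + step) %% 8L) + 1L
      nb <- cur + offs[i, ]
      if (m[nb[1], nb[2]]) {
        if (diagstep[i]) n_diag <- n_diag + 1L else n_straight <- n_straight + 1L
        backtrack <- ((i - 1L) + 4L) %% 8L + 1L
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) break                    # single-pixel object
    if (all(cur == c(sr, sc))) break
  }
  c(straight = n_straight, diag = n_diag)
}

# Traced perimeter with the ImageJ corner correction: straight chain steps
# weighted 0.948, diagonal steps 1.340 (= 0.948 * sqrt(2)). Single-pixel
# objects get perimeter 4 * 0.948.
traced_perimeter <- function(lab, k) {
  st <- trace_boundary_steps(lab, k)
  n <- sum(st)
  if (n == 0L) return(4 * 0.948)
  0.948 * st[["straight"]] + 1.340 * st[["diag"]]
}

#' Particle analysis: measure and filter candidate beads
#'
#' Computes per-particle shape descriptors (area, traced perimeter,
#' circularity, centroid, edge contact) and retains particles passing the
#' standard validation rules: area at least \code{min_area_px}, circularity
#' within \[\code{circularity_min}, \code{circularity_max}\], and, when
#' \code{exclude_edges} is set, no pixel on the image border. Rejections are
#' returned with the rule that removed them (checked in the order size,
#' circularity, edge), which makes the audit log of a run reconstructible.
#'
#' The perimeter is the traced-boundary estimate of the reference software
#' for this assay: Moore-chain steps weighted 0.948 (straight) and 1.340
#' (diagonal). Circularity cuts are only reproducible together with this
#' convention.
#'
#' @param labels a [label_map()].
#' @param params a [seg_params()].
#' @return A list with components \code{particles} (data frame: label, area,
#'   perimeter, circularity, centroid, edge flag -- retained particles only,
#'   relabelled 1..K), \code{labels} (the compacted filtered [label_map()]),
#'   and \code{rejected} (data frame with a \code{reason} column:
#'   \code{"size"}, \code{"circularity"} or \code{"edge"}).
#' @export
analyze_particles <- function(labels, params = seg_params()) {
  stopifnot(inherits(labels, "label_map"), inherits(params, "seg_params"))
  lab <- unclass(labels)
  lv <- setdiff(sort(unique(as.integer(lab))), 0L)
  empty <- data.frame(label = integer(), area_px = numeric(),
                      perimeter_px = numeric(), circularity = numeric(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      touches_edge = logical())
  if (!length(lv))
    return(list(particles = empty,
                labels = compact_labels(labels),
                rejected = cbind(empty, reason = character())))
  nr <- nrow(lab); nc <- ncol(lab)
  feats <- lapply(lv, function(k) {
    pos <- which(lab == k, arr.ind = TRUE)
    area <- nrow(pos)
    per <- traced_perimeter(lab, k)
    data.frame(label = k, area_px = area, perimeter_px = per,
               circularity = circularity_of(area, per),
               centroid_r = mean(pos[, 1]), centroid_c = mean(pos[, 2]),
               touches_edge = any(pos[, 1] == 1L | pos[, 1] == nr |
                                    pos[, 2] == 1L | pos[, 2] == nc))
  })
  feats <- do.call(rbind, feats)
  reason <- rep(NA_character_, nrow(feats))
  reason[is.na(reason) & feats$area_px < params$min_area_px] <- "size"
  reason[is.na(reason) &
           (feats$circularity < params$circularity_min |
              feats$circularity > params$circularity_max)] <- "circularity"
  if (params$exclude_edges)
    reason[is.na(reason) & feats$touches_edge] <- "edge"
  keep <- is.na(reason)
  kept <- feats[keep, , drop = FALSE]
  rej <- cbind(feats[!keep, , drop = FALSE],
               reason = reason[!keep])
  out_lab <- lab
  out_lab[!(lab %in% kept$label)] <- 0L
  out_lab <- compact_labels(label_map(out_lab))
  # relabel kept particles to match the compacted map (order preserved)
  if (nrow(kept)) kept$label <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  rownames(rej) <- NULL
  list(particles = kept, labels = out_lab, rejected = rej)
}

#' Segment a preprocessed image into validated bead masks
#'
#' Convenience wrapper running [threshold_image()], [watershed_split()] (or
#' plain 8-connected labeling when watershed is disabled) and
#' [analyze_particles()], and recording the per-stage particle counts the
#' pipeline logs (masked, size-filtered, circularity-filtered,
#' edge-filtered).
#'
#' @param img a preprocessed [gray_image()] (smoothed,
#'   background-subtracted).
#' @param params a [seg_params()].
#' @return As [analyze_particles()], plus \code{threshold} (value used) and
#'   \code{stage_counts} (named integer vector, non-increasing).
#' @export
segment_beads <- function(img, params = seg_params()) {
  mask <- threshold_image(img, params$threshold_method,
                          params$threshold_value)
  labels <- if (params$watershed) watershed_split(mask)
  else label_components(mask)
  res <- analyze_particles(labels, params)
  n0 <- n_labels(labels)
  n_size <- n0 - sum(res$rejected$reason == "size")
  n_circ <- n_size - sum(res$rejected$reason == "circularity")
  n_edge <- n_circ - sum(res$rejected$reason == "edge")
  res$threshold <- attr(mask, "threshold")
  res$stage_counts <- c(masked = n0, size_filtered = n_size,
                        circularity_filtered = n_circ,
                        edge_filtered = n_edge)
  res
}
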