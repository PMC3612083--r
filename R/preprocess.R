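#' Gaussian smoothing of a fluorescence image
#'
#' Denoising step applied before background subtraction and segmentation.
#' The \code{radius_px} parameter is interpreted as the Gaussian sigma in
#' pixels (the conventional "radius" of an ImageJ-style Gaussian blur), with
#' the kernel truncated at 4 sigma and renormalized, so total intensity of
#' interior-supported signals is conserved. \code{radius_px = 0} returns the
#' image unchanged.
#'
#' @param img a [gray_image()].
#' @param radius_px Gaussian sigma in pixels, >= 0. Default 1, the standard
#'   setting for this assay.
#' @return A [gray_image()] with the same shape and metadata.
#' @export
gaussian_smooth <- function(img, radius_px = 1) {
  stopifnot(inherits(img, "gray_image"))
  if (!is.numeric(radius_px) || length(radius_px) != 1 || radius_px < 0)
    stop("negative radius: `radius_px` must be >= 0", call. = FALSE)
  if (radius_px == 0) return(img)
  k1 <- gaussian_kernel_1d(radius_px)
  k2 <- outer(k1, k1)
  out <- img
  out$pixels <- EBImage::filter2(img$pixels, k2, boundary = "replicate")
  out$pixels <- matrix(as.numeric(out$pixels), nrow(img$pixels))
  out
}

#' Discrete 1-D Gaussian kernel
#'
#' Kernel of standard deviation \code{sigma}, truncated at 4 sigma and
#' normalized to sum 1. Exposed so tests can convolve with the exact kernel
#' the pipeline uses.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @return Numeric vector of odd length \code{2*ceiling(4*sigma) + 1}.
#' @export
gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Ball (spherical-cap) structuring element: heights z(dx,dy) =
# sqrt(r^2 - dx^2 - dy^2) over the disk support, NA outside. Any additive
# constant in z cancels in the opening, so heights are left unshifted.
ball_element <- function(radius) {
  r <- ceiling(radius)
  d <- (-r):r
  d2 <- outer(d^2, d^2, "+")
  z <- sqrt(pmax(radius^2 - d2, 0))
  z[d2 > radius^2] <- NA_real_
  z
}

# Exact grayscale opening by the ball element (erosion then dilation).
open_ball <- function(px, radius) {
  se <- ball_element(radius)
  cpp_ball_dilate(cpp_ball_erode(px, se), se)
}

# Block-minimum downscale by integer factor s (pads the last partial block
# by replicating edge values via the available pixels).
shrink_min <- function(px, s) {
  nr <- nrow(px); nc <- ncol(px)
  br <- ceiling(nr / s); bc <- ceiling(nc / s)
  out <- matrix(Inf, br, bc)
  ri <- rep(seq_len(br), each = s, length.out = nr)
  ci <- rep(seq_len(bc), each = s, length.out = nc)
  tmp <- matrix(Inf, br, nc)
  for (b in seq_len(br)) {
    rows <- which(ri == b)
    tmp[b, ] <- if (length(rows) > 1L) apply(px[rows, , drop = FALSE], 2, min)
    else px[rows, ]
  }
  for (b in seq_len(bc)) {
    cols <- which(ci == b)
    out[, b] <- if (length(cols) > 1L)
      apply(tmp[, cols, drop = FALSE], 1, min) else tmp[, cols]
  }
  out
}

# Robust least-squares plane through the (shrunk) intensity field. Bright
# structures (beads) are positive outliers, so after an initial fit the
# plane is refit on the lower half of the residuals; it then tracks the
# illumination slope, not the beads. Only the slope matters -- any vertical
# offset is absorbed by the opening of the residual.
robust_plane <- function(px, iters = 3L) {
  nr <- nrow(px); nc <- ncol(px)
  rr <- as.vector(row(px)); cc <- as.vector(col(px)); v <- as.vector(px)
  X <- cbind(1, rr, cc)
  keep <- rep(TRUE, length(v))
  coefs <- c(mean(v), 0, 0)
  for (i in seq_len(iters)) {
    coefs <- qr.solve(X[keep, , drop = FALSE], v[keep])
    resid <- v - X %*% coefs
    keep <- resid <= stats::quantile(resid, 0.5)
  }
  matrix(X %*% coefs, nr, nc)
}

# Bilinear upscale of a shrunk background to the full grid. Block b covers
# original rows (b-1)*s+1 .. b*s; its sample point is the block centre.
expand_bilinear <- function(small, s, nr, nc) {
  br <- nrow(small); bc <- ncol(small)
  # sample coordinates of block centres on the original grid
  rs <- (seq_len(br) - 1) * s + (s + 1) / 2
  cs <- (seq_len(bc) - 1) * s + (s + 1) / 2
  interp_axis <- function(x, grid) {
    # for each target coord, bracketing indices + weight
    i <- findInterval(x, grid, all.inside = TRUE)
    i <- pmin(pmax(i, 1L), length(grid) - 1L)
    w <- (x - grid[i]) / (grid[i + 1L] - grid[i])
    w <- pmin(pmax(w, 0), 1)
    list(i = i, w = w)
  }
  if (br == 1L && bc == 1L) return(matrix(small[1, 1], nr, nc))
  ax_r <- if (br > 1L) interp_axis(seq_len(nr), rs) else
    list(i = rep(1L, nr), w = rep(0, nr))
  ax_c <- if (bc > 1L) interp_axis(seq_len(nc), cs) else
    list(i = rep(1L, nc), w = rep(0, nc))
  i2 <- if (br > 1L) ax_r$i + 1L else ax_r$i
  j2 <- if (bc > 1L) ax_c$i + 1L else ax_c$i
  a <- small[ax_r$i, ax_c$i, drop = FALSE]
  b <- small[i2, ax_c$i, drop = FALSE]
  cc <- small[ax_r$i, j2, drop = FALSE]
  d <- small[i2, j2, drop = FALSE]
  wr <- matrix(ax_r$w, nr, nc)
  wc <- matrix(ax_c$w, nr, nc, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) +
    cc * (1 - wr) * wc + d * wr * wc
}

#' Rolling-ball background subtraction
#'
#' Estimates the uneven background of a fluorescence field as the smooth
#' lower envelope traced by a ball of the given radius rolled beneath the
#' intensity surface -- implemented as grayscale opening with a ball
#' (spherical-cap) structuring element -- and subtracts it. Structures much
#' smaller than the ball (the beads) are preserved; slowly varying
#' illumination is absorbed into the background.
#'
#' For radii above 64 px, where exact opening is quadratic in the radius per
#' pixel, the image is reduced by block-minimum downscaling, the dominant
#' illumination slope is removed with a robust plane fit, the slope-free
#' residual is opened with the proportionally smaller ball, and the
#' background (plane + opened residual) is restored to full resolution by
#' bilinear interpolation; it is then capped at the observed image so the
#' lower-envelope contract holds exactly. The fast path is validated against
#' exact opening at small radii.
#'
#' @param img a [gray_image()].
#' @param ball_radius_px ball radius in pixels (>= 1). Default 400, the
#'   standard setting for this assay's full-resolution fields.
#' @return A list with components \code{corrected} (a [gray_image()],
#'   \code{img - background} clipped at 0, since negative fluorescence is
#'   non-physical) and \code{background} (a [gray_image()]).
#' @export
subtract_background <- function(img, ball_radius_px = 400) {
  stopifnot(inherits(img, "gray_image"))
  if (!is.numeric(ball_radius_px) || length(ball_radius_px) != 1 ||
      ball_radius_px < 1)
    stop("non-positive radius: `ball_radius_px` must be >= 1", call. = FALSE)
  px <- img$pixels
  if (ball_radius_px <= 64) {
    bg <- open_ball(px, ball_radius_px)
  } else {
    s <- ceiling(ball_radius_px / 32)
    r_eff <- ball_radius_px / s
    small <- shrink_min(px, s)
    # remove the dominant illumination slope before opening: with a steep
    # ramp the ball's contact point can fall outside the field and clipped
    # windows would bias the envelope; the slope-free residual has local
    # contacts, and the plane is added back afterwards
    plane <- robust_plane(small)
    small_bg <- open_ball(small - plane, r_eff) + plane
    bg <- expand_bilinear(small_bg, s, nrow(px), ncol(px))
  }
  bg <- pmin(bg, px)   # enforce lower envelope after interpolation
  corrected <- img
  corrected$pixels <- pmax(px - bg, 0)
  background <- img
  background$pixels <- bg
  list(corrected = corrected, background = background)
}
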