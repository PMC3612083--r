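# Geometric fixtures and independent oracles used across the suite.
# Oracles are deliberately naive (direct formulas, brute-force loops) and
# share no code with the package internals they check.

# ---- raster fixtures ---------------------------------------------------

disk_mask <- function(radius, n = 2 * radius + 11, centre = c((n + 1) / 2, (n + 1) / 2)) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  m <- matrix(FALSE, n, n)
  sel <- (g$r - centre[1])^2 + (g$c - centre[2])^2 <= radius^2
  m[as.matrix(g)[sel, , drop = FALSE]] <- TRUE
  m
}

# paint a disk into an existing matrix
paint_disk <- function(px, centre, radius, value) {
  g <- expand.grid(r = seq_len(nrow(px)), c = seq_len(ncol(px)))
  sel <- (g$r - centre[1])^2 + (g$c - centre[2])^2 <= radius^2
  px[as.matrix(g)[sel, , drop = FALSE]] <- value
  px
}

paint_ellipse <- function(px, centre, a, b, value) {
  g <- expand.grid(r = seq_len(nrow(px)), c = seq_len(ncol(px)))
  sel <- ((g$r - centre[1]) / b)^2 + ((g$c - centre[2]) / a)^2 <= 1
  px[as.matrix(g)[sel, , drop = FALSE]] <- value
  px
}

gimg <- function(px, exposure_ms = 100, bit_depth = 16)
  gray_image(px, exposure_ms = exposure_ms, bit_depth = bit_depth)

# The five-object validation field: two clean disks (pass), a sub-200-px
# disk (size), an elongated 4:1 ellipse of area ~2000 (circularity; a 3:1
# ellipse has true circularity ~0.66 and passes the 0.60 cut under any
# perimeter convention faithful to circles, so the elongated rejection
# object is built at 4:1), and a disk cut by the image border (edge).
five_object_field <- function(value = 1000, n = 360) {
  px <- matrix(0, n, n)
  px <- paint_disk(px, c(80, 80), 30, value)            # clean disk
  px <- paint_disk(px, c(80, 240), 5, value)            # area 79 < 200
  b <- sqrt(2000 / (4 * pi))                            # 4:1 ellipse
  px <- paint_ellipse(px, c(200, 160), 4 * b, b, value)
  px <- paint_disk(px, c(n - 10, 180), 30, value)       # cut by border
  px <- paint_disk(px, c(290, 60), 30, value)           # second clean disk
  px
}

# ---- independent oracles ----------------------------------------------

# Brute-force grayscale opening by a ball structuring element: plain
# double loops over the support, padding with +Inf / -Inf at borders.
oracle_ball_opening <- function(px, radius) {
  r <- ceiling(radius)
  d <- (-r):r
  supp <- which(outer(d^2, d^2, "+") <= radius^2, arr.ind = TRUE)
  hz <- sqrt(radius^2 - (supp[, 1] - r - 1)^2 - (supp[, 2] - r - 1)^2)
  nr <- nrow(px); nc <- ncol(px)
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(supp))) {
    di <- supp[k, 1] - r - 1L; dj <- supp[k, 2] - r - 1L
    sh <- matrix(Inf, nr, nc)
    ri <- seq_len(nr) + di; ci <- seq_len(nc) + dj
    okr <- ri >= 1 & ri <= nr; okc <- ci >= 1 & ci <= nc
    sh[okr, okc] <- px[ri[okr], ci[okc]]
    ero <- pmin(ero, sh - hz[k])
  }
  dil <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(supp))) {
    di <- supp[k, 1] - r - 1L; dj <- supp[k, 2] - r - 1L
    sh <- matrix(-Inf, nr, nc)
    ri <- seq_len(nr) - di; ci <- seq_len(nc) - dj
    okr <- ri >= 1 & ri <= nr; okc <- ci >= 1 & ci <= nc
    sh[okr, okc] <- ero[ri[okr], ci[okc]]
    dil <- pmax(dil, sh + hz[k])
  }
  dil
}

# Exhaustive Otsu: search every candidate threshold, maximizing
# between-class variance of the two groups.
oracle_otsu <- function(values, levels) {
  best_t <- NA; best_v <- -Inf
  for (t in levels) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# Direct Welch formulas with the t CDF obtained by numerical integration
# of the t density (no calls to pt()).
oracle_welch <- function(a, b) {
  m1 <- sum(a) / length(a); m2 <- sum(b) / length(b)
  v1 <- sum((a - m1)^2) / (length(a) - 1)
  v2 <- sum((b - m2)^2) / (length(b) - 1)
  se2 <- v1 / length(a) + v2 / length(b)
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / length(a))^2 / (length(a) - 1) +
                   (v2 / length(b))^2 / (length(b) - 1))
  dens <- function(x) exp(lgamma((df + 1) / 2) - lgamma(df / 2)) /
    sqrt(df * pi) * (1 + x^2 / df)^(-(df + 1) / 2)
  Tv <- abs(tstat)
  tail <- if (Tv <= 1) {
    integrate(dens, Tv, Inf, rel.tol = 1e-13)$value
  } else {
    # substitute u = 1/x so the far tail becomes a finite, well-behaved
    # integral: int_T^Inf f(x) dx = int_0^{1/T} f(1/u)/u^2 du
    integrate(function(u) dens(1 / u) / u^2, 0, 1 / Tv,
              rel.tol = 1e-13)$value
  }
  list(t = tstat, df = df, p = 2 * tail)
}

# OLS by the closed-form normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Greedy matching of truth beads to detected particles within a radius.
match_beads <- function(truth, particles, max_err = 2) {
  if (nrow(particles) == 0L)
    return(list(recovered = 0, false_pos = 0, errors = numeric()))
  d <- sqrt(outer(truth$center_r, particles$centroid_r, "-")^2 +
              outer(truth$center_c, particles$centroid_c, "-")^2)
  best_t <- apply(d, 1, min)
  best_p <- apply(d, 2, min)
  list(recovered = sum(best_t <= max_err),
       false_pos = sum(best_p > max_err),
       errors = best_t[best_t <= max_err])
}
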