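# Camouflage quantification: CIELAB mean/SD differences between the target
# and its local background, and the GabRat Gabor edge-disruption metric.

#' Local background sampling region
#'
#' The pixels inside a circle of diameter `factor` times the target's
#' maximum diameter, centred on the target centroid, with all target pixels
#' excluded, clipped to the slide bounds (clipping is flagged).
#'
#' @param slide_dim integer `c(height, width)` of the slide.
#' @param target_mask logical matrix over the slide (`TRUE` = target pixel).
#' @param factor diameter multiple (default 2).
#' @return list: `pixels` (n x 2 row/col index matrix), `n`, `clipped`,
#'   `diameter` (the circle diameter in px).
#' @export
local_region <- function(slide_dim, target_mask, factor = 2) {
  pts <- which(target_mask, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("target mask is empty", call. = FALSE)
  md <- mask_max_diameter(target_mask)
  radius <- factor * md / 2
  cy <- mean(pts[, 1]); cx <- mean(pts[, 2])
  y0 <- max(1L, floor(cy - radius)); y1 <- min(slide_dim[1], ceiling(cy + radius))
  x0 <- max(1L, floor(cx - radius)); x1 <- min(slide_dim[2], ceiling(cx + radius))
  clipped <- (cy - radius < 1) || (cy + radius > slide_dim[1]) ||
    (cx - radius < 1) || (cx + radius > slide_dim[2])
  yy <- y0:y1; xx <- x0:x1
  inside <- outer(yy, xx, function(a, b) (a - cy)^2 + (b - cx)^2 <= radius^2)
  tm <- target_mask[yy, xx, drop = FALSE]
  keep <- inside & !tm
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("local background region is empty (target fills the circle)",
         call. = FALSE)
  pixels <- cbind(idx[, 1] + y0 - 1L, idx[, 2] + x0 - 1L)
  list(pixels = pixels, n = nrow(pixels), clipped = clipped,
       diameter = 2 * radius)
}

#' Channel statistics over a pixel set
#'
#' Means and population (divide-by-n) standard deviations of the L, A and B
#' planes over the given pixels.
#'
#' @param pixels n x 2 matrix of row/col indices.
#' @param lab H x W x 3 CIELAB array.
#' @return named vector `muL, muA, muB, sdL, sdA, sdB`.
#' @export
lab_stats <- function(pixels, lab) {
  if (is.null(dim(pixels)) || nrow(pixels) == 0)
    stop("pixel set must be non-empty", call. = FALSE)
  out <- numeric(6)
  for (ch in 1:3) {
    v <- lab[, , ch][pixels]
    out[ch] <- mean(v)
    out[ch + 3] <- sqrt(mean((v - out[ch])^2))
  }
  names(out) <- c("muL", "muA", "muB", "sdL", "sdA", "sdB")
  out
}

#' Target-vs-background CIELAB differences
#'
#' @param target_stats,local_stats outputs of [lab_stats()].
#' @param signed logical; emit signed (target minus background) differences
#'   instead of the default absolute magnitudes.
#' @return named vector `dmuL, dmuA, dmuB, dsdL, dsdA, dsdB`.
#' @export
camo_diffs <- function(target_stats, local_stats, signed = FALSE) {
  d <- target_stats - local_stats
  if (!signed) d <- abs(d)
  names(d) <- c("dmuL", "dmuA", "dmuB", "dsdL", "dsdA", "dsdB")
  d
}

# zero-DC Gabor quadrature pair; theta is the EDGE orientation the filter
# responds to (carrier runs perpendicular to it). The envelope is elongated
# along the edge axis (aspect 2:1) for orientation selectivity, so a clean
# straight edge drives essentially only its parallel filter.
gabor_pair <- function(sigma, theta, wavelength = 2 * sigma, aspect = 2) {
  r <- as.integer(ceiling(3 * sigma * max(1, aspect)))
  x <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1)
  y <- t(x)
  # carrier axis perpendicular to the edge orientation
  ca <- theta + pi / 2
  xr <- x * cos(ca) + y * sin(ca)
  yr <- -x * sin(ca) + y * cos(ca)
  env <- exp(-(xr^2 / (2 * sigma^2) + yr^2 / (2 * (aspect * sigma)^2)))
  even <- env * cos(2 * pi * xr / wavelength)
  odd <- env * sin(2 * pi * xr / wavelength)
  even <- even - env * sum(even) / sum(env)  # zero DC response
  list(even = even, odd = odd)
}

# local outline tangent angles (radians, mod pi) from the gradient of the
# smoothed mask: tangent = normal + 90 degrees
outline_tangents <- function(mask, pts, smooth_sigma = 1.5) {
  m <- gaussian_blur(matrix(as.numeric(mask), nrow(mask)), smooth_sigma)
  nr <- nrow(m); nc <- ncol(m)
  up <- pmax(pts[, 1] - 1L, 1L); dn <- pmin(pts[, 1] + 1L, nr)
  lf <- pmax(pts[, 2] - 1L, 1L); rt <- pmin(pts[, 2] + 1L, nc)
  gy <- m[cbind(dn, pts[, 2])] - m[cbind(up, pts[, 2])]
  gx <- m[cbind(pts[, 1], rt)] - m[cbind(pts[, 1], lf)]
  (atan2(gy, gx) + pi / 2) %% pi
}

#' GabRat edge disruption
#'
#' For each pixel of the target outline a bank of `n_orientations` evenly
#' spaced Gabor quadrature filters is evaluated on the channel plane. The
#' bank energies are interpolated (periodically over orientation) at the
#' local outline tangent -- the "true edge" response -- and at its
#' perpendicular -- the "false edge" response.
#' GabRat is the mean over outline pixels of `false / (false + true)`, in
#' `[0, 1]`; higher values mean a more disrupted (harder to segment)
#' outline. Pixels with no edge signal either way contribute the neutral
#' value 0.5 and are flagged via the `"neutral"` attribute.
#'
#' The `"fft"` method evaluates the filter bank over the whole plane by
#' circular FFT correlation; `"naive"` is the independent per-pixel
#' convolution oracle (identical boundary semantics, evaluated only at
#' outline pixels).
#'
#' @param plane numeric matrix (one CIELAB channel; A/B planes are z-scored
#'   internally so channel scale cannot dominate).
#' @param mask logical target mask defining the outline.
#' @param sigma Gabor envelope sigma in px (default 3).
#' @param n_orientations number of bank orientations (default 4).
#' @param method `"fft"` (fast) or `"naive"` (oracle).
#' @param zscore logical; standardize the plane first (default `TRUE`).
#' @return scalar in `[0, 1]` with attribute `neutral` (count of 0/0 pixels).
#' @export
gabrat <- function(plane, mask, sigma = 3, n_orientations = 4L,
                   method = c("fft", "naive"), zscore = TRUE) {
  method <- match.arg(method)
  stopifnot(sigma > 0)
  pts <- which(boundary_pixels(mask), arr.ind = TRUE)
  if (nrow(pts) == 0)
    stop("mask has no outline (degenerate target)", call. = FALSE)
  if (zscore) {
    s <- stats::sd(plane)
    plane <- if (s > 1e-12) (plane - mean(plane)) / s else plane * 0
  }
  thetas <- (seq_len(n_orientations) - 1L) * pi / n_orientations
  energies <- matrix(0, nrow(pts), n_orientations)
  for (j in seq_len(n_orientations)) {
    gp <- gabor_pair(sigma, thetas[j])
    if (method == "fft") {
      ev <- fft_correlate(plane, gp$even)[pts]
      od <- fft_correlate(plane, gp$odd)[pts]
    } else {
      ev <- naive_correlate_at(plane, gp$even, pts)
      od <- naive_correlate_at(plane, gp$odd, pts)
    }
    energies[, j] <- sqrt(ev^2 + od^2)
  }
  tangents <- outline_tangents(mask, pts)
  # periodic (period pi) linear interpolation of the bank energies at an
  # arbitrary orientation: the aligned "true" and perpendicular "false"
  # edge responses of the original metric
  interp_energy <- function(p, angle) {
    a <- (angle %% pi) / (pi / n_orientations)
    lo <- floor(a)
    f <- a - lo
    j0 <- (as.integer(lo) %% n_orientations) + 1L
    j1 <- (j0 %% n_orientations) + 1L
    (1 - f) * energies[p, j0] + f * energies[p, j1]
  }
  ratios <- numeric(nrow(pts))
  neutral <- 0L
  for (p in seq_len(nrow(pts))) {
    true_e <- interp_energy(p, tangents[p])
    false_e <- interp_energy(p, tangents[p] + pi / 2)
    tot <- true_e + false_e
    if (tot < 1e-12) {
      ratios[p] <- 0.5
      neutral <- neutral + 1L
    } else ratios[p] <- false_e / tot
  }
  structure(mean(ratios), neutral = neutral)
}

#' Full camouflage metrics for a placed target
#'
#' CIELAB mean/SD differences against the local background plus (optionally)
#' per-channel GabRat, computed on a window around the target for speed.
#'
#' @param slide_lab H x W x 3 CIELAB array of the composed slide.
#' @param target_mask logical target mask over the slide.
#' @param factor local-region diameter factor (default 2).
#' @param gabrat_sigma Gabor sigma (default 3).
#' @param compute_gabrat logical; skip the Gabor bank when the observer does
#'   not use it.
#' @param signed logical; signed instead of absolute differences.
#' @return named numeric vector: `dmuL..dsdB`, `gabL`, `gabA`, `gabB`
#'   (NA when not computed), `region_n`, `region_clipped`.
#' @export
slide_metrics <- function(slide_lab, target_mask, factor = 2,
                          gabrat_sigma = 3, compute_gabrat = TRUE,
                          signed = FALSE) {
  dims <- dim(slide_lab)[1:2]
  region <- local_region(dims, target_mask, factor)
  t_pts <- which(target_mask, arr.ind = TRUE)
  ts <- lab_stats(t_pts, slide_lab)
  bs <- lab_stats(region$pixels, slide_lab)
  d <- camo_diffs(ts, bs, signed = signed)
  gab <- c(gabL = NA_real_, gabA = NA_real_, gabB = NA_real_)
  if (compute_gabrat) {
    # crop a window spanning the local region to keep the FFT small
    pad <- ceiling(region$diameter / 2) + 4 * gabrat_sigma
    cy <- mean(t_pts[, 1]); cx <- mean(t_pts[, 2])
    y0 <- max(1, floor(cy - pad)); y1 <- min(dims[1], ceiling(cy + pad))
    x0 <- max(1, floor(cx - pad)); x1 <- min(dims[2], ceiling(cx + pad))
    sub_mask <- target_mask[y0:y1, x0:x1, drop = FALSE]
    for (ch in 1:3) {
      nm <- c("gabL", "gabA", "gabB")[ch]
      gab[nm] <- as.numeric(gabrat(slide_lab[y0:y1, x0:x1, ch], sub_mask,
                                   sigma = gabrat_sigma))
    }
  }
  c(d, gab, region_n = region$n, region_clipped = as.numeric(region$clipped))
}
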