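# Low-level raster helpers shared by the pattern generators and metrics.
# Images are plain numeric matrices (rows = y, cols = x) or H x W x 3 arrays
# for CIELAB planes; masks are logical matrices.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)  # x first: keep dims
clamp01 <- function(x) clamp(x, 0, 1)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded sub-computations
#' (gamut builds, synthetic backgrounds, per-genome speckle noise) do not
#' perturb the single run-level RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a bounded child seed from a run seed and a string key (deterministic,
# stays below 2^31 so it is always a valid R integer seed)
derive_seed <- function(seed, key) {
  v <- utf8ToInt(as.character(key))
  h <- sum(v * seq_along(v)) %% 104729
  as.integer((as.numeric(seed) * 48271 + h * 16807 + 1) %% 2147483647)
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# replicate-pad a matrix by r rows/cols on each side
pad_replicate <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  m[ri, ci, drop = FALSE]
}

# separable convolution with replicate boundary
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  p <- pad_replicate(m, r)
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * tmp[, (i - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

#' Gaussian blur of a matrix
#' @param m numeric matrix.
#' @param sigma blur standard deviation in pixels; `sigma <= 0` is identity.
#' @return blurred matrix of the same dimensions.
#' @keywords internal
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep(m, gaussian_kernel1d(sigma))
}

# Bilinear sampling of matrix m at (row, col) coordinates (1-based, clamped).
# y and x may be vectors or matrices of equal shape.
bilinear_sample <- function(m, y, x) {
  nr <- nrow(m); nc <- ncol(m)
  y <- clamp(y, 1, nr); x <- clamp(x, 1, nc)
  y0 <- pmin(floor(y), nr - 1L); x0 <- pmin(floor(x), nc - 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  v <- (1 - fy) * (1 - fx) * m[i00] +
    (1 - fy) * fx * m[cbind(as.vector(y0), as.vector(x0) + 1L)] +
    fy * (1 - fx) * m[cbind(as.vector(y0) + 1L, as.vector(x0))] +
    fy * fx * m[cbind(as.vector(y0) + 1L, as.vector(x0) + 1L)]
  if (is.matrix(y)) matrix(v, nrow(y), ncol(y)) else v
}

# resize a matrix to out_h x out_w by bilinear interpolation of pixel centres
bilinear_resize <- function(m, out_h, out_w) {
  yy <- (seq_len(out_h) - 0.5) * nrow(m) / out_h + 0.5
  xx <- (seq_len(out_w) - 0.5) * ncol(m) / out_w + 0.5
  bilinear_sample(m, matrix(yy, out_h, out_w), matrix(xx, out_h, out_w, byrow = TRUE))
}

# 8-neighbour binary dilation
dilate_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  sh <- function(dy, dx) {
    m2 <- matrix(FALSE, nr, nc)
    ys <- seq_len(nr) + dy; xs <- seq_len(nc) + dx
    ok_y <- ys >= 1 & ys <= nr; ok_x <- xs >= 1 & xs <= nc
    m2[ok_y, ok_x] <- mask[ys[ok_y], xs[ok_x]]
    m2
  }
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out | sh(dy, dx)
  }
  out
}

# outline pixels: in-mask pixels with at least one 4-neighbour outside the mask
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !inner
}

# approximate (chessboard) distance from the maculation boundary, up to max_d,
# restricted to pixels where `side` is TRUE; Inf beyond max_d
band_distance <- function(boundary, side, max_d) {
  d <- matrix(Inf, nrow(boundary), ncol(boundary))
  frontier <- boundary
  reached <- frontier
  step <- 0L
  d[frontier & side] <- 0
  while (step < max_d && any(frontier)) {
    step <- step + 1L
    frontier <- dilate_mask(frontier) & !reached
    reached <- reached | frontier
    hit <- frontier & side & !is.finite(d)
    d[hit] <- step
  }
  d
}

# Rotate a raster (list of planes + logical mask) by `angle` degrees
# counter-clockwise, expanding the canvas to the rotated bounding box.
# Continuous planes are bilinearly resampled; the mask uses nearest neighbour.
rotate_raster <- function(planes, mask, angle) {
  th <- angle * pi / 180
  h <- nrow(mask); w <- ncol(mask)
  nw <- as.integer(ceiling(abs(w * cos(th)) + abs(h * sin(th))))
  nh <- as.integer(ceiling(abs(w * sin(th)) + abs(h * cos(th))))
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ncy <- (nh + 1) / 2; ncx <- (nw + 1) / 2
  yy <- matrix(seq_len(nh) - ncy, nh, nw)
  xx <- matrix(seq_len(nw) - ncx, nh, nw, byrow = TRUE)
  # inverse map: rotate output coords by -angle back into source frame
  # (image y axis points down, so CCW rotation flips the usual sign)
  sx <- cos(-th) * xx - sin(-th) * yy + cx
  sy <- sin(-th) * xx + cos(-th) * yy + cy
  inside <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  nm <- matrix(FALSE, nh, nw)
  ri <- cbind(as.vector(clamp(round(sy), 1, h)), as.vector(clamp(round(sx), 1, w)))
  nm[as.vector(inside)] <- mask[ri[as.vector(inside), , drop = FALSE]]
  out_planes <- lapply(planes, function(p) {
    v <- bilinear_sample(p, sy, sx)
    v[!inside] <- 0
    v
  })
  list(planes = out_planes, mask = nm)
}

# circular (wrap) cross-correlation of img with a centred kernel, via FFT:
# R(p) = sum_o K(o) * img(p + o), offsets o centred on the kernel middle
fft_correlate <- function(img, kern) {
  n1 <- nrow(img); n2 <- ncol(img)
  kd <- dim(kern)
  r1 <- (kd[1] - 1L) %/% 2L; r2 <- (kd[2] - 1L) %/% 2L
  K <- matrix(0, n1, n2)
  idx1 <- ((seq_len(kd[1]) - 1L - r1) %% n1) + 1L
  idx2 <- ((seq_len(kd[2]) - 1L - r2) %% n2) + 1L
  K[idx1, idx2] <- kern
  Re(stats::fft(stats::fft(img) * Conj(stats::fft(K)), inverse = TRUE)) / (n1 * n2)
}

# naive wrap cross-correlation evaluated only at the given points (n x 2 matrix
# of row/col indices); independent slow path used as the GabRat oracle route
naive_correlate_at <- function(img, kern, pts) {
  n1 <- nrow(img); n2 <- ncol(img)
  kd <- dim(kern)
  r1 <- (kd[1] - 1L) %/% 2L; r2 <- (kd[2] - 1L) %/% 2L
  out <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    acc <- 0
    for (i in seq_len(kd[1])) {
      yy <- ((pts[p, 1] - 1L + i - 1L - r1) %% n1) + 1L
      for (j in seq_len(kd[2])) {
        xx <- ((pts[p, 2] - 1L + j - 1L - r2) %% n2) + 1L
        acc <- acc + kern[i, j] * img[yy, xx]
      }
    }
    out[p] <- acc
  }
  out
}
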