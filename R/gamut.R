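# Reaction-diffusion pattern gamut: one Gray-Scott integration whose feed
# rate F varies along x and kill rate k along y, precomputed per run and
# sampled by window-addressing genes.

#' Build a Gray-Scott reaction-diffusion gamut
#'
#' Integrates the two-species Gray-Scott system on a grid where the feed
#' parameter F varies along x and the kill parameter k along y, from a
#' seeded noisy initial condition (u = 1 everywhere; a centred square of
#' u = 0.5, v = 0.25 with 5% multiplicative noise, plus a sparse 1% scatter
#' of v = 0.25 dots so pattern can nucleate across the whole sheet). The
#' returned `u` field is min-max normalized to `[0, 1]`; a flat field (no
#' pattern, e.g. zero initial perturbation) normalizes to all zeros and is
#' flagged.
#'
#' Defaults are the classic spots/stripes/labyrinth parameterization:
#' `Du = 0.16`, `Dv = 0.08`, `dt = 1`, F in `[0.01, 0.09]`, k in
#' `[0.045, 0.070]`, 256 x 256 grid, 5000 iterations. Results are cached
#' in memory per session, keyed by the full parameter set.
#'
#' @param F_range,k_range numeric length-2 parameter ranges.
#' @param resolution grid side length in pixels.
#' @param iterations number of Euler steps.
#' @param Du,Dv diffusion coefficients of the two species.
#' @param dt time step.
#' @param seed RNG seed for the initial perturbation.
#' @param perturb logical; `FALSE` suppresses the initial perturbation
#'   (yields the trivial flat field).
#' @param cache logical; reuse a cached build with identical parameters.
#' @return an object of class `rd_gamut`: list with the normalized `texture`
#'   matrix (rows = k axis, cols = F axis), parameter ranges, `resolution`,
#'   `seed` and a `flat` flag.
#' @export
build_rd_gamut <- function(F_range = c(0.01, 0.09), k_range = c(0.045, 0.070),
                           resolution = 256L, iterations = 5000L,
                           Du = 0.16, Dv = 0.08, dt = 1, seed = 1L,
                           perturb = TRUE, cache = TRUE) {
  key <- paste("gamut", paste(F_range, collapse = ","),
               paste(k_range, collapse = ","), resolution, iterations,
               Du, Dv, dt, seed, perturb, sep = "|")
  if (cache && !is.null(.camosim_cache[[key]]))
    return(.camosim_cache[[key]])

  n <- as.integer(resolution)
  F_col <- seq(F_range[1], F_range[2], length.out = n)
  k_row <- seq(k_range[1], k_range[2], length.out = n)
  u <- matrix(1, n, n)
  v <- matrix(0, n, n)
  if (perturb) {
    with_seed(seed, {
      side <- max(2L, n %/% 2L)
      lo <- (n - side) %/% 2L + 1L
      sq <- lo:(lo + side - 1L)
      noise <- matrix(runif(side * side, 0.95, 1.05), side, side)
      u[sq, sq] <- 0.5 * noise
      v[sq, sq] <- 0.25 * noise
      dots <- matrix(runif(n * n) < 0.01, n, n)
      v[dots] <- 0.25
    })
  }
  texture <- gray_scott_cpp(u, v, F_col, k_row, Du, Dv, dt,
                            as.integer(iterations))
  if (any(!is.finite(texture))) {
    bad <- which(!is.finite(texture), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("reaction-diffusion integration diverged near ",
                        "F = %.4f, k = %.4f; narrow the parameter ranges ",
                        "or reduce dt"),
                 F_col[bad[2]], k_row[bad[1]]), call. = FALSE)
  }
  rng <- range(texture)
  flat <- (rng[2] - rng[1]) < 1e-12
  texture <- if (flat) matrix(0, n, n) else (texture - rng[1]) / (rng[2] - rng[1])
  out <- structure(list(texture = texture, F_range = F_range,
                        k_range = k_range, resolution = n,
                        iterations = as.integer(iterations),
                        Du = Du, Dv = Dv, dt = dt, seed = as.integer(seed),
                        flat = flat),
                   class = "rd_gamut")
  if (cache) .camosim_cache[[key]] <- out
  out
}

#' @export
print.rd_gamut <- function(x, ...) {
  cat("<rd_gamut> ", x$resolution, "x", x$resolution,
      " F=[", x$F_range[1], ",", x$F_range[2], "]",
      " k=[", x$k_range[1], ",", x$k_range[2], "]",
      if (x$flat) " (flat)" else "", "\n", sep = "")
  invisible(x)
}
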