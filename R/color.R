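# CIELAB <-> sRGB via grDevices::convertColor (D65 white point throughout).

#' CIELAB exploration limits for target colors
#'
#' The ranges onto which the 0-1 color genes are mapped affinely. Defaults
#' follow the packaged demo experiment: L (lightness) 0-100, A (green-red)
#' -60-60, B (blue-yellow) -10-70. Optional narrower `start` ranges constrain
#' only the colors of the initial population; the exploration space itself is
#' unchanged (initial color genes are rescaled into the sub-interval of [0,1]
#' that maps into the start range).
#'
#' @param L,A,B numeric length-2 ranges `c(min, max)`.
#' @param start optional named list with any of `L`, `A`, `B` ranges for the
#'   starting population; each must lie inside the main range.
#' @return an object of class `color_limits`.
#' @export
color_limits <- function(L = c(0, 100), A = c(-60, 60), B = c(-10, 70),
                         start = NULL) {
  chk <- function(r, nm) {
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2])
      stop("invalid ", nm, " range: min must be < max", call. = FALSE)
  }
  chk(L, "L"); chk(A, "A"); chk(B, "B")
  if (!is.null(start)) {
    main <- list(L = L, A = A, B = B)
    for (nm in names(start)) {
      chk(start[[nm]], paste0("start ", nm))
      if (start[[nm]][1] < main[[nm]][1] || start[[nm]][2] > main[[nm]][2])
        stop("start range for ", nm, " must lie inside the main range", call. = FALSE)
    }
  }
  structure(list(L = L, A = A, B = B, start = start), class = "color_limits")
}

# map a 0-1 gene onto a channel range
gene_to_channel <- function(gene, range) range[1] + gene * (range[2] - range[1])

#' Convert CIELAB values to sRGB
#'
#' @param lab an n x 3 matrix of L, A, B values or an H x W x 3 array.
#' @return values in `[0, 1]`, same shape as the input; the number of pixels
#'   clipped at the sRGB gamut boundary is attached as attribute `"clipped"`.
#' @export
lab_to_srgb <- function(lab) {
  arr <- length(dim(lab)) == 3
  m <- if (arr) matrix(lab, ncol = 3) else lab
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB",
                                 from.ref.white = "D65", to.ref.white = "D65",
                                 clip = FALSE)
  clipped <- sum(rowSums(rgb < -1e-9 | rgb > 1 + 1e-9) > 0)
  rgb <- clamp01(rgb)
  out <- if (arr) array(rgb, dim = dim(lab)) else rgb
  attr(out, "clipped") <- clipped
  out
}

#' Convert sRGB values to CIELAB
#' @param rgb an n x 3 matrix or H x W x 3 array with values in `[0, 1]`.
#' @return CIELAB values, same shape.
#' @export
srgb_to_lab <- function(rgb) {
  arr <- length(dim(rgb)) == 3
  m <- if (arr) matrix(rgb, ncol = 3) else rgb
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab",
                                 from.ref.white = "D65", to.ref.white = "D65")
  if (arr) array(lab, dim = dim(rgb)) else lab
}
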