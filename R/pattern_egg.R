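# Egg-style phenotypes: thresholded-noise maculation (two layers, one smeared
# by a random walk) and a two-axis pigment model (deposition x
# biliverdin:protoporphyrin ratio) mapped into CIELAB within avian bounds.

#' Egg phenotype specification
#'
#' @param noise_sigma_range Gaussian smoothing range of the noise sheet
#'   (sigma varies along y, so the `win_y` genes select the texture
#'   granularity).
#' @param scale_range window-size range as a fraction of the noise sheet.
#' @param shade_range maximum gradient-shade strength.
#' @param weight_range per-layer deposition weight range.
#' @param walk_steps_range random-walk step count range (layer b).
#' @param walk_length_range random-walk step length range, px.
#' @param luminance_shift_L extreme of the global exposure shift, L units
#'   (gene 0.5 maps to zero shift).
#' @return an object of class `egg_spec`.
#' @export
egg_spec <- function(noise_sigma_range = c(0.5, 8),
                     scale_range = c(0.1, 0.5),
                     shade_range = c(0, 0.5),
                     weight_range = c(0, 1),
                     walk_steps_range = c(0, 40),
                     walk_length_range = c(1, 5),
                     luminance_shift_L = 15) {
  structure(list(noise_sigma_range = noise_sigma_range,
                 scale_range = scale_range, shade_range = shade_range,
                 weight_range = weight_range,
                 walk_steps_range = walk_steps_range,
                 walk_length_range = walk_length_range,
                 luminance_shift_L = luminance_shift_L,
                 tags = egg_tag_layout()),
            class = "egg_spec")
}

#' Egg pigment color model
#'
#' Coloration is determined by two axes: deposition (amount of pigment) and
#' ratio (biliverdin : protoporphyrin mixture). More deposition makes the
#' egg darker and more saturated. Anchors give the CIELAB color of the bare
#' shell (zero deposition) and of full deposition of each pure pigment;
#' interpolation runs in LCh (lightness, chroma, hue) space so lightness is
#' monotone non-increasing and chroma monotone non-decreasing in deposition.
#' The avian color bound is the reachable surface of the model itself.
#'
#' @param shell,biliverdin,protoporphyrin CIELAB anchor vectors `c(L, A, B)`.
#' @param exponent deposition interpolation exponent (1 = linear).
#' @return an object of class `egg_color_model`.
#' @export
egg_color_model <- function(shell = c(93, 2, 12),
                            biliverdin = c(55, -18, 2),
                            protoporphyrin = c(35, 18, 30),
                            exponent = 1) {
  to_lch <- function(lab) {
    c(L = lab[1], C = sqrt(lab[2]^2 + lab[3]^2), h = atan2(lab[3], lab[2]))
  }
  structure(list(shell = shell, biliverdin = biliverdin,
                 protoporphyrin = protoporphyrin, exponent = exponent,
                 shell_lch = to_lch(shell), bili_lch = to_lch(biliverdin),
                 proto_lch = to_lch(protoporphyrin)),
            class = "egg_color_model")
}

# interpolate hue angles along the shorter arc
mix_hue <- function(h0, h1, t) {
  d <- ((h1 - h0 + pi) %% (2 * pi)) - pi
  h0 + t * d
}

#' Map deposition and pigment ratio to CIELAB
#'
#' The pigment color is the ratio-interpolation between the protoporphyrin
#' (`ratio = 0`) and biliverdin (`ratio = 1`) anchors; the output is the
#' deposition-weighted interpolation from the shell anchor toward that
#' pigment color (exponent-warped), all in LCh space.
#'
#' @param deposition,ratio numeric vectors in `[0, 1]` (recycled).
#' @param model an [egg_color_model()].
#' @return n x 3 matrix of CIELAB values.
#' @export
egg_pigment_to_lab <- function(deposition, ratio, model = egg_color_model()) {
  n <- max(length(deposition), length(ratio))
  deposition <- rep_len(clamp01(deposition), n)
  ratio <- rep_len(clamp01(ratio), n)
  pr <- model$proto_lch; bi <- model$bili_lch; sh <- model$shell_lch
  pig_L <- pr[["L"]] + ratio * (bi[["L"]] - pr[["L"]])
  pig_C <- pr[["C"]] + ratio * (bi[["C"]] - pr[["C"]])
  pig_h <- mix_hue(pr[["h"]], bi[["h"]], ratio)
  t <- deposition^model$exponent
  L <- sh[["L"]] + t * (pig_L - sh[["L"]])
  C <- sh[["C"]] + t * (pig_C - sh[["C"]])
  h <- mix_hue(sh[["h"]], pig_h, t)
  cbind(L = L, A = C * cos(h), B = C * sin(h))
}

#' Reachable CIELAB bounds of an egg color model
#'
#' Channel-wise ranges of the model surface over a fine (deposition, ratio)
#' grid -- the configured avian egg color bound.
#'
#' @param model an [egg_color_model()].
#' @param n grid resolution per axis.
#' @return list of length-2 ranges `L`, `A`, `B`.
#' @export
egg_color_bounds <- function(model = egg_color_model(), n = 101L) {
  g <- expand.grid(dep = seq(0, 1, length.out = n),
                   rat = seq(0, 1, length.out = n))
  lab <- egg_pigment_to_lab(g$dep, g$rat, model)
  list(L = range(lab[, 1]), A = range(lab[, 2]), B = range(lab[, 3]))
}

# noise sheet whose Gaussian smoothing sigma varies along y; cached per seed
egg_noise_sheet <- function(n = 192L, sigma_range = c(0.5, 8), seed = 1L) {
  key <- paste("eggnoise", n, paste(sigma_range, collapse = ","), seed,
               sep = "|")
  if (!is.null(.camosim_cache[[key]])) return(.camosim_cache[[key]])
  sheet <- with_seed(seed, {
    base <- matrix(runif(n * n), n, n)
    sigmas <- exp(seq(log(max(sigma_range[1], 0.3)), log(sigma_range[2]),
                      length.out = 7))
    stack <- lapply(sigmas, function(s) {
      b <- gaussian_blur(base, s)
      # restandardize each level so the threshold genes act comparably
      (b - mean(b)) / max(stats::sd(b), 1e-9) * 0.2 + 0.5
    })
    row_sigma <- seq(sigma_range[1], sigma_range[2], length.out = n)
    out <- matrix(0, n, n)
    for (i in seq_len(n)) {
      pos <- stats::approx(sigmas, seq_along(sigmas), xout = row_sigma[i],
                           rule = 2)$y
      lo <- floor(pos); hi <- min(lo + 1, length(sigmas)); f <- pos - lo
      out[i, ] <- (1 - f) * stack[[lo]][i, ] + f * stack[[hi]][i, ]
    }
    clamp01(out)
  })
  .camosim_cache[[key]] <- sheet
  sheet
}

# one maculation layer: window, scale, shade, threshold (values below -> 0)
egg_layer <- function(sheet, x_g, y_g, scale_g, shade_g, thresh_g, out_dim,
                      spec) {
  n <- nrow(sheet)
  frac <- gene_to_channel(scale_g, spec$scale_range)
  w_px <- clamp(frac * n, 2, n)
  x0 <- 1 + x_g * (n - w_px)
  y0 <- 1 + y_g * (n - w_px)
  H <- out_dim[1]; W <- out_dim[2]
  yy <- y0 + (seq_len(H) - 0.5) / H * w_px
  xx <- x0 + (seq_len(W) - 0.5) / W * w_px
  patch <- bilinear_sample(sheet, matrix(yy, H, W),
                           matrix(xx, H, W, byrow = TRUE))
  strength <- gene_to_channel(shade_g, spec$shade_range)
  if (strength > 0) {
    ry <- matrix(seq_len(H) - (H + 1) / 2, H, W) / max(H, 1)
    patch <- clamp01(patch + strength * ry)
  }
  patch[patch < thresh_g] <- 0
  patch
}

# smear a layer by a seeded random walk: union (pmax) of displaced copies
random_walk_smear <- function(layer, n_steps, step_len) {
  n_steps <- as.integer(round(n_steps))
  if (n_steps < 1) return(layer)
  H <- nrow(layer); W <- ncol(layer)
  out <- layer
  y_off <- 0L; x_off <- 0L
  dirs <- matrix(c(-1, -1, -1, 0, -1, 1, 0, -1, 0, 1, 1, -1, 1, 0, 1, 1),
                 ncol = 2, byrow = TRUE)
  for (s in seq_len(n_steps)) {
    d <- dirs[sample.int(8, 1), ]
    y_off <- y_off + d[1] * step_len
    x_off <- x_off + d[2] * step_len
    shifted <- matrix(0, H, W)
    ys <- seq_len(H) - round(y_off); xs <- seq_len(W) - round(x_off)
    ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
    if (any(ok_y) && any(ok_x))
      shifted[ok_y, ok_x] <- layer[ys[ok_y], xs[ok_x]]
    out <- pmax(out, shifted)
  }
  out
}

#' Egg maculation: two layers and the combined deposition field
#'
#' Each layer windows, scales and shades a Gaussian noise sheet whose
#' smoothing varies along y, then zeroes values below its threshold gene.
#' Layer b is additionally smeared by a seeded random walk (copy-paste of
#' the maculation along the walk), creating spirals and streaks. The
#' deposition field combines the base deposition with both weighted layers,
#' clamped to `[0, 1]`.
#'
#' @param g a `camo_genome` with the [egg_tag_layout()].
#' @param out_dim integer `c(height, width)`.
#' @param spec an [egg_spec()].
#' @param seed seed for the noise sheet and the random walk.
#' @return list: `layer_a`, `layer_b` (matrices in `[0,1]`), `deposition`.
#' @export
egg_maculation <- function(g, out_dim, spec = egg_spec(), seed = 1L) {
  gn <- function(tag) gene_of(g, tag)
  sheet <- egg_noise_sheet(sigma_range = spec$noise_sigma_range, seed = seed)
  la <- egg_layer(sheet, gn("mca_win_x"), gn("mca_win_y"), gn("mca_mod_scale"),
                  gn("mca_shd_strength"), gn("mca_mod_thresh"), out_dim, spec)
  lb <- egg_layer(sheet, gn("mcb_win_x"), gn("mcb_win_y"), gn("mcb_mod_scale"),
                  gn("mcb_shd_strength"), gn("mcb_mod_thresh"), out_dim, spec)
  steps <- gene_to_channel(gn("mcb_wlk_steps"), spec$walk_steps_range)
  len <- gene_to_channel(gn("mcb_wlk_length"), spec$walk_length_range)
  lb <- with_seed(derive_seed(seed, paste0(g$id, "/walk")),
                  random_walk_smear(lb, steps, len))
  wa <- gene_to_channel(gn("mca_pig_weight"), spec$weight_range)
  wb <- gene_to_channel(gn("mcb_pig_weight"), spec$weight_range)
  base <- gn("col_pig_dep")
  deposition <- clamp01(base + wa * la + wb * lb)
  list(layer_a = la, layer_b = lb, deposition = deposition)
}

#' Render an egg-style target phenotype
#'
#' Per-pixel deposition is mapped through the pigment model (shared ratio
#' gene, per-layer deposition weights); the global exposure-shift gene then
#' adds up to +/- `luminance_shift_L` to L (gene 0.5 = no shift), mimicking
#' camera exposure variation. Deterministic given (genome, spec, model,
#' seed).
#'
#' @param g a `camo_genome` with the [egg_tag_layout()].
#' @param shape_mask logical egg silhouette ([egg_mask()] by default).
#' @param spec an [egg_spec()].
#' @param model an [egg_color_model()].
#' @param seed run seed.
#' @return a `target_image`.
#' @export
render_egg <- function(g, shape_mask = egg_mask(), spec = egg_spec(),
                       model = egg_color_model(), seed = 1L) {
  if (!is.logical(shape_mask)) {
    if (!all(shape_mask %in% c(0, 1)))
      stop("shape mask must be binary", call. = FALSE)
    shape_mask <- shape_mask > 0.5
  }
  mac <- egg_maculation(g, dim(shape_mask), spec, seed)
  ratio <- gene_of(g, "col_pig_ratio")
  lab_flat <- egg_pigment_to_lab(as.vector(mac$deposition), ratio, model)
  H <- dim(shape_mask)[1]; W <- dim(shape_mask)[2]
  lab <- array(0, c(H, W, 3))
  shift <- (gene_of(g, "col_exp_shift") - 0.5) * 2 * spec$luminance_shift_L
  lab[, , 1] <- matrix(lab_flat[, 1], H, W) + shift
  lab[, , 2] <- matrix(lab_flat[, 2], H, W)
  lab[, , 3] <- matrix(lab_flat[, 3], H, W)
  for (ch in 1:3) {
    plane <- lab[, , ch]
    plane[!shape_mask] <- 0
    lab[, , ch] <- plane
  }
  structure(list(lab = lab, alpha = shape_mask, id = g$id,
                 max_diameter = mask_max_diameter(shape_mask)),
            class = "target_image")
}
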