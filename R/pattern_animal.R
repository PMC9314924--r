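# Animal-style phenotype rendering: reaction-diffusion maculation sampled
# from the gamut, bilateral symmetry, CIELAB coloration, edge enhancement
# and speckling. Every named parameter is controlled by exactly one tagged
# gene (see animal_tag_layout()).

#' Animal phenotype specification
#'
#' Fixed, documented mappings from 0-1 genes onto rendering parameters.
#' Symmetry is an experimenter choice (circle/triangle targets are
#' asymmetric, moth/frog targets bilaterally symmetric), not an evolvable
#' gene.
#'
#' @param symmetric logical; mirror the maculation about the vertical
#'   midline.
#' @param window_frac length-2 range of the gamut-window side as a fraction
#'   of the gamut (scaled further by the scale gene over `scale_range`).
#' @param scale_range multiplier range for the pattern-scale gene.
#' @param stretch_range Y-stretch range for stripe generation (1x to 8x).
#' @param shade_range maximum luminance-gradient strength (0-1 patch units).
#' @param speckle_density_range fraction of pixels receiving salt noise.
#' @param speckle_sigma_range Gaussian blur sigma for speckles, px.
#' @param edge_intensity_range L-unit range of edge enhancement intensity.
#' @param edge_expansion_range band width range, px.
#' @param edge_sigma_range falloff blur sigma range, px.
#' @return an object of class `animal_spec`.
#' @export
animal_spec <- function(symmetric = FALSE,
                        window_frac = c(0.08, 0.45),
                        scale_range = c(0.5, 2),
                        stretch_range = c(1, 8),
                        shade_range = c(0, 0.5),
                        speckle_density_range = c(0, 0.05),
                        speckle_sigma_range = c(0.5, 3),
                        edge_intensity_range = c(0, 25),
                        edge_expansion_range = c(0, 10),
                        edge_sigma_range = c(0.5, 3)) {
  structure(list(symmetric = isTRUE(symmetric), window_frac = window_frac,
                 scale_range = scale_range, stretch_range = stretch_range,
                 shade_range = shade_range,
                 speckle_density_range = speckle_density_range,
                 speckle_sigma_range = speckle_sigma_range,
                 edge_intensity_range = edge_intensity_range,
                 edge_expansion_range = edge_expansion_range,
                 edge_sigma_range = edge_sigma_range,
                 tags = animal_tag_layout()),
            class = "animal_spec")
}

# named gene lookup
gene_of <- function(g, tag) {
  i <- match(tag, g$tags)
  if (is.na(i)) stop("genome lacks gene tagged ", tag, call. = FALSE)
  g$genes[i]
}

#' Sample a window of the reaction-diffusion gamut
#'
#' Crops the gene-addressed window (position and size genes, scaled by the
#' scale gene), rescales it to the target bounding box with an optional
#' Y-stretch for stripes, and adds a linear luminance gradient of
#' gene-controlled angle and strength. Windows clamp to the gamut bounds;
#' output is in `[0, 1]`.
#'
#' @param gamut an `rd_gamut`.
#' @param genes named numeric vector with elements `x`, `y`, `wid`, `hei`,
#'   `scale`, `stretch`, `angle`, `strength`, all in `[0, 1]`.
#' @param out_dim integer `c(height, width)` of the output patch.
#' @param spec an [animal_spec()] providing the parameter ranges.
#' @return numeric matrix `out_dim` in `[0, 1]`.
#' @export
sample_gamut <- function(gamut, genes, out_dim, spec = animal_spec()) {
  n <- gamut$resolution
  wf <- gene_to_channel(genes[["wid"]], spec$window_frac) *
    gene_to_channel(genes[["scale"]], spec$scale_range)
  hf <- gene_to_channel(genes[["hei"]], spec$window_frac) *
    gene_to_channel(genes[["scale"]], spec$scale_range)
  w_px <- clamp(wf * n, 2, n)
  h_px <- clamp(hf * n, 2, n)
  x0 <- 1 + genes[["x"]] * (n - w_px)
  y0 <- 1 + genes[["y"]] * (n - h_px)
  stretch <- gene_to_channel(genes[["stretch"]], spec$stretch_range)
  H <- out_dim[1]; W <- out_dim[2]
  # stripes: compress the source row step by the stretch factor
  yy <- y0 + (seq_len(H) - 0.5) / H * (h_px / stretch)
  xx <- x0 + (seq_len(W) - 0.5) / W * w_px
  patch <- bilinear_sample(gamut$texture,
                           matrix(yy, H, W), matrix(xx, H, W, byrow = TRUE))
  strength <- gene_to_channel(genes[["strength"]], spec$shade_range)
  if (strength > 0) {
    th <- genes[["angle"]] * 2 * pi
    ry <- matrix(seq_len(H) - (H + 1) / 2, H, W) / max(H, 1)
    rx <- matrix(seq_len(W) - (W + 1) / 2, H, W, byrow = TRUE) / max(W, 1)
    ramp <- rx * cos(th) + ry * sin(th)  # in about [-0.7, 0.7]
    patch <- patch + strength * ramp
  }
  clamp01(patch)
}

#' Binarize a patch into a maculation mask, optionally mirrored
#'
#' `mask = patch >= threshold` (white = maculation). When `symmetric`, the
#' left half is reflected onto the right about the vertical midline.
#'
#' @param patch numeric matrix in `[0, 1]`.
#' @param threshold scalar threshold in `[0, 1]`.
#' @param symmetric logical.
#' @return logical matrix.
#' @export
binarize_and_mirror <- function(patch, threshold, symmetric = FALSE) {
  mask <- patch >= threshold
  if (symmetric) {
    W <- ncol(mask)
    left_w <- ceiling(W / 2)
    mask[, W:(W - left_w + 1)] <- mask[, seq_len(left_w)]
  }
  mask
}

#' Apply CIELAB coloration to a maculation mask
#'
#' Each of the six color genes maps affinely onto its configured channel
#' range; maculation pixels receive the maculation color, the rest the
#' background color.
#'
#' @param mask logical maculation matrix.
#' @param genes named numeric vector `bkg_lum`, `bkg_a`, `bkg_b`,
#'   `mac_lum`, `mac_a`, `mac_b`, each in `[0, 1]`.
#' @param limits a [color_limits()].
#' @return H x W x 3 CIELAB array.
#' @export
colorize <- function(mask, genes, limits = color_limits()) {
  bkg <- c(gene_to_channel(genes[["bkg_lum"]], limits$L),
           gene_to_channel(genes[["bkg_a"]], limits$A),
           gene_to_channel(genes[["bkg_b"]], limits$B))
  mac <- c(gene_to_channel(genes[["mac_lum"]], limits$L),
           gene_to_channel(genes[["mac_a"]], limits$A),
           gene_to_channel(genes[["mac_b"]], limits$B))
  lab <- array(0, c(nrow(mask), ncol(mask), 3))
  for (ch in 1:3) {
    plane <- matrix(bkg[ch], nrow(mask), ncol(mask))
    plane[mask] <- mac[ch]
    lab[, , ch] <- plane
  }
  lab
}

#' Edge enhancement along the maculation boundary
#'
#' Increases luminance contrast at the maculation edge: the dark side gets
#' darker and the light side lighter, within bands whose width (expansion),
#' strength (intensity) and falloff blur (sigma) are independently
#' gene-controlled for the light and dark regions. A/B planes are untouched.
#'
#' @param lab H x W x 3 CIELAB array.
#' @param mask logical maculation matrix.
#' @param genes named vector `lgt_int`, `lgt_exp`, `lgt_sig`, `drk_int`,
#'   `drk_exp`, `drk_sig` in `[0, 1]`.
#' @param spec an [animal_spec()].
#' @param limits a [color_limits()]; L is clamped to its range afterwards.
#' @return modified CIELAB array.
#' @export
edge_enhance <- function(lab, mask, genes, spec = animal_spec(),
                         limits = color_limits()) {
  if (all(mask) || !any(mask)) return(lab)  # no boundary
  L <- lab[, , 1]
  mac_L <- mean(L[mask]); bkg_L <- mean(L[!mask])
  dark_side <- if (mac_L <= bkg_L) mask else !mask
  b <- boundary_pixels(mask) | boundary_pixels(!mask)
  apply_band <- function(L, side, int_g, exp_g, sig_g, sign) {
    intensity <- gene_to_channel(int_g, spec$edge_intensity_range)
    if (intensity <= 0) return(L)
    width <- gene_to_channel(exp_g, spec$edge_expansion_range)
    sigma <- gene_to_channel(sig_g, spec$edge_sigma_range)
    d <- band_distance(b, side, max_d = ceiling(width))
    band <- matrix(0, nrow(L), ncol(L))
    band[is.finite(d) & d <= width] <- 1
    L + sign * intensity * gaussian_blur(band, sigma)
  }
  L <- apply_band(L, dark_side, genes[["drk_int"]], genes[["drk_exp"]],
                  genes[["drk_sig"]], -1)
  L <- apply_band(L, !dark_side, genes[["lgt_int"]], genes[["lgt_exp"]],
                  genes[["lgt_sig"]], +1)
  lab[, , 1] <- clamp(L, limits$L[1], limits$L[2])
  lab
}

#' Speckling: blurred salt noise on the luminance plane
#'
#' Adds salt-type bright noise at a gene-scaled density, Gaussian-blurred
#' with a gene-scaled sigma, composited onto L. Density 0 is the identity.
#'
#' @param lab H x W x 3 CIELAB array.
#' @param density_gene,size_gene genes in `[0, 1]`.
#' @param spec an [animal_spec()].
#' @param limits a [color_limits()].
#' @param amplitude speckle brightness in L units (default 40).
#' @return modified CIELAB array.
#' @export
apply_speckling <- function(lab, density_gene, size_gene,
                            spec = animal_spec(), limits = color_limits(),
                            amplitude = 40) {
  density <- gene_to_channel(density_gene, spec$speckle_density_range)
  if (density <= 0) return(lab)
  sigma <- gene_to_channel(size_gene, spec$speckle_sigma_range)
  H <- dim(lab)[1]; W <- dim(lab)[2]
  salt <- matrix(as.numeric(runif(H * W) < density), H, W)
  lab[, , 1] <- clamp(lab[, , 1] + amplitude * gaussian_blur(salt, sigma),
                      limits$L[1], limits$L[2])
  lab
}

# --- shape masks -------------------------------------------------------------

#' Built-in target shape masks
#'
#' `triangle_mask` is an isoceles triangle (apex up) filling a `w x h`
#' bounding box -- the packaged demo uses 150 x 75 px. `ellipse_mask` and
#' `egg_mask` fill the box with an ellipse and an egg-shaped oval (one end
#' narrowed).
#'
#' @param w,h bounding box width and height in px.
#' @return logical matrix (`TRUE` = target).
#' @export
triangle_mask <- function(w = 150L, h = 75L) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    half <- (i / h) * (w / 2)
    x0 <- max(1, ceiling(w / 2 - half)); x1 <- min(w, floor(w / 2 + half))
    if (x1 >= x0) m[i, x0:x1] <- TRUE
  }
  m
}

#' @rdname triangle_mask
#' @export
ellipse_mask <- function(w = 100L, h = 70L) {
  y <- matrix(seq_len(h) - (h + 1) / 2, h, w) / (h / 2)
  x <- matrix(seq_len(w) - (w + 1) / 2, h, w, byrow = TRUE) / (w / 2)
  x^2 + y^2 <= 1
}

#' @rdname triangle_mask
#' @export
egg_mask <- function(w = 80L, h = 100L) {
  # vertical egg: width tapers toward the top via a linear asymmetry term
  y <- matrix((seq_len(h) - (h + 1) / 2) / (h / 2), h, w)
  x <- matrix((seq_len(w) - (w + 1) / 2) / (w / 2), h, w, byrow = TRUE)
  taper <- 1 + 0.25 * y  # narrower at y = -1 (top)
  (x / taper)^2 + y^2 <= 1
}

# max pairwise extent of a mask (target "maximum diameter"), via convex hull
mask_max_diameter <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2) return(0)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[hull, , drop = FALSE]
  d <- as.matrix(stats::dist(hp))
  max(d) + 1  # pixel centres -> add one pixel of extent
}

#' Render an animal-style target phenotype
#'
#' Full pipeline: gamut sampling, binarization and optional mirroring,
#' CIELAB coloration, edge enhancement, speckling, masked to the target
#' silhouette. Deterministic given (genome, spec, gamut, seed): the speckle
#' noise stream is derived from the run seed and the genome id.
#'
#' @param g a `camo_genome` with the [animal_tag_layout()].
#' @param shape_mask logical silhouette matrix (`TRUE` = target).
#' @param spec an [animal_spec()].
#' @param limits a [color_limits()].
#' @param gamut an `rd_gamut`.
#' @param seed run seed used to derive the speckle stream.
#' @return an object of class `target_image`: list with `lab` (H x W x 3),
#'   `alpha` (logical mask), `id`, `max_diameter`.
#' @export
render_target <- function(g, shape_mask, spec = animal_spec(),
                          limits = color_limits(), gamut, seed = 1L) {
  if (!is.logical(shape_mask)) {
    if (!all(shape_mask %in% c(0, 1)))
      stop("shape mask must be binary", call. = FALSE)
    shape_mask <- shape_mask > 0.5
  }
  gn <- function(tag) gene_of(g, tag)
  patch <- sample_gamut(gamut,
                        c(x = gn("pat_win_x"), y = gn("pat_win_y"),
                          wid = gn("pat_win_wid"), hei = gn("pat_win_hei"),
                          scale = gn("pat_mod_scale"),
                          stretch = gn("pat_mod_stretch"),
                          angle = gn("pat_shd_angle"),
                          strength = gn("pat_shd_strength")),
                        dim(shape_mask), spec)
  mac <- binarize_and_mirror(patch, gn("pat_mod_thresh"), spec$symmetric)
  lab <- colorize(mac,
                  c(bkg_lum = gn("col_bkg_lum"), bkg_a = gn("col_bkg_a"),
                    bkg_b = gn("col_bkg_b"), mac_lum = gn("col_mac_lum"),
                    mac_a = gn("col_mac_a"), mac_b = gn("col_mac_b")),
                  limits)
  lab <- edge_enhance(lab,
                      mac,
                      c(lgt_int = gn("edg_lgt_int"), lgt_exp = gn("edg_lgt_exp"),
                        lgt_sig = gn("edg_lgt_sig"), drk_int = gn("edg_drk_int"),
                        drk_exp = gn("edg_drk_exp"), drk_sig = gn("edg_drk_sig")),
                      spec, limits)
  lab <- with_seed(derive_seed(seed, g$id),
                   apply_speckling(lab, gn("spk_noi_density"),
                                   gn("spk_noi_size"), spec, limits))
  for (ch in 1:3) {
    plane <- lab[, , ch]
    plane[!shape_mask] <- 0
    lab[, , ch] <- plane
  }
  structure(list(lab = lab, alpha = shape_mask, id = g$id,
                 max_diameter = mask_max_diameter(shape_mask)),
            class = "target_image")
}

#' @export
print.target_image <- function(x, ...) {
  cat("<target_image> id=", x$id, " ", dim(x$lab)[1], "x", dim(x$lab)[2],
      " max_diameter=", round(x$max_diameter, 1), "\n", sep = "")
  invisible(x)
}

#' sRGB raster of a rendered target
#' @param target a `target_image`.
#' @return H x W x 3 sRGB array in `[0, 1]` (pixels outside the mask are 0).
#' @export
target_srgb <- function(target) {
  srgb <- lab_to_srgb(target$lab)
  for (ch in 1:3) {
    plane <- srgb[, , ch]
    plane[!target$alpha] <- 0
    srgb[, , ch] <- plane
  }
  srgb
}
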