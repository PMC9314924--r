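# Reaction-diffusion gamut and the animal phenotype rendering pipeline.

test_that("gamut build is deterministic, normalized and patterned", {
  g1 <- build_rd_gamut(resolution = 96L, iterations = 1500L, seed = 42L,
                       cache = FALSE)
  g2 <- build_rd_gamut(resolution = 96L, iterations = 1500L, seed = 42L,
                       cache = FALSE)
  expect_identical(g1$texture, g2$texture)
  expect_true(all(g1$texture >= 0 & g1$texture <= 1))
  # cache hit is bit-identical to a fresh build
  g3 <- test_gamut()
  expect_identical(g3$texture, g1$texture)
  expect_identical(test_gamut()$texture, g3$texture)
  # patterning emerges in the spotted region (F ~ 0.03, k ~ 0.062)
  n <- g1$resolution
  cols <- round(((0.025 - 0.01) / 0.08) * n):round(((0.04 - 0.01) / 0.08) * n)
  rows <- round(((0.055 - 0.045) / 0.025) * n):round(((0.068 - 0.045) / 0.025) * n)
  expect_gt(sd(g1$texture[rows, cols]), 0.05)
})

test_that("gamut degenerate and divergent cases", {
  flat <- build_rd_gamut(resolution = 48L, iterations = 300L, seed = 1L,
                         perturb = FALSE, cache = FALSE)
  expect_true(flat$flat)
  expect_true(all(flat$texture == 0))
  expect_error(build_rd_gamut(resolution = 48L, iterations = 600L, dt = 2.5,
                              seed = 1L, cache = FALSE),
               "diverged near F = ")
})

test_that("gamut sampling: windows, gradient and stripe stretch", {
  gam <- test_gamut()
  base <- c(x = 0.3, y = 0.3, wid = 0.5, hei = 0.5, scale = 0.5,
            stretch = 0, angle = 0.25, strength = 0)
  p0 <- sample_gamut(gam, base, c(40, 40))
  expect_true(all(p0 >= 0 & p0 <= 1))
  # zero gradient strength: the angle gene has no effect
  p1 <- sample_gamut(gam, replace(base, "angle", 0.9), c(40, 40))
  expect_identical(p0, p1)
  # nonzero strength shifts luminance along the gradient
  p2 <- sample_gamut(gam, replace(base, "strength", 1), c(40, 40))
  expect_gt(mean(abs(p2 - p0)), 0)
  # opposite gamut corners give different patches
  ca <- sample_gamut(gam, replace(base, c("x", "y"), c(0, 0)), c(40, 40))
  cb <- sample_gamut(gam, replace(base, c("x", "y"), c(1, 1)), c(40, 40))
  expect_gt(sqrt(mean((ca - cb)^2)), 0.01)
  # maximal stretch: higher autocorrelation along Y than along X
  ps <- sample_gamut(gam, replace(base, "stretch", 1), c(60, 60))
  acf_dir <- function(m, dy, dx) {
    a <- m[seq_len(nrow(m) - dy), seq_len(ncol(m) - dx)]
    b <- m[dy + seq_len(nrow(m) - dy), dx + seq_len(ncol(m) - dx)]
    stats::cor(as.vector(a), as.vector(b))
  }
  expect_gt(acf_dir(ps, 3, 0), acf_dir(ps, 0, 3))
})

test_that("binarization and bilateral mirroring", {
  gam <- test_gamut()
  patch <- sample_gamut(gam, c(x = 0.3, y = 0.5, wid = 0.5, hei = 0.5,
                               scale = 0.5, stretch = 0, angle = 0,
                               strength = 0), c(50, 50))
  expect_true(all(binarize_and_mirror(patch, 0)))
  m <- binarize_and_mirror(patch, 0.5, symmetric = TRUE)
  expect_identical(m, m[, ncol(m):1])         # mirror-symmetric
  expect_identical(xor(m, m[, ncol(m):1]), matrix(FALSE, 50, 50))
  # threshold at the patch median splits area about in half
  frac <- mean(binarize_and_mirror(patch, median(patch)))
  expect_equal(frac, 0.5, tolerance = 0.02)
  # maculation fraction is monotone non-increasing in the threshold gene
  fr <- vapply(seq(0, 1, by = 0.1),
               function(th) mean(binarize_and_mirror(patch, th)), 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("colorization maps genes affinely onto the channel limits", {
  limits <- color_limits(L = c(0, 100), A = c(-60, 60), B = c(-10, 70))
  mask <- matrix(c(TRUE, FALSE), 2, 2)
  lab <- colorize(mask, c(bkg_lum = 0, bkg_a = 0.5, bkg_b = 1,
                          mac_lum = 1, mac_a = 0, mac_b = 0), limits)
  expect_equal(lab[1, 1, 1], 100)   # maculation L gene 1 -> 100
  expect_equal(lab[2, 1, 1], 0)     # background L gene 0 -> 0
  expect_equal(lab[2, 1, 2], 0)     # A gene 0.5 with range -60..60 -> 0
  expect_equal(lab[2, 1, 3], 70)    # B gene 1 with range -10..70 -> 70
  expect_equal(lab[1, 1, 2], -60)
  expect_equal(lab[1, 1, 3], -10)
})

test_that("edge enhancement darkens/lightens bands at the boundary only", {
  mask <- matrix(FALSE, 40, 40); mask[, 1:20] <- TRUE   # vertical interface
  lab <- colorize(mask, c(bkg_lum = 0.7, bkg_a = 0.5, bkg_b = 0.5,
                          mac_lum = 0.3, mac_a = 0.5, mac_b = 0.5))
  zero <- c(lgt_int = 0, lgt_exp = 0.5, lgt_sig = 0.5,
            drk_int = 0, drk_exp = 0.5, drk_sig = 0.5)
  expect_identical(edge_enhance(lab, mask, zero), lab)
  # uniform mask: no boundary, identity even at max intensity
  full <- matrix(TRUE, 40, 40)
  maxg <- replace(zero, c("lgt_int", "drk_int"), c(1, 1))
  expect_identical(edge_enhance(lab, full, maxg), lab)
  # max dark intensity lowers L near the dark (maculation) side boundary
  out <- edge_enhance(lab, mask, replace(zero, "drk_int", 1))
  band <- matrix(FALSE, 40, 40); band[, 19:20] <- TRUE  # 2 px inside dark side
  expect_lt(min(out[, , 1][band]), min(lab[, , 1][band]))
  # light side untouched by the dark band; A/B planes never change
  expect_equal(out[, , 2], lab[, , 2])
  expect_equal(out[, , 3], lab[, , 3])
})

test_that("speckling adds blurred salt noise to L only", {
  mask <- matrix(FALSE, 30, 30); mask[, 1:15] <- TRUE
  lab <- colorize(mask, c(bkg_lum = 0.5, bkg_a = 0.5, bkg_b = 0.5,
                          mac_lum = 0.5, mac_a = 0.5, mac_b = 0.5))
  expect_identical(apply_speckling(lab, 0, 0.5), lab)
  s1 <- camosim:::with_seed(9, apply_speckling(lab, 1, 0.1))
  s2 <- camosim:::with_seed(9, apply_speckling(lab, 1, 0.1))
  expect_identical(s1, s2)
  expect_gt(var(as.vector(s1[, , 1])), var(as.vector(lab[, , 1])))
  expect_equal(s1[, , 2], lab[, , 2])
})

test_that("full render is deterministic, masked and symmetric on demand", {
  gam <- test_gamut()
  tags <- animal_tag_layout()
  g <- rand_genome(tags, "r1", seed = 30)
  sm <- triangle_mask(40, 20)
  t1 <- render_target(g, sm, gamut = gam, seed = 5)
  t2 <- render_target(g, sm, gamut = gam, seed = 5)
  expect_identical(t1$lab, t2$lab)
  expect_identical(t1$alpha, sm)
  for (ch in 1:3) expect_true(all(t1$lab[, , ch][!sm] == 0))
  # CIELAB values inside the mask respect the limits
  lim <- color_limits()
  expect_true(all(t1$lab[, , 1][sm] >= lim$L[1] & t1$lab[, , 1][sm] <= lim$L[2]))
  expect_true(all(t1$lab[, , 2][sm] >= lim$A[1] & t1$lab[, , 2][sm] <= lim$A[2]))
  expect_true(all(t1$lab[, , 3][sm] >= lim$B[1] & t1$lab[, , 3][sm] <= lim$B[2]))
  # symmetric spec + symmetric mask: raster equals its mirror inside the mask
  # (speckling disabled: its noise is deliberately asymmetric)
  g$genes[match("spk_noi_density", tags)] <- 0
  em <- ellipse_mask(40, 30)
  ts <- render_target(g, em, spec = animal_spec(symmetric = TRUE),
                      gamut = gam, seed = 5)
  mirrored <- ts$lab[, ncol(em):1, , drop = FALSE]
  expect_equal(ts$lab, mirrored, tolerance = 1e-8)
  # binary 0/1 masks accepted, anything else rejected
  expect_error(render_target(g, matrix(0.3, 10, 10), gamut = gam),
               "binary")
  num <- render_target(g, matrix(c(0, 1), 10, 10), gamut = gam, seed = 5)
  expect_true(is.logical(num$alpha))
})

test_that("built-in shape masks have the advertised geometry", {
  tm <- triangle_mask(150, 75)
  expect_identical(dim(tm), c(75L, 150L))
  expect_equal(camosim:::mask_max_diameter(tm), 150, tolerance = 1e-4)
  em <- ellipse_mask(60, 40)
  expect_identical(em, em[, ncol(em):1])      # bilaterally symmetric
  eg <- egg_mask(40, 50)
  expect_identical(dim(eg), c(50L, 40L))
  # egg narrows toward the top
  expect_lt(sum(eg[10, ]), sum(eg[40, ]))
})
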