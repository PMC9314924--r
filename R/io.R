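# Shared formats: chromosome text logs, structured run configuration,
# synthetic background fixtures and portable anymap (PNM) rasters.
# Coordinate convention throughout: 0-based pixel indices, origin top-left,
# x rightward, y downward; rotations in counter-clockwise degrees.

#' Write / read a chromosome log
#'
#' One plain-text file per generation. Format: a header line with the
#' column names and tag labels (tab-separated), then one line per member:
#' id, lifeline flag (0/1), fitness, rank, then the gene values at 6
#' decimal places.
#'
#' @param pop a `camo_population`.
#' @param path file path.
#' @return `write_chromosomes` returns `path` invisibly; `read_chromosomes`
#'   returns a `camo_population`.
#' @export
write_chromosomes <- function(pop, path) {
  header <- paste(c("id", "lifeline", "fitness", "rank", pop$tags),
                  collapse = "\t")
  fit <- if (is.null(pop$fitnesses)) rep(NA_real_, pop$N) else pop$fitnesses
  rnk <- if (is.null(pop$ranks)) rep(NA_integer_, pop$N) else pop$ranks
  lines <- vapply(seq_len(pop$N), function(i) {
    paste(c(pop$ids[i], as.integer(pop$lifeline[i]),
            ifelse(is.na(fit[i]), "NA", sprintf("%.6f", fit[i])),
            ifelse(is.na(rnk[i]), "NA", as.character(rnk[i])),
            sprintf("%.6f", pop$genes[i, ])), collapse = "\t")
  }, character(1))
  # atomic write: temp file in the same directory, then rename
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(c(header, lines), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_chromosomes
#' @param expected_tags optional tag layout to validate the header against.
#' @param generation generation index to stamp on the population.
#' @export
read_chromosomes <- function(path, expected_tags = NULL, generation = 0L) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("chromosome file has no members", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 5 ||
      !identical(header[1:4], c("id", "lifeline", "fitness", "rank")))
    stop("malformed chromosome header", call. = FALSE)
  tags <- header[-(1:4)]
  if (!is.null(expected_tags) && !identical(tags, expected_tags)) {
    bad <- which(tags != expected_tags[seq_along(tags)])[1]
    offending <- if (length(tags) != length(expected_tags))
      tags[length(expected_tags) + 1] else tags[bad]
    stop("chromosome header tags do not match the expected layout; first ",
         "offending tag: ", offending, call. = FALSE)
  }
  G <- length(tags)
  n <- length(lines) - 1L
  genes <- matrix(0, n, G)
  ids <- character(n); lifeline <- logical(n)
  fit <- numeric(n); rnk <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L + G)
      stop("malformed chromosome line ", i + 1L, ": expected ", 4L + G,
           " fields, found ", length(f), call. = FALSE)
    ids[i] <- f[1]
    lifeline[i] <- f[2] == "1"
    fit[i] <- suppressWarnings(as.numeric(f[3]))
    rnk[i] <- suppressWarnings(as.integer(f[4]))
    gv <- as.numeric(f[-(1:4)])
    if (any(!is.finite(gv)) || any(gv < 0 | gv > 1))
      stop("gene value out of [0, 1] on line ", i + 1L, call. = FALSE)
    genes[i, ] <- gv
  }
  population(genes, tags, generation = generation, ids = ids,
             fitnesses = if (all(is.na(fit))) NULL else fit,
             ranks = if (all(is.na(rnk))) NULL else rnk,
             lifeline = lifeline)
}

#' Run configuration
#'
#' The full experiment description: genetic algorithm settings, phenotype
#' system, color limits, geometry, timing and observer parameters. Defaults
#' realize the packaged demo experiment: 24 triangle targets (150 x 75 px),
#' 1478 x 1130 px centre crops, 15 s slides, hybrid survival-time fitness
#' with a 600 ms threshold, 15 generations, two warm-up targets.
#'
#' @param ga a [ga_config()].
#' @param phenotype `"animal"` or `"egg"`.
#' @param limits a [color_limits()].
#' @param target_size integer `c(width, height)` of the target bounding box.
#' @param shape `"triangle"`, `"ellipse"` or `"egg"` (built-in masks), or a
#'   path to a PNM mask file (white = target).
#' @param crop_size integer `c(width, height)` of the background centre crop.
#' @param slide_duration slide timeout, ms.
#' @param hybrid_threshold capture-minus-response threshold of the hybrid
#'   fitness rule, ms.
#' @param fitness_method `"hybrid"`, `"response"`, `"capture"`, `"location"`.
#' @param generations number of generation turnovers.
#' @param warmups number of randomly generated warm-up targets shown first
#'   and excluded from the population (default 2).
#' @param region_factor local-background diameter factor (default 2).
#' @param symmetric logical, bilateral target symmetry.
#' @param gamut_resolution,gamut_iterations reaction-diffusion gamut build
#'   parameters.
#' @param backgrounds either `NULL` (synthesize per run), a character vector
#'   of PNM paths, or a list describing the synthetic set:
#'   `list(n =, mean_lab =, sd_lab =, corr_length =)`.
#' @param observer a list of [observer_model()] arguments.
#' @param out_dir optional output directory for run artifacts.
#' @param write_images logical; also write rendered targets/slides as PNM.
#' @param seed run seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(ga = ga_config(), phenotype = c("animal", "egg"),
                       limits = color_limits(),
                       target_size = c(150L, 75L), shape = "triangle",
                       crop_size = c(1478L, 1130L),
                       slide_duration = 15000, hybrid_threshold = 600,
                       fitness_method = "hybrid", generations = 15L,
                       warmups = 2L, region_factor = 2, symmetric = FALSE,
                       gamut_resolution = 256L, gamut_iterations = 5000L,
                       backgrounds = NULL, observer = list(),
                       out_dir = NULL, write_images = FALSE, seed = 1L) {
  phenotype <- match.arg(phenotype)
  structure(list(ga = ga, phenotype = phenotype, limits = limits,
                 target_size = as.integer(target_size), shape = shape,
                 crop_size = as.integer(crop_size),
                 slide_duration = slide_duration,
                 hybrid_threshold = hybrid_threshold,
                 fitness_method = fitness_method,
                 generations = as.integer(generations),
                 warmups = as.integer(warmups),
                 region_factor = region_factor,
                 symmetric = isTRUE(symmetric),
                 gamut_resolution = as.integer(gamut_resolution),
                 gamut_iterations = as.integer(gamut_iterations),
                 backgrounds = backgrounds, observer = observer,
                 out_dir = out_dir, write_images = isTRUE(write_images),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration (JSON)
#'
#' Round-trips losslessly: `read_config(write_config(cfg, path))` equals
#' `cfg` field for field.
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$ga <- unclass(x$ga)
  # named atomic vectors lose names in JSON arrays; keep them as objects
  x$ga$structural_rates <- as.list(x$ga$structural_rates)
  x$limits <- unclass(x$limits)
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ga$structural_rates <- unlist(x$ga$structural_rates)
  ga <- do.call(ga_config, x$ga[setdiff(names(x$ga), character(0))])
  limits <- color_limits(L = x$limits$L, A = x$limits$A, B = x$limits$B,
                         start = x$limits$start)
  args <- x[setdiff(names(x), c("ga", "limits"))]
  args$ga <- ga
  args$limits <- limits
  if (!is.null(args$backgrounds) && is.list(args$backgrounds))
    args$backgrounds <- lapply(args$backgrounds, unlist)
  do.call(run_config, args)
}

#' Synthetic background generator
#'
#' Spatially correlated noise standing in for photographed habitats: per
#' CIELAB channel, Gaussian-filtered white noise restandardized to the
#' requested mean and SD. The autocorrelation length (distance at which the
#' normalized autocorrelation falls to 1/e) equals `corr_length`; the blur
#' sigma is `corr_length / 2` since blurred white noise has Gaussian
#' autocovariance `exp(-d^2 / (4 sigma^2))`.
#'
#' @param width,height image size in px.
#' @param mean_lab,sd_lab length-3 channel means and SDs.
#' @param corr_length autocorrelation length in px.
#' @param seed RNG seed.
#' @return H x W x 3 CIELAB array.
#' @export
synth_background <- function(width = 1600L, height = 1200L,
                             mean_lab = c(50, 5, 15), sd_lab = c(12, 6, 6),
                             corr_length = 20, seed = 1L) {
  with_seed(seed, {
    lab <- array(0, c(height, width, 3))
    sigma <- corr_length / 2
    for (ch in 1:3) {
      z <- matrix(rnorm(height * width), height, width)
      z <- gaussian_blur(z, sigma)
      z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
      lab[, , ch] <- mean_lab[ch] + sd_lab[ch] * z
    }
    lab[, , 1] <- clamp(lab[, , 1], 0, 100)
    lab
  })
}

# --- portable anymap I/O -----------------------------------------------------

#' Read / write PNM rasters
#'
#' Minimal portable anymap support (P2/P3 ASCII, P5/P6 binary, maxval 255),
#' used for shape masks and rendered-image output since it needs no image
#' libraries. `write_pnm` takes a matrix (greyscale) or H x W x 3 array in
#' `[0, 1]`; `read_pnm` returns the same shapes. `read_mask` reads any PNM
#' and thresholds it at 0.5 (white = target).
#'
#' @param img numeric matrix or H x W x 3 array in `[0, 1]`.
#' @param path file path.
#' @param ascii logical; write ASCII (P2/P3) instead of binary (P5/P6).
#' @return `read_pnm`: matrix or array in `[0, 1]`; `read_mask`: logical
#'   matrix.
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  color <- length(dim(img)) == 3
  h <- dim(img)[1]; w <- dim(img)[2]
  vals <- if (color) {
    # interleave RGB row-major
    v <- array(0L, c(3, w, h))
    for (ch in 1:3) v[ch, , ] <- t(round(clamp01(img[, , ch]) * 255))
    as.integer(v)
  } else {
    as.integer(t(round(clamp01(img) * 255)))
  }
  magic <- if (color) (if (ascii) "P3" else "P6") else (if (ascii) "P2" else "P5")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(magic, paste(w, h), "255"), con)
  if (ascii) writeLines(paste(vals, collapse = " "), con)
  else writeBin(as.raw(vals), con)
  invisible(path)
}

#' @rdname write_pnm
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pnm_tokens(con, 4L)
  magic <- tok[1]
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic: ", magic, call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxv <- as.integer(tok[4])
  color <- magic %in% c("P3", "P6")
  n <- w * h * if (color) 3L else 1L
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("truncated PNM data", call. = FALSE)
  if (color) {
    arr <- array(0, c(h, w, 3))
    m <- matrix(vals, nrow = 3)
    for (ch in 1:3) arr[, , ch] <- matrix(m[ch, ], h, w, byrow = TRUE) / maxv
    arr
  } else {
    matrix(vals, h, w, byrow = TRUE) / maxv
  }
}

#' @rdname write_pnm
#' @export
read_mask <- function(path) {
  img <- read_pnm(path)
  if (length(dim(img)) == 3) img <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  img > 0.5
}

# read whitespace-separated header tokens, skipping '#' comments
pnm_tokens <- function(con, n) {
  out <- character(0)
  buf <- ""
  while (length(out) < n) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PNM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { out <- c(out, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  out
}

#' Load background images for a run
#'
#' @param backgrounds `NULL` or a list spec (synthesize) or character paths
#'   (PNM files, converted sRGB -> CIELAB).
#' @param cfg a [run_config()] (crop size used to validate dimensions).
#' @param seed base seed for synthetic backgrounds.
#' @return list of H x W x 3 CIELAB arrays.
#' @export
load_backgrounds <- function(backgrounds, cfg, seed = 1L) {
  if (is.character(backgrounds)) {
    out <- lapply(backgrounds, function(p) {
      img <- read_pnm(p)
      if (length(dim(img)) != 3) {
        img <- array(rep(img, 3), c(dim(img), 3))
      }
      if (dim(img)[1] < cfg$crop_size[2] || dim(img)[2] < cfg$crop_size[1])
        stop("background ", p, " is smaller than the crop size", call. = FALSE)
      srgb_to_lab(img)
    })
    return(out)
  }
  spec <- if (is.list(backgrounds)) backgrounds else list()
  n <- spec$n %||% 4L
  mean_lab <- spec$mean_lab %||% c(50, 5, 15)
  sd_lab <- spec$sd_lab %||% c(12, 6, 6)
  corr <- spec$corr_length %||% 20
  margin <- 1.1
  lapply(seq_len(n), function(i) {
    synth_background(width = ceiling(cfg$crop_size[1] * margin),
                     height = ceiling(cfg$crop_size[2] * margin),
                     mean_lab = mean_lab, sd_lab = sd_lab,
                     corr_length = corr,
                     seed = derive_seed(seed, paste0("bkg", i)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
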