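# Headless replacement for the human-played visual search game: slide
# construction with the original timing semantics, a simulated observer
# whose detection time depends on the camouflage metrics, survival-time
# fitness, and the generational evolution loop.

#' Simulated observer
#'
#' Stands in for the human player. A conspicuousness score
#' `c = w_mu * |dmu| + w_sd * |dsd| - w_gab * mean(GabRat)` (channel
#' differences normalized by the color-limit ranges) sets the median of a
#' log-normal detection-time distribution, `median = baseline * exp(-c)`,
#' shrunk multiplicatively by accumulated learning (search-image effect) and
#' capped at the slide duration. Higher conspicuousness gives stochastically
#' shorter detection times. Click execution adds a gamma-distributed delay
#' with median about 300 ms.
#'
#' @param baseline baseline median search time, ms (default 9000).
#' @param w_mu,w_sd,w_gab sensitivity weights on the normalized mean
#'   difference, SD difference and GabRat terms.
#' @param noise_sigma log-normal sigma of the detection time (0 = noiseless).
#' @param learning_rate multiplicative per-slide time shrink (0 = off;
#'   0.005 shrinks times by ~0.5% per completed slide).
#' @param lapse probability of missing the target entirely (timeout).
#' @param click_delay_median median move-to-click delay, ms.
#' @param name observer label for logs.
#' @return an object of class `observer_model`.
#' @export
observer_model <- function(baseline = 9000, w_mu = 8, w_sd = 4, w_gab = 2,
                           noise_sigma = 0.35, learning_rate = 0,
                           lapse = 0.02, click_delay_median = 300,
                           name = "sim") {
  stopifnot(baseline > 0, lapse >= 0, lapse <= 1, noise_sigma >= 0)
  structure(list(baseline = baseline, w_mu = w_mu, w_sd = w_sd,
                 w_gab = w_gab, noise_sigma = noise_sigma,
                 learning_rate = learning_rate, lapse = lapse,
                 click_delay_median = click_delay_median, name = name),
            class = "observer_model")
}

#' Build slides: one placed target per background crop
#'
#' Backgrounds are centre-cropped to the configured slide size; targets are
#' assigned in a random display sequence (without replacement), rotated
#' uniformly in 0-360 degrees and placed uniformly at positions keeping the
#' rotated target fully inside the crop.
#'
#' @param targets list of `target_image`s.
#' @param backgrounds list of H x W x 3 CIELAB arrays, each at least the
#'   crop size.
#' @param crop_size integer `c(width, height)` of the slide.
#' @return list of `slide` objects: `lab` (composed slide), `target_mask`,
#'   `target_id`, `x`, `y` (0-based target centre), `rotation` (CCW deg),
#'   `display_order`.
#' @export
build_slides <- function(targets, backgrounds, crop_size = c(1478L, 1130L)) {
  n <- length(targets)
  cw <- crop_size[1]; ch <- crop_size[2]
  order_idx <- sample.int(n)
  bkg_idx <- if (length(backgrounds) >= n) sample.int(length(backgrounds), n)
             else sample(rep_len(seq_along(backgrounds), n))
  slides <- vector("list", n)
  for (k in seq_len(n)) {
    t_i <- order_idx[k]
    tg <- targets[[t_i]]
    bkg <- backgrounds[[bkg_idx[k]]]
    bh <- dim(bkg)[1]; bw <- dim(bkg)[2]
    if (bh < ch || bw < cw)
      stop("background ", bkg_idx[k], " (", bw, "x", bh,
           ") is smaller than the crop size ", cw, "x", ch, call. = FALSE)
    y0 <- (bh - ch) %/% 2L; x0 <- (bw - cw) %/% 2L
    crop <- bkg[y0 + seq_len(ch), x0 + seq_len(cw), , drop = FALSE]

    rot <- runif(1, 0, 360)
    planes <- lapply(1:3, function(chn) tg$lab[, , chn])
    rr <- rotate_raster(planes, tg$alpha, rot)
    th <- nrow(rr$mask); tw <- ncol(rr$mask)
    if (th >= ch || tw >= cw)
      stop("target larger than the slide crop", call. = FALSE)
    ty <- sample.int(ch - th, 1)  # top-left placement, fully inside
    tx <- sample.int(cw - tw, 1)
    mask <- matrix(FALSE, ch, cw)
    mask[ty + seq_len(th) - 1L, tx + seq_len(tw) - 1L] <- rr$mask
    for (chn in 1:3) {
      sub <- crop[ty + seq_len(th) - 1L, tx + seq_len(tw) - 1L, chn]
      sub[rr$mask] <- rr$planes[[chn]][rr$mask]
      crop[ty + seq_len(th) - 1L, tx + seq_len(tw) - 1L, chn] <- sub
    }
    slides[[k]] <- structure(
      list(lab = crop, target_mask = mask, target_id = tg$id,
           target_index = t_i,
           x = tx - 1L + (tw - 1) / 2, y = ty - 1L + (th - 1) / 2,
           rotation = rot, display_order = k, background = bkg_idx[k]),
      class = "camo_slide")
  }
  slides
}

#' Simulate one observation of a slide
#'
#' @param metrics named metric vector from [slide_metrics()].
#' @param observer an [observer_model()].
#' @param limits a [color_limits()] used to normalize the differences.
#' @param duration slide timeout, ms.
#' @param slides_seen number of slides already completed by this observer
#'   (drives the learning shrink).
#' @return list: `response_time`, `capture_time` (ms), `timed_out`.
#' @export
simulate_observation <- function(metrics, observer, limits = color_limits(),
                                 duration = 15000, slides_seen = 0) {
  widths <- c(diff(limits$L), diff(limits$A), diff(limits$B))
  dmu <- mean(c(metrics[["dmuL"]], metrics[["dmuA"]], metrics[["dmuB"]]) / widths)
  dsd <- mean(c(metrics[["dsdL"]], metrics[["dsdA"]], metrics[["dsdB"]]) / widths)
  gab <- mean(c(metrics[["gabL"]], metrics[["gabA"]], metrics[["gabB"]]))
  if (is.na(gab)) gab <- 0  # GabRat not computed (observer weight 0)
  score <- observer$w_mu * dmu + observer$w_sd * dsd - observer$w_gab * gab
  med <- observer$baseline * exp(-score) *
    (1 - observer$learning_rate)^slides_seen
  lapsed <- observer$lapse > 0 && runif(1) < observer$lapse
  if (lapsed) {
    return(list(response_time = duration, capture_time = duration,
                timed_out = TRUE))
  }
  response <- if (observer$noise_sigma > 0)
    rlnorm(1, meanlog = log(med), sdlog = observer$noise_sigma) else med
  response <- max(response, 1)
  if (response >= duration) {
    return(list(response_time = duration, capture_time = duration,
                timed_out = TRUE))
  }
  # gamma(shape 2) has median ~1.678 * scale
  delay <- rgamma(1, shape = 2, scale = observer$click_delay_median / 1.678)
  capture <- min(response + delay, duration)
  list(response_time = response, capture_time = capture, timed_out = FALSE)
}

#' Survival-time fitness from an observation
#'
#' The default hybrid rule uses the response time (first cursor movement)
#' unless capture minus response exceeds the threshold (600 ms), in which
#' case the capture time is used: a long move-to-click gap implies the
#' initial movement was not a true detection. Timeouts return the slide
#' duration.
#'
#' @param obs result of [simulate_observation()].
#' @param method `"hybrid"`, `"response"`, `"capture"` or `"location"`.
#' @param threshold hybrid capture-minus-response threshold, ms.
#' @param duration slide timeout, ms.
#' @return fitness in ms (longer = better camouflage).
#' @export
survival_time <- function(obs, method = c("hybrid", "response", "capture",
                                          "location"),
                          threshold = 600, duration = 15000) {
  method <- match.arg(method)
  if (obs$timed_out) return(duration)
  switch(method,
    hybrid = if (obs$capture_time - obs$response_time > threshold)
      obs$capture_time else obs$response_time,
    response = obs$response_time,
    capture = obs$capture_time,
    # location scoring: a correct side call keeps the response time; the
    # (rare) mis-click scores the full duration. Correctness is resolved by
    # the caller via obs$correct when a click position is simulated.
    location = if (isTRUE(obs$correct) || is.null(obs$correct))
      obs$response_time else duration)
}

# render one genome under the configured phenotype system
render_phenotype <- function(g, cfg, gamut, shape_mask, spec, model, seed) {
  if (cfg$phenotype == "animal")
    render_target(g, shape_mask, spec = spec, limits = cfg$limits,
                  gamut = gamut, seed = seed)
  else
    render_egg(g, shape_mask, spec = spec, model = model, seed = seed)
}

# built-in shape lookup
config_shape_mask <- function(cfg) {
  ts <- cfg$target_size
  if (file.exists(cfg$shape %||% "")) return(read_mask(cfg$shape))
  switch(cfg$shape,
         triangle = triangle_mask(ts[1], ts[2]),
         ellipse = ellipse_mask(ts[1], ts[2]),
         egg = egg_mask(ts[1], ts[2]),
         stop("unknown shape: ", cfg$shape, call. = FALSE))
}

#' Run one generation of the predation game
#'
#' Renders every member of the population plus the configured warm-up
#' targets (randomly generated within the phenotype space, shown first,
#' excluded from the fitness list), builds slides, computes camouflage
#' metrics per slide and simulates the observations.
#'
#' @param pop a `camo_population`.
#' @param backgrounds list of CIELAB background arrays.
#' @param cfg a [run_config()].
#' @param observer an [observer_model()].
#' @param gamut an `rd_gamut` (animal phenotype; built on demand if `NULL`).
#' @param slides_seen observer's running slide count (learning state).
#' @return list: `fitnesses` (aligned with `pop` members), `display_order`,
#'   `metrics` (data frame, warm-ups included and flagged), `slides_seen`.
#' @export
run_generation <- function(pop, backgrounds, cfg, observer,
                           gamut = NULL, slides_seen = 0) {
  shape_mask <- config_shape_mask(cfg)
  spec <- if (cfg$phenotype == "animal") animal_spec(symmetric = cfg$symmetric)
          else egg_spec()
  model <- if (cfg$phenotype == "egg") egg_color_model() else NULL
  if (cfg$phenotype == "animal" && is.null(gamut))
    gamut <- build_rd_gamut(resolution = cfg$gamut_resolution,
                            iterations = cfg$gamut_iterations,
                            seed = cfg$seed)
  targets <- lapply(seq_len(pop$N), function(i)
    render_phenotype(get_genome(pop, i), cfg, gamut, shape_mask, spec, model,
                     cfg$seed))
  # warm-up targets: random genomes, not part of the population
  warm <- lapply(seq_len(cfg$warmups), function(k) {
    g <- genome(runif(length(pop$tags)), pop$tags,
                id = sprintf("warm%03d_%d", pop$generation, k))
    render_phenotype(g, cfg, gamut, shape_mask, spec, model, cfg$seed)
  })
  warm_slides <- if (length(warm))
    build_slides(warm, backgrounds, cfg$crop_size) else list()
  pop_slides <- build_slides(targets, backgrounds, cfg$crop_size)
  compute_gab <- observer$w_gab != 0
  n_all <- length(warm_slides) + length(pop_slides)
  rows <- vector("list", n_all)
  fitnesses <- numeric(pop$N)
  display_order <- integer(pop$N)
  k <- 0L
  for (s in c(warm_slides, pop_slides)) {
    k <- k + 1L
    m <- slide_metrics(s$lab, s$target_mask, factor = cfg$region_factor,
                       compute_gabrat = compute_gab)
    obs <- simulate_observation(m, observer, cfg$limits,
                                duration = cfg$slide_duration,
                                slides_seen = slides_seen)
    slides_seen <- slides_seen + 1
    fit <- survival_time(obs, cfg$fitness_method,
                         threshold = cfg$hybrid_threshold,
                         duration = cfg$slide_duration)
    is_warm <- k <= length(warm_slides)
    if (!is_warm) {
      i <- s$target_index
      fitnesses[i] <- fit
      display_order[i] <- s$display_order + length(warm_slides)
    }
    rows[[k]] <- data.frame(
      generation = pop$generation, id = s$target_id, warmup = is_warm,
      slide = k, x = s$x, y = s$y, rotation = s$rotation,
      dmuL = m[["dmuL"]], dmuA = m[["dmuA"]], dmuB = m[["dmuB"]],
      dsdL = m[["dsdL"]], dsdA = m[["dsdA"]], dsdB = m[["dsdB"]],
      gabL = m[["gabL"]], gabA = m[["gabA"]], gabB = m[["gabB"]],
      response_time = obs$response_time, capture_time = obs$capture_time,
      timed_out = obs$timed_out, fitness = fit)
  }
  list(fitnesses = fitnesses, display_order = display_order,
       metrics = do.call(rbind, rows), slides_seen = slides_seen,
       targets = targets)
}

#' Run a full camouflage evolution experiment
#'
#' Alternates the predation game and the generation turnover for the
#' configured number of generations. Every stochastic draw flows through a
#' single RNG seeded once from the config, so identical (config, seed)
#' pairs reproduce bit-identical runs, chromosome logs included. When
#' `cfg$out_dir` is set, per-generation chromosome logs, the full metrics
#' table and the generation history are written there.
#'
#' @param cfg a [run_config()].
#' @param observers an [observer_model()] or a list of them, cycled per
#'   generation (alternating observers offsets predator learning).
#' @return an object of class `camo_evolution`: list with `history` (one
#'   row per evaluated generation: best/median fitness, diversity, mean
#'   metrics of all and of the top third), `metrics` (all slides), `pop`
#'   (final evaluated population), `cfg`.
#' @export
run_evolution <- function(cfg, observers = observer_model()) {
  if (inherits(observers, "observer_model")) observers <- list(observers)
  set.seed(cfg$seed)
  gamut <- if (cfg$phenotype == "animal")
    build_rd_gamut(resolution = cfg$gamut_resolution,
                   iterations = cfg$gamut_iterations, seed = cfg$seed)
  else NULL
  backgrounds <- load_backgrounds(cfg$backgrounds, cfg, seed = cfg$seed)
  pop <- init_population(cfg$ga, phenotype_tags(cfg$phenotype))
  pop <- rescale_start_colors(pop, cfg$limits)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  history <- list()
  all_metrics <- list()
  n_evals <- cfg$generations + 1L  # initial population is evaluated too
  slides_seen <- 0
  for (t in seq_len(n_evals)) {
    obs <- observers[[(t - 1L) %% length(observers) + 1L]]
    if (length(observers) > 1) slides_seen <- 0  # naive observer each swap
    gen <- run_generation(pop, backgrounds, cfg, obs, gamut, slides_seen)
    slides_seen <- gen$slides_seen
    pop$fitnesses <- gen$fitnesses
    pop$ranks <- rank_population(gen$fitnesses,
                                 reverse = cfg$ga$reverse_ranking,
                                 tie_key = gen$display_order)
    history[[t]] <- generation_summary(pop, gen, cfg)
    all_metrics[[t]] <- gen$metrics
    if (!is.null(out_dir)) {
      write_chromosomes(pop, file.path(out_dir,
                                       sprintf("chromosomes_gen%03d.txt",
                                               pop$generation)))
      if (cfg$write_images) {
        for (tg in gen$targets)
          write_pnm(target_srgb(tg),
                    file.path(out_dir, sprintf("target_gen%03d_%s.pnm",
                                               pop$generation, tg$id)))
      }
    }
    if (t < n_evals) pop <- next_generation(pop, cfg$ga)
  }
  history <- do.call(rbind, history)
  metrics <- do.call(rbind, all_metrics)
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  }
  structure(list(history = history, metrics = metrics, pop = pop, cfg = cfg),
            class = "camo_evolution")
}

phenotype_tags <- function(phenotype) {
  if (phenotype == "animal") animal_tag_layout() else egg_tag_layout()
}

# initial color genes rescaled so starting colors honor narrower start ranges
rescale_start_colors <- function(pop, limits) {
  if (is.null(limits$start)) return(pop)
  main <- list(L = limits$L, A = limits$A, B = limits$B)
  chan_of <- c(lum = "L", a = "A", b = "B")
  tl <- split_tags(pop$tags)
  for (j in seq_along(pop$tags)) {
    if (tl[j, 1] != "col" || !tl[j, 3] %in% names(chan_of)) next
    nm <- chan_of[[tl[j, 3]]]
    st <- limits$start[[nm]]
    if (is.null(st)) next
    r <- main[[nm]]
    lo <- (st[1] - r[1]) / (r[2] - r[1])
    hi <- (st[2] - r[1]) / (r[2] - r[1])
    pop$genes[, j] <- lo + pop$genes[, j] * (hi - lo)
  }
  pop
}

generation_summary <- function(pop, gen, cfg) {
  m <- gen$metrics[!gen$metrics$warmup, , drop = FALSE]
  top <- pop$ids[pop$ranks <= max(1L, round(pop$N / 3))]
  mt <- m[m$id %in% top, , drop = FALSE]
  dmu_cols <- c("dmuL", "dmuA", "dmuB")
  data.frame(generation = pop$generation,
             best_fitness = max(pop$fitnesses),
             median_fitness = stats::median(pop$fitnesses),
             diversity = genetic_diversity(pop),
             mean_dmu = mean(as.matrix(m[, dmu_cols])),
             mean_dsd = mean(as.matrix(m[, c("dsdL", "dsdA", "dsdB")])),
             mean_gab = mean(as.matrix(m[, c("gabL", "gabA", "gabB")])),
             top_dmu = mean(as.matrix(mt[, dmu_cols])),
             timeouts = sum(m$timed_out))
}

#' @export
print.camo_evolution <- function(x, ...) {
  cat("<camo_evolution> ", nrow(x$history), " evaluated generations, N=",
      x$cfg$ga$N, ", phenotype=", x$cfg$phenotype, "\n", sep = "")
  print(utils::head(x$history[, c("generation", "best_fitness",
                                  "median_fitness", "mean_dmu",
                                  "diversity")], 3))
  cat("...\n")
  print(utils::tail(x$history[, c("generation", "best_fitness",
                                  "median_fitness", "mean_dmu",
                                  "diversity")], 3))
  invisible(x)
}

#' Packaged demo configuration
#'
#' The example experiment as a ready-to-run config: 24 triangle targets
#' (150 x 75 px) against synthetic backgrounds, 1478 x 1130 crops, CIELAB
#' limits L 0-100, A -60-60, B -10-70, 15 generations, hybrid survival-time
#' fitness. Scale `scale` < 1 shrinks the geometry proportionally for quick
#' demonstrations.
#'
#' @param seed run seed.
#' @param scale geometry scale factor (1 = full size).
#' @param generations number of generations (default 15).
#' @return a [run_config()].
#' @export
demo_config <- function(seed = 1L, scale = 1, generations = 15L) {
  run_config(ga = ga_config(N = 24L, seed = seed),
             phenotype = "animal",
             limits = color_limits(L = c(0, 100), A = c(-60, 60),
                                   B = c(-10, 70)),
             target_size = c(max(6L, round(150 * scale)),
                             max(3L, round(75 * scale))),
             shape = "triangle",
             crop_size = c(max(32L, round(1478 * scale)),
                           max(32L, round(1130 * scale))),
             generations = generations,
             gamut_resolution = if (scale < 1) 128L else 256L,
             gamut_iterations = if (scale < 1) 2000L else 5000L,
             backgrounds = list(n = 4L, mean_lab = c(50, 5, 15),
                                sd_lab = c(12, 6, 6), corr_length = 20),
             seed = seed)
}
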