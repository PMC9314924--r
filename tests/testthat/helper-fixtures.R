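# Shared fixtures, all generated in code. The small reaction-diffusion gamut
# is built once per session (memoized by the package cache).

test_gamut <- function() {
  build_rd_gamut(resolution = 96L, iterations = 1500L, seed = 42L)
}

# random genome with a given layout
rand_genome <- function(tags, id = "t", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome(runif(length(tags)), tags, id = id)
}

# an evaluated + ranked population with arbitrary fitnesses
ranked_pop <- function(cfg, tags = egg_tag_layout(), seed = 1) {
  set.seed(seed)
  pop <- init_population(cfg, tags)
  pop$fitnesses <- runif(cfg$N, 100, 15000)
  pop$ranks <- rank_population(pop$fitnesses)
  pop
}

# small geometry run config for fast end-to-end tests
mini_config <- function(seed = 1L, N = 6L, generations = 2L, ...) {
  run_config(ga = ga_config(N = N, survive_fraction = 1 / 3,
                            lifeline_count = min(3L, floor(N / 3)),
                            seed = seed),
             target_size = c(24L, 12L), crop_size = c(140L, 140L),
             generations = generations,
             gamut_resolution = 96L, gamut_iterations = 1500L,
             backgrounds = list(n = 2L, corr_length = 10), seed = seed, ...)
}

noiseless_observer <- function(w_mu = 8, w_sd = 0, w_gab = 0) {
  observer_model(w_mu = w_mu, w_sd = w_sd, w_gab = w_gab,
                 noise_sigma = 0, lapse = 0, learning_rate = 0)
}
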