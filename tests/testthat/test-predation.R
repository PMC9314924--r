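# Slide construction, simulated observations, survival-time fitness and the
# generational loop.

test_that("slides: one per target, centre crop, full containment", {
  gam <- test_gamut()
  tags <- animal_tag_layout()
  set.seed(60)
  targets <- lapply(1:5, function(i)
    render_target(rand_genome(tags, paste0("t", i)), triangle_mask(20, 10),
                  gamut = gam, seed = 1))
  # background with coordinate-encoding planes to verify the centre crop
  bg <- array(0, c(120, 140, 3))
  bg[, , 1] <- matrix(seq_len(120), 120, 140)          # L = row index
  bg[, , 2] <- matrix(seq_len(140), 120, 140, byrow = TRUE)
  slides <- build_slides(targets, list(bg), crop_size = c(100L, 80L))
  expect_length(slides, 5)
  expect_setequal(vapply(slides, `[[`, "", "target_id"), paste0("t", 1:5))
  s <- slides[[1]]
  expect_identical(dim(s$lab)[1:2], c(80L, 100L))
  # centre crop: top-left pixel of the crop is bg[21, 21] (offsets 20, 20)
  off <- unname(which(!s$target_mask, arr.ind = TRUE)[1, ])
  expect_equal(s$lab[off[1], off[2], 1], 20 + off[1])
  expect_equal(s$lab[off[1], off[2], 2], 20 + off[2])
  # rotated targets never touch the crop border (100 placements)
  set.seed(61)
  for (rep in 1:20) {
    sl <- build_slides(targets, list(bg), crop_size = c(100L, 80L))
    for (s in sl) {
      expect_false(any(s$target_mask[1, ]) || any(s$target_mask[80, ]) ||
                   any(s$target_mask[, 1]) || any(s$target_mask[, 100]))
    }
  }
  # background smaller than the crop is rejected by name
  expect_error(build_slides(targets, list(bg), crop_size = c(200L, 80L)),
               "smaller than the crop")
})

test_that("survival time implements the hybrid 600 ms rule", {
  mk <- function(r, c, to = FALSE) list(response_time = r, capture_time = c,
                                        timed_out = to)
  expect_equal(survival_time(mk(2000, 2400)), 2000)   # gap 400 <= 600
  expect_equal(survival_time(mk(2000, 2601)), 2601)   # gap just above
  expect_equal(survival_time(mk(2000, 2600)), 2000)   # boundary: not >
  expect_equal(survival_time(mk(1, 1, TRUE)), 15000)  # timeout
  expect_equal(survival_time(mk(2000, 2601), method = "response"), 2000)
  expect_equal(survival_time(mk(2000, 2601), method = "capture"), 2601)
  expect_error(survival_time(mk(1, 2), method = "nonsense"))
})

test_that("observer simulation: lapse, determinism, monotonicity", {
  m_easy <- c(dmuL = 40, dmuA = 20, dmuB = 20, dsdL = 5, dsdA = 5, dsdB = 5,
              gabL = NA, gabA = NA, gabB = NA)
  m_hard <- c(dmuL = 2, dmuA = 1, dmuB = 1, dsdL = 1, dsdA = 1, dsdB = 1,
              gabL = NA, gabA = NA, gabB = NA)
  lapser <- observer_model(lapse = 1)
  o <- simulate_observation(m_easy, lapser)
  expect_true(o$timed_out)
  expect_equal(o$capture_time, 15000)
  obs <- observer_model(noise_sigma = 0.3, lapse = 0)
  set.seed(62); o1 <- simulate_observation(m_easy, obs)
  set.seed(62); o2 <- simulate_observation(m_easy, obs)
  expect_identical(o1, o2)
  expect_lte(o1$response_time, o1$capture_time)
  # more conspicuous targets are found stochastically faster (1e3 draws)
  set.seed(63)
  te <- replicate(1e3, simulate_observation(m_easy, obs)$response_time)
  th <- replicate(1e3, simulate_observation(m_hard, obs)$response_time)
  expect_lt(median(te), median(th))
  # noiseless observer is deterministic without seeding
  nl <- noiseless_observer()
  expect_equal(simulate_observation(m_easy, nl)$response_time,
               simulate_observation(m_easy, nl)$response_time)
})

test_that("one generation: warm-ups excluded, counts and determinism", {
  cfg <- mini_config(seed = 3L, N = 6L)
  set.seed(64)
  backgrounds <- load_backgrounds(cfg$backgrounds, cfg, seed = 3L)
  pop <- init_population(cfg$ga, animal_tag_layout())
  gam <- test_gamut()
  set.seed(65)
  gen <- run_generation(pop, backgrounds, cfg, noiseless_observer(),
                        gamut = gam)
  expect_equal(nrow(gen$metrics), 8L)          # 6 slides + 2 warm-ups
  expect_equal(sum(gen$metrics$warmup), 2L)
  expect_length(gen$fitnesses, 6L)
  expect_true(all(gen$fitnesses > 0 & gen$fitnesses <= cfg$slide_duration))
  # warm-ups occupy the first display slots; members follow
  expect_setequal(gen$display_order, 3:8)
  set.seed(65)
  gen2 <- run_generation(pop, backgrounds, cfg, noiseless_observer(),
                         gamut = gam)
  expect_identical(gen$metrics, gen2$metrics)
})

test_that("zero-generation runs evaluate the initial population once", {
  cfg <- mini_config(seed = 4L, N = 6L, generations = 0L)
  ev <- run_evolution(cfg, noiseless_observer())
  expect_equal(nrow(ev$history), 1L)
  expect_equal(ev$history$generation, 0)
  expect_equal(ev$pop$generation, 0L)
  expect_false(is.null(ev$pop$fitnesses))
})

test_that("evolution runs are reproducible and write their artifacts", {
  out <- file.path(tempdir(), "camosim-run-test")
  unlink(out, recursive = TRUE)
  cfg <- mini_config(seed = 5L, N = 6L, generations = 2L, out_dir = out)
  ev1 <- run_evolution(cfg, noiseless_observer())
  ev2 <- run_evolution(cfg, noiseless_observer())
  expect_identical(ev1$history, ev2$history)
  expect_identical(ev1$pop$genes, ev2$pop$genes)
  expect_true(file.exists(file.path(out, "chromosomes_gen000.txt")))
  expect_true(file.exists(file.path(out, "chromosomes_gen002.txt")))
  expect_true(file.exists(file.path(out, "metrics.csv")))
  expect_true(file.exists(file.path(out, "history.csv")))
  # chromosome log round-trips to the same ranked population
  back <- read_chromosomes(file.path(out, "chromosomes_gen002.txt"),
                           expected_tags = animal_tag_layout(),
                           generation = 2L)
  expect_equal(back$genes, round(ev1$pop$genes * 1e6) / 1e6)
  expect_identical(back$ranks, ev1$pop$ranks)
  unlink(out, recursive = TRUE)
})

test_that("observer learning shrinks detection times across slides", {
  m <- c(dmuL = 10, dmuA = 5, dmuB = 5, dsdL = 2, dsdA = 2, dsdB = 2,
         gabL = NA, gabA = NA, gabB = NA)
  lrn <- observer_model(noise_sigma = 0, lapse = 0, learning_rate = 0.01)
  t0 <- simulate_observation(m, lrn, slides_seen = 0)$response_time
  t50 <- simulate_observation(m, lrn, slides_seen = 50)$response_time
  expect_lt(t50, t0)
})
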