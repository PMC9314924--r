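# The decimal-gene genetic algorithm: initialization, ranking, selection,
# crossover, mutation, lifeline rescue and generation turnover. All stochastic
# draws flow through R's global RNG; seed once per run (see run_evolution).

#' Genetic algorithm configuration
#'
#' Defaults realize the standard turnover: population 24, bottom two thirds
#' deleted, survivors breed twice, top three protected by lifelines.
#'
#' @param N population size (default 24).
#' @param survive_fraction fraction of the ranked population retained to
#'   breed (default 1/3).
#' @param lifeline_count number of top-ranked individuals protected from
#'   deletion in the following generation (default 3).
#' @param base_mutation_rate per-gene point-mutation probability (default 0.1).
#' @param mutation_step scale of the point-mutation perturbation; magnitude is
#'   `step * K` with `K ~ Poisson(1)`, sign equiprobable (default 0.05).
#' @param structural_rates named probabilities for the `swap`, `scramble` and
#'   `duplication` tag-aware mutations, per offspring per event (default 0.02
#'   each; kept low).
#' @param adaptive logical; scale mutation rates by population diversity and
#'   per-individual relative unfitness.
#' @param c_d,c_f adaptive coefficients on diversity deficit and relative
#'   unfitness (defaults 1 and 0.5).
#' @param rate_min,rate_max clamp bounds for adaptive rates (0.01, 0.5).
#' @param reverse_ranking logical; rank 1 = shortest survival time, selecting
#'   for conspicuousness instead of camouflage.
#' @param seed RNG seed for the run.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(N = 24L, survive_fraction = 1 / 3, lifeline_count = 3L,
                      base_mutation_rate = 0.1, mutation_step = 0.05,
                      structural_rates = c(swap = 0.02, scramble = 0.02,
                                           duplication = 0.02),
                      adaptive = FALSE, c_d = 1, c_f = 0.5,
                      rate_min = 0.01, rate_max = 0.5,
                      reverse_ranking = FALSE, seed = 1L) {
  N <- as.integer(N)
  if (is.na(N) || N < 2) stop("population size N must be >= 2", call. = FALSE)
  if (survive_fraction <= 0 || survive_fraction >= 1)
    stop("survive_fraction must be in (0, 1)", call. = FALSE)
  n_breed <- round(N * survive_fraction)
  if (lifeline_count > floor(N * survive_fraction))
    stop("lifeline_count must be <= floor(N * survive_fraction)", call. = FALSE)
  probs <- c(base_mutation_rate, mutation_step, structural_rates,
             rate_min, rate_max)
  if (any(probs < 0 | probs > 1))
    stop("all rates and probabilities must be in [0, 1]", call. = FALSE)
  structure(list(N = N, survive_fraction = survive_fraction,
                 lifeline_count = as.integer(lifeline_count),
                 base_mutation_rate = base_mutation_rate,
                 mutation_step = mutation_step,
                 structural_rates = structural_rates,
                 adaptive = isTRUE(adaptive), c_d = c_d, c_f = c_f,
                 rate_min = rate_min, rate_max = rate_max,
                 reverse_ranking = isTRUE(reverse_ranking),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Initialize a population
#'
#' The default `"overdispersed"` mode gives each gene position the N values
#' `k/(N+1)`, `k = 1..N`, independently permuted across members, so the
#' initial genotypic space is as wide as possible for the population size
#' (evenly spaced with interval `1/(N+1)`, no boundary values). Alternatives:
#' `"random"` (uniform), `"gaussian"` (mean 0.5, sd 0.15, reflected into
#' `[0,1]`) and `"custom"` (explicit matrix).
#'
#' @param cfg a [ga_config()].
#' @param tag_layout character vector of three-level gene tags.
#' @param mode one of `"overdispersed"`, `"random"`, `"gaussian"`, `"custom"`.
#' @param custom N x G matrix in `[0,1]` for `mode = "custom"`.
#' @return an unevaluated `camo_population` at generation 0.
#' @export
init_population <- function(cfg, tag_layout,
                            mode = c("overdispersed", "random", "gaussian",
                                     "custom"),
                            custom = NULL) {
  mode <- match.arg(mode)
  if (length(tag_layout) < 1) stop("tag_layout must be non-empty", call. = FALSE)
  N <- cfg$N; G <- length(tag_layout)
  genes <- switch(mode,
    overdispersed = {
      g <- matrix(0, N, G)
      for (j in seq_len(G)) g[, j] <- sample.int(N) / (N + 1)
      g
    },
    random = matrix(runif(N * G), N, G),
    gaussian = {
      g <- matrix(rnorm(N * G, 0.5, 0.15), N, G)
      matrix(reflect01(g), N, G)
    },
    custom = {
      if (is.null(custom) || !is.matrix(custom) ||
          nrow(custom) != N || ncol(custom) != G)
        stop("custom matrix must be ", N, " x ", G, call. = FALSE)
      if (any(!is.finite(custom)) || any(custom < 0 | custom > 1))
        stop("custom gene values must be in [0, 1]", call. = FALSE)
      custom
    })
  population(genes, tag_layout, generation = 0L)
}

#' Rank fitness values
#'
#' Rank 1 is the fittest: the longest survival time, or the shortest when
#' `reverse = TRUE` (conspicuousness mode). Ties are broken deterministically
#' by display order, the member shown later in the session winning (a target
#' found equally fast later beat a fresher observer).
#'
#' @param fitnesses numeric vector, one per member; must be finite.
#' @param reverse logical; rank 1 = smallest fitness when `TRUE`.
#' @param tie_key integer vector of the members' slide display order.
#' @return integer rank permutation aligned with `fitnesses`.
#' @export
rank_population <- function(fitnesses, reverse = FALSE,
                            tie_key = seq_along(fitnesses)) {
  if (any(!is.finite(fitnesses)))
    stop("fitness values must be finite", call. = FALSE)
  if (length(tie_key) != length(fitnesses))
    stop("tie_key must match fitnesses in length", call. = FALSE)
  key <- if (reverse) fitnesses else -fitnesses
  ord <- order(key, -tie_key)   # later display order wins ties
  ranks <- integer(length(fitnesses))
  ranks[ord] <- seq_along(ord)
  ranks
}

#' Split a ranked population into breeders and deleted members
#'
#' The top `round(N * survive_fraction)` ranked members survive and breed;
#' the rest die (default: bottom two thirds).
#'
#' @param pop a ranked `camo_population`.
#' @param cfg a [ga_config()].
#' @return list with integer member indices `breeders` and `deleted`.
#' @export
select_survivors <- function(pop, cfg) {
  if (is.null(pop$ranks)) stop("population must be ranked", call. = FALSE)
  n_b <- round(pop$N * cfg$survive_fraction)
  list(breeders = which(pop$ranks <= n_b),
       deleted = which(pop$ranks > n_b))
}

#' Plan lifeline rescues for a generation turnover
#'
#' Any member that held a lifeline (top `lifeline_count` ranks of the
#' previous generation) but now falls in the deletion pool is reinstated
#' unmutated, each rescue consuming one planned offspring slot; survivor
#' rankings are not re-adjusted.
#'
#' @param prev_elites character ids of the previous generation's elites.
#' @param pop the current, ranked `camo_population`.
#' @param cfg a [ga_config()].
#' @return list: `rescued` (ids to reinstate, worst-ranked last) and
#'   `n_offspring` (offspring slots remaining).
#' @export
apply_lifeline <- function(prev_elites, pop, cfg) {
  sel <- select_survivors(pop, cfg)
  planned <- pop$N - length(sel$breeders)
  del_ids <- pop$ids[sel$deleted]
  rescued <- prev_elites[prev_elites %in% del_ids]
  # deterministic order: better current rank reinstated first
  if (length(rescued)) {
    r <- pop$ranks[match(rescued, pop$ids)]
    rescued <- rescued[order(r)]
  }
  stopifnot(length(rescued) <= planned)  # guaranteed: lifeline_count <= breeders
  list(rescued = rescued, n_offspring = planned - length(rescued))
}

#' Incomplete (weighted-average) crossover
#'
#' Each offspring gene is `w * a + (1 - w) * b` with an independent uniform
#' weight per position, so offspring explore the full interval between the
#' parental values instead of copying either parent.
#'
#' @param parent_a,parent_b `camo_genome`s sharing one tag layout.
#' @param id id for the offspring genome.
#' @return a `camo_genome`.
#' @export
crossover <- function(parent_a, parent_b, id = "offspring") {
  if (!identical(parent_a$tags, parent_b$tags))
    stop("parents must share the same tag layout", call. = FALSE)
  w <- runif(length(parent_a$genes))
  genome(w * parent_a$genes + (1 - w) * parent_b$genes, parent_a$tags, id = id)
}

# reflect out-of-range values back into [0,1] (fold-back, repeated as needed)
reflect01 <- function(x) {
  x <- abs(x) %% 2
  ifelse(x > 1, 2 - x, x)
}

#' Point mutation with Poisson-scaled noise
#'
#' Each gene mutates independently with probability `rate`; the perturbation
#' magnitude is `step * K` with `K ~ Poisson(1)` and an equiprobable sign.
#' Out-of-range results are reflected back into `[0, 1]` rather than clipped,
#' avoiding probability mass piling up at the bounds.
#'
#' @param g a `camo_genome`.
#' @param rate per-gene mutation probability in `[0, 1]`.
#' @param step perturbation scale in `[0, 1]`.
#' @return mutated `camo_genome`.
#' @export
mutate_point <- function(g, rate, step) {
  stopifnot(rate >= 0, rate <= 1, step >= 0, step <= 1)
  if (rate == 0) return(g)
  n <- length(g$genes)
  hit <- runif(n) < rate
  if (!any(hit)) return(g)
  k <- rpois(sum(hit), 1)
  sgn <- sample(c(-1, 1), sum(hit), replace = TRUE)
  genes <- g$genes
  genes[hit] <- reflect01(genes[hit] + sgn * step * k)
  genome(genes, g$tags, id = g$id, lifeline = g$lifeline)
}

# deterministic structural primitives (exposed for testing) ------------------

#' Structural mutation primitives
#'
#' `swap_genes` exchanges the values of two tag-equivalent genes;
#' `scramble_genes` permutes values within one equivalence set;
#' `duplicate_gene` sets `target = w * source + (1 - w) * target` (weighted
#' duplication, preserving some of the target's identity).
#'
#' @param g a `camo_genome`.
#' @param i,j,from,to gene indices within one tag-equivalence class.
#' @param idx index vector of an equivalence class.
#' @param perm permutation of `seq_along(idx)`.
#' @param w duplication weight in `[0, 1]`.
#' @return mutated `camo_genome`.
#' @name structural-primitives
#' @export
swap_genes <- function(g, i, j) {
  genes <- g$genes
  genes[c(i, j)] <- genes[c(j, i)]
  genome(genes, g$tags, id = g$id, lifeline = g$lifeline)
}

#' @rdname structural-primitives
#' @export
scramble_genes <- function(g, idx, perm = sample(length(idx))) {
  genes <- g$genes
  genes[idx] <- genes[idx][perm]
  genome(genes, g$tags, id = g$id, lifeline = g$lifeline)
}

#' @rdname structural-primitives
#' @export
duplicate_gene <- function(g, from, to, w = runif(1)) {
  genes <- g$genes
  genes[to] <- w * genes[from] + (1 - w) * genes[to]
  genome(genes, g$tags, id = g$id, lifeline = g$lifeline)
}

#' Tag-aware structural mutation
#'
#' With the configured (low) per-event probabilities, applies a swap, a
#' scramble and/or a weighted duplication, each acting within one randomly
#' chosen tag-equivalence class (genes sharing group and channel labels), so
#' values only ever move between genes with the same phenotypic meaning.
#'
#' @param g a `camo_genome`.
#' @param cfg a [ga_config()] (uses `structural_rates`).
#' @return mutated `camo_genome`; layouts with no equivalent pairs return the
#'   genome unchanged with a one-time warning.
#' @export
mutate_structural <- function(g, cfg) {
  cls <- tag_equivalence_classes(g$tags)
  rates <- cfg$structural_rates
  if (!length(cls)) {
    if (any(rates > 0) && runif(1) < max(rates))
      warning("structural mutation requested but tag layout has no ",
              "equivalent gene pairs; no-op", call. = FALSE)
    return(g)
  }
  pick <- function() cls[[sample.int(length(cls), 1)]]
  if (runif(1) < rates[["swap"]]) {
    idx <- sample(pick(), 2)
    g <- swap_genes(g, idx[1], idx[2])
  }
  if (runif(1) < rates[["scramble"]]) {
    idx <- pick()
    g <- scramble_genes(g, idx)
  }
  if (runif(1) < rates[["duplication"]]) {
    idx <- sample(pick(), 2)
    g <- duplicate_gene(g, idx[1], idx[2])
  }
  g
}

#' Adaptive per-individual mutation rates
#'
#' `rate_i = clamp(base * (1 + c_d * (1 - D / D0)) * (1 + c_f * u_i),
#' rate_min, rate_max)` where `D` is the population's genetic diversity,
#' `D0 = 1/3` is the closed-form diversity of an overdispersed population
#' (any size), and `u_i = (rank_i - 1) / (N - 1)` is relative unfitness, so
#' fitter individuals receive lower rates and diversity loss raises rates.
#' With `adaptive = FALSE` every individual receives the base rate.
#'
#' @param pop an evaluated, ranked `camo_population`.
#' @param cfg a [ga_config()].
#' @return numeric vector of per-member rates.
#' @export
adaptive_rate <- function(pop, cfg) {
  if (!cfg$adaptive) return(rep(cfg$base_mutation_rate, pop$N))
  if (is.null(pop$ranks)) stop("population must be ranked", call. = FALSE)
  D <- genetic_diversity(pop)
  D0 <- 1 / 3
  u <- (pop$ranks - 1) / (pop$N - 1)
  r <- cfg$base_mutation_rate * (1 + cfg$c_d * (1 - D / D0)) * (1 + cfg$c_f * u)
  clamp(r, cfg$rate_min, cfg$rate_max)
}

# one round of random pairing: every breeder produces one offspring; an odd
# last breeder draws a random second partner
pair_offspring_round <- function(pop, breeders, rates, cfg, id_prefix) {
  perm <- if (length(breeders) > 1) sample(breeders) else breeders
  n <- length(perm)
  out <- vector("list", n)
  make_child <- function(a, b, k) {
    child <- crossover(get_genome(pop, a), get_genome(pop, b),
                       id = paste0(id_prefix, "_", k))
    child <- mutate_point(child, (rates[a] + rates[b]) / 2, cfg$mutation_step)
    mutate_structural(child, cfg)
  }
  k <- 0L
  i <- 1L
  while (i + 1L <= n) {
    a <- perm[i]; b <- perm[i + 1L]
    out[[k + 1L]] <- make_child(a, b, k + 1L)
    out[[k + 2L]] <- make_child(b, a, k + 2L)
    k <- k + 2L; i <- i + 2L
  }
  if (i == n) {  # odd breeder count: random second partner
    a <- perm[n]
    b <- if (n > 1) sample(perm[-n], 1) else a
    out[[k + 1L]] <- make_child(a, b, k + 1L)
    k <- k + 1L
  }
  out[seq_len(k)]
}

#' Generation turnover
#'
#' Survivors (the ranked top fraction) are carried over with genes unaltered.
#' Breeders mate in two rounds of fresh random pairing, each breeder
#' producing one offspring per round; offspring undergo incomplete crossover,
#' point mutation and structural mutation. Previous-generation elites caught
#' in the deletion pool are reinstated unmutated in place of offspring
#' (lifeline rescue). The generation counter is incremented and fitness
#' cleared: every member, survivors included, is re-evaluated next round.
#'
#' @param pop an evaluated, ranked `camo_population`.
#' @param cfg a [ga_config()].
#' @return the next `camo_population`.
#' @export
next_generation <- function(pop, cfg) {
  if (is.null(pop$ranks)) stop("population must be ranked", call. = FALSE)
  sel <- select_survivors(pop, cfg)
  plan <- apply_lifeline(pop$prev_elites, pop, cfg)
  rates <- adaptive_rate(pop, cfg)
  gen <- pop$generation + 1L
  # survivors in rank order
  surv_idx <- sel$breeders[order(pop$ranks[sel$breeders])]

  offspring <- list()
  round_i <- 0L
  while (length(offspring) < plan$n_offspring) {
    round_i <- round_i + 1L
    offspring <- c(offspring,
                   pair_offspring_round(pop, sel$breeders, rates, cfg,
                                        sprintf("g%03d_r%d", gen, round_i)))
  }
  offspring <- offspring[seq_len(plan$n_offspring)]

  rescued_idx <- match(plan$rescued, pop$ids)
  new_ids <- c(pop$ids[surv_idx],
               vapply(offspring, `[[`, "", "id"),
               pop$ids[rescued_idx])
  off_genes <- if (length(offspring))
    do.call(rbind, lapply(offspring, `[[`, "genes")) else NULL
  new_genes <- rbind(pop$genes[surv_idx, , drop = FALSE],
                     off_genes,
                     pop$genes[rescued_idx, , drop = FALSE])
  elites <- pop$ids[order(pop$ranks)][seq_len(cfg$lifeline_count)]
  population(new_genes, pop$tags, generation = gen, ids = new_ids,
             lifeline = new_ids %in% elites, prev_elites = elites)
}
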