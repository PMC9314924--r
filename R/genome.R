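# Genomes and populations. A population stores its genomes as an N x G
# matrix (one row per member) for speed; individual genomes are exposed as
# lists with class "camo_genome".

#' Construct a genome
#'
#' A genome is a fixed-length vector of decimal genes in `[0, 1]`, each
#' carrying a three-level hierarchical tag of the form
#' `"<group>_<subgroup>_<channel>"` (e.g. `"col_mac_lum"`).
#'
#' @param genes numeric vector in `[0, 1]`.
#' @param tags character vector of tag labels, same length as `genes`.
#' @param id unique identifier string.
#' @param lifeline logical; whether the genome currently holds an elitist
#'   lifeline.
#' @return an object of class `camo_genome`.
#' @export
genome <- function(genes, tags, id = "g", lifeline = FALSE) {
  genes <- as.numeric(genes)
  if (length(genes) != length(tags))
    stop("genes and tags must have equal length", call. = FALSE)
  if (any(!is.finite(genes)) || any(genes < 0 | genes > 1))
    stop("gene values must be finite and in [0, 1]", call. = FALSE)
  structure(list(genes = genes, tags = as.character(tags), id = id,
                 lifeline = isTRUE(lifeline)),
            class = "camo_genome")
}

#' @export
print.camo_genome <- function(x, ...) {
  cat("<camo_genome> id=", x$id, " G=", length(x$genes),
      if (x$lifeline) " [lifeline]" else "", "\n", sep = "")
  invisible(x)
}

# split "grp_sub_chan" tags into a 3-column matrix
split_tags <- function(tags) {
  parts <- strsplit(tags, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("tag labels must have exactly three '_'-separated levels; offending: ",
         tags[which(bad)[1]], call. = FALSE)
  do.call(rbind, parts)
}

#' Tag-equivalence classes of a gene layout
#'
#' Genes are structurally equivalent when they share the same channel
#' (level 3) and agree on either the group (level 1) or the subgroup
#' (level 2): `col_mac_lum` and `col_bkg_lum` are equivalent (same group and
#' channel, maculation vs background color), as are `mca_win_x` and
#' `mcb_win_x` (same subgroup and channel under two maculation layers).
#' Classes are the connected components of that relation. Swap, scramble and
#' duplication mutations only ever act within one equivalence class, so a
#' value copied between genes keeps its phenotypic meaning.
#'
#' @param tags character vector of three-level tag labels.
#' @return list of integer index vectors, only classes of size >= 2.
#' @export
tag_equivalence_classes <- function(tags) {
  tl <- split_tags(tags)
  n <- length(tags)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  # union genes sharing a key (union-find over the two key families)
  for (key in list(paste(tl[, 1], tl[, 3]), paste(tl[, 2], tl[, 3]))) {
    for (grp in split(seq_len(n), key)) {
      if (length(grp) < 2) next
      r <- find(grp[1])
      for (i in grp[-1]) parent[find(i)] <- r
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  cls <- split(seq_len(n), roots)
  unname(cls[vapply(cls, length, 1L) >= 2L])
}

#' Construct a population
#'
#' @param genes N x G numeric matrix in `[0, 1]`, one member per row.
#' @param tags character vector of G tag labels (shared by all members).
#' @param generation non-negative generation index.
#' @param ids character vector of N unique member ids (generated if `NULL`).
#' @param fitnesses optional numeric vector of N fitness values.
#' @param ranks optional integer permutation of `1..N` (1 = fittest).
#' @param lifeline logical vector of N lifeline flags.
#' @param prev_elites character vector of member ids holding lifelines from
#'   the previous generation.
#' @return an object of class `camo_population`.
#' @export
population <- function(genes, tags, generation = 0L, ids = NULL,
                       fitnesses = NULL, ranks = NULL,
                       lifeline = rep(FALSE, nrow(genes)),
                       prev_elites = character(0)) {
  genes <- as.matrix(genes)
  N <- nrow(genes)
  if (ncol(genes) != length(tags))
    stop("tag layout length must equal the gene count", call. = FALSE)
  if (any(!is.finite(genes)) || any(genes < 0 | genes > 1))
    stop("gene values must be finite and in [0, 1]", call. = FALSE)
  if (is.null(ids))
    ids <- sprintf("g%03d_%03d", generation, seq_len(N))
  if (anyDuplicated(ids)) stop("member ids must be unique", call. = FALSE)
  if (!is.null(ranks)) {
    if (!setequal(ranks, seq_len(N)))
      stop("ranks must be a permutation of 1..N", call. = FALSE)
    ranks <- as.integer(ranks)
  }
  structure(list(genes = genes, tags = as.character(tags),
                 generation = as.integer(generation), N = N, ids = ids,
                 fitnesses = fitnesses, ranks = ranks,
                 lifeline = lifeline, prev_elites = prev_elites),
            class = "camo_population")
}

#' @export
print.camo_population <- function(x, ...) {
  cat("<camo_population> N=", x$N, " G=", ncol(x$genes),
      " generation=", x$generation,
      if (is.null(x$fitnesses)) " (unevaluated)" else " (evaluated)",
      "\n", sep = "")
  invisible(x)
}

#' Extract one member of a population as a genome
#' @param pop a `camo_population`.
#' @param i member index.
#' @return a `camo_genome`.
#' @export
get_genome <- function(pop, i) {
  genome(pop$genes[i, ], pop$tags, id = pop$ids[i],
         lifeline = isTRUE(pop$lifeline[i]))
}

#' Genetic diversity of a population
#'
#' Mean over gene positions of the mean pairwise absolute difference between
#' members; lies in `[0, 1]`. An overdispersed initial population has
#' diversity exactly 1/3 at every size (the closed form used as the adaptive
#' mutation reference level).
#'
#' @param pop a `camo_population` with at least two members.
#' @return a scalar in `[0, 1]`.
#' @export
genetic_diversity <- function(pop) {
  if (pop$N < 2) stop("diversity requires at least two members", call. = FALSE)
  g <- pop$genes
  N <- nrow(g)
  per_gene <- vapply(seq_len(ncol(g)), function(j) {
    v <- sort(g[, j])
    # mean pairwise |difference| via the order-statistics identity:
    # sum_{i<j} (v_j - v_i) = sum_k (2k - N - 1) v_(k)
    sum((2 * seq_len(N) - N - 1) * v) / choose(N, 2)
  }, numeric(1))
  mean(per_gene)
}

#' Default gene layout for animal phenotypes
#'
#' Three-level tags: pattern-window genes (`pat_win_*`), pattern modifiers
#' (`pat_mod_*`: scale, stripe stretch, binarization threshold), gradient
#' shading (`pat_shd_*`), speckling (`spk_noi_*`), edge enhancement
#' (`edg_lgt_*` / `edg_drk_*`: intensity, expansion, sigma) and CIELAB
#' coloration (`col_bkg_*` / `col_mac_*`).
#'
#' @return character vector of tag labels.
#' @export
animal_tag_layout <- function() {
  c("pat_win_x", "pat_win_y", "pat_win_wid", "pat_win_hei",
    "pat_mod_scale", "pat_mod_stretch", "pat_mod_thresh",
    "pat_shd_angle", "pat_shd_strength",
    "spk_noi_density", "spk_noi_size",
    "edg_lgt_int", "edg_lgt_exp", "edg_lgt_sig",
    "edg_drk_int", "edg_drk_exp", "edg_drk_sig",
    "col_bkg_lum", "col_bkg_a", "col_bkg_b",
    "col_mac_lum", "col_mac_a", "col_mac_b")
}

#' Default gene layout for egg phenotypes
#'
#' Two maculation layers (`mca_*`, `mcb_*`: noise window, scale, shading,
#' threshold, deposition weight; layer b additionally random-walk step count
#' and length), pigment genes (`col_pig_dep`: base deposition,
#' `col_pig_ratio`: biliverdin:protoporphyrin mixture) and a global exposure
#' shift (`col_exp_shift`).
#'
#' @return character vector of tag labels.
#' @export
egg_tag_layout <- function() {
  c("mca_win_x", "mca_win_y", "mca_mod_scale", "mca_shd_strength",
    "mca_mod_thresh", "mca_pig_weight",
    "mcb_win_x", "mcb_win_y", "mcb_mod_scale", "mcb_shd_strength",
    "mcb_mod_thresh", "mcb_pig_weight",
    "mcb_wlk_steps", "mcb_wlk_length",
    "col_pig_dep", "col_pig_ratio", "col_exp_shift")
}
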