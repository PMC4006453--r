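# Deterministic generators for planted-module functional networks,
# module-specific binary profiles, toy ontologies and multi-species
# networks with orthology clusters. They emulate the structure the method
# assumes — per-species networks that are mutually disconnected blocks,
# joined only by orthology cliques, with annotations available in only some
# species — so every stage of the pipeline can be exercised without any
# external download. A single integer master seed fixes all output;
# sub-generators derive their streams from fixed offsets of it, so adding a
# generator never perturbs the others.

seed_offset <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Generate a planted-partition weighted graph
#'
#' Vertices are split into modules; each intra-module pair is joined with
#' probability `p_in` (weight uniform on `w_in`), each inter-module pair
#' with probability `p_out` (weight uniform on `w_out`). Defaults give a
#' strongly modular network in which a vertex's direct neighbours are
#' predominantly its module mates.
#'
#' @param n_nodes total number of vertices (default 120).
#' @param n_modules number of planted modules (default 4, equal sizes as
#'   far as rounding allows).
#' @param p_in intra-module edge probability (default 0.25).
#' @param p_out inter-module edge probability (default 0.02);
#'   `0 <= p_out < p_in <= 1` is required.
#' @param w_in,w_out weight ranges, uniform: intra `[0.5, 1]`,
#'   inter `[0.05, 0.3]`.
#' @param seed integer seed; fixes the output completely.
#' @param prefix accession prefix.
#' @return list with `graph` (a [weighted_graph()]) and `modules`
#'   (integer module label per vertex, 1-based).
#' @export
gen_planted_partition <- function(n_nodes = 120L, n_modules = 4L,
                                  p_in = 0.25, p_out = 0.02,
                                  w_in = c(0.5, 1), w_out = c(0.05, 0.3),
                                  seed = 42L, prefix = "P") {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1")
  modules <- rep(seq_len(n_modules), length.out = n_nodes)
  modules <- sort(modules)
  acc <- sprintf("%s%04d", prefix, seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2L)
  same <- modules[pairs[1L, ]] == modules[pairs[2L, ]]
  with_seed(seed_offset(seed, 0L), {
    prob <- ifelse(same, p_in, p_out)
    present <- stats::runif(ncol(pairs)) < prob
    lo <- ifelse(same[present], w_in[1L], w_out[1L])
    hi <- ifelse(same[present], w_in[2L], w_out[2L])
    w <- stats::runif(sum(present), lo, hi)
  })
  edges <- data.frame(src = pairs[1L, present] - 1L,
                      dst = pairs[2L, present] - 1L,
                      weight = w)
  list(graph = weighted_graph(edges, acc), modules = modules)
}

#' Generate module-specific binary profiles
#'
#' Each module owns a block of `n_features` features; a protein carries its
#' module's block, then every (protein, feature) bit across the full
#' universe is flipped independently with probability `noise_flip_prob`.
#' With zero noise, within-module Jaccard similarity is exactly 1 and
#' cross-module similarity exactly 0.
#'
#' @param module_labels integer module label per protein (1-based).
#' @param n_features features per module block (default 10).
#' @param noise_flip_prob flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @param accessions optional protein names (default `P0001`...).
#' @return named list: accession -> character feature vector.
#' @export
gen_profiles <- function(module_labels, n_features = 10L,
                         noise_flip_prob = 0, seed = 42L,
                         accessions = NULL) {
  if (noise_flip_prob < 0 || noise_flip_prob >= 0.5)
    stop("noise_flip_prob must be in [0, 0.5)")
  n <- length(module_labels)
  if (is.null(accessions)) accessions <- sprintf("P%04d", seq_len(n))
  n_modules <- max(module_labels)
  universe <- sprintf("F%02d_%02d", rep(seq_len(n_modules), each = n_features),
                      rep(seq_len(n_features), n_modules))
  base <- matrix(FALSE, n, length(universe))
  for (i in seq_len(n)) {
    block <- (module_labels[i] - 1L) * n_features + seq_len(n_features)
    base[i, block] <- TRUE
  }
  if (noise_flip_prob > 0) {
    with_seed(seed_offset(seed, 1L), {
      flips <- matrix(stats::runif(length(base)) < noise_flip_prob,
                      n, length(universe))
    })
    base <- xor(base, flips)
  }
  profiles <- lapply(seq_len(n), function(i) universe[base[i, ]])
  stats::setNames(profiles, accessions)
}

#' Generate a complete-tree toy ontology
#'
#' A rooted tree of the given depth and branching factor, edges stored
#' child -> parent. The expected leaf-distance weight of a term at distance
#' `d` above the leaves is `1/(d+1)`.
#'
#' @param depth number of levels below the root (0 = a single term).
#' @param branching children per internal term.
#' @return list with `edges` (data frame `child`, `parent`), `terms`,
#'   `expected_weights` (named numeric, the `1/(d+1)` level formula).
#' @export
gen_toy_ontology <- function(depth = 2L, branching = 2L) {
  terms <- "T0_1"
  edges <- data.frame(child = character(0), parent = character(0))
  level_terms <- list("T0_1")
  for (lev in seq_len(depth)) {
    parents <- level_terms[[lev]]
    children <- sprintf("T%d_%d", lev,
                        seq_len(length(parents) * branching))
    edges <- rbind(edges, data.frame(
      child = children,
      parent = rep(parents, each = branching)))
    level_terms[[lev + 1L]] <- children
    terms <- c(terms, children)
  }
  level_of <- rep(seq_len(depth + 1L) - 1L, lengths(level_terms))
  names(level_of) <- unlist(level_terms)
  expected <- 1 / (depth - level_of[terms] + 1)
  list(edges = edges, terms = terms,
       expected_weights = stats::setNames(as.numeric(expected), terms))
}

#' Generate a multi-species network with orthology clusters
#'
#' Builds one planted-partition network per species (identical module
#' structure, species-specific random seeds), merges them into one graph in
#' which the species blocks are mutually disconnected, and emits: a species
#' map, NOG clusters (one per module "slot", containing the slot's protein
#' from every species — species-consistent by construction — for a fraction
#' `nog_rate` of slots), and annotations (`term = GO:MOD<m>` for module `m`)
#' for the first `n_annotated_species` species only, each annotation kept
#' with probability `annotation_rate`.
#'
#' @param n_species number of species (default 4).
#' @param n_modules modules per species (default 3).
#' @param module_size proteins per module per species (default 20).
#' @param n_annotated_species how many species carry annotations (default
#'   half of them).
#' @param annotation_rate probability a positive protein of an annotated
#'   species is actually annotated (default 0.8).
#' @param nog_rate fraction of module slots that get a consistent NOG
#'   (default 1).
#' @param p_in,p_out,w_in,w_out per-species planted-partition parameters.
#'   The intra-module default is deliberately sparser (0.08) than in
#'   [gen_planted_partition()]: real single-species networks are typically
#'   sparse and partly fragmented, which is exactly what makes cross-species
#'   annotation transfer through orthology edges valuable.
#' @param seed master integer seed.
#' @return list with `graph` (merged [weighted_graph()]),
#'   `species_graphs` (per-species graphs), `species_map` (named character),
#'   `nogs` (named list), `annotations` (data frame `accession`, `term`),
#'   `modules` (named module label per protein).
#' @export
gen_multispecies <- function(n_species = 4L, n_modules = 3L,
                             module_size = 20L,
                             n_annotated_species = ceiling(n_species / 2),
                             annotation_rate = 0.8, nog_rate = 1,
                             p_in = 0.08, p_out = 0.02,
                             w_in = c(0.5, 1), w_out = c(0.05, 0.3),
                             seed = 42L) {
  n_per_species <- n_modules * module_size
  species_ids <- sprintf("sp%d", seq_len(n_species))
  species_graphs <- vector("list", n_species)
  names(species_graphs) <- species_ids
  all_edges <- NULL
  all_acc <- character(0)
  modules_all <- integer(0)
  for (s in seq_len(n_species)) {
    pp <- gen_planted_partition(n_nodes = n_per_species,
                                n_modules = n_modules,
                                p_in = p_in, p_out = p_out,
                                w_in = w_in, w_out = w_out,
                                seed = seed_offset(seed, 100L * s),
                                prefix = sprintf("S%d_P", s))
    species_graphs[[s]] <- pp$graph
    offset <- length(all_acc)
    e <- pp$graph$edges
    all_edges <- rbind(all_edges,
                       data.frame(src = e$src + offset,
                                  dst = e$dst + offset,
                                  weight = e$weight))
    all_acc <- c(all_acc, pp$graph$id_map)
    modules_all <- c(modules_all,
                     stats::setNames(pp$modules, pp$graph$id_map))
  }
  graph <- weighted_graph(all_edges, all_acc)
  species_map <- stats::setNames(
    rep(species_ids, each = n_per_species), all_acc)

  # NOGs: slot j of module m across all species
  nogs <- list()
  slot_keys <- expand.grid(slot = seq_len(module_size),
                           module = seq_len(n_modules))
  with_seed(seed_offset(seed, 7L), {
    chosen <- stats::runif(nrow(slot_keys)) < nog_rate
  })
  for (k in which(chosen)) {
    m <- slot_keys$module[k]
    j <- slot_keys$slot[k]
    members <- sprintf("S%d_P%04d", seq_len(n_species),
                       (m - 1L) * module_size + j)
    nogs[[sprintf("NOG_m%d_s%d", m, j)]] <- members
  }

  # annotations only in the first n_annotated_species species
  ann <- NULL
  with_seed(seed_offset(seed, 11L), {
    for (s in seq_len(n_annotated_species)) {
      for (m in seq_len(n_modules)) {
        prots <- sprintf("S%d_P%04d", s,
                         (m - 1L) * module_size + seq_len(module_size))
        keep <- stats::runif(length(prots)) < annotation_rate
        if (any(keep))
          ann <- rbind(ann, data.frame(accession = prots[keep],
                                       term = sprintf("GO:MOD%d", m)))
      }
    }
  })
  list(graph = graph, species_graphs = species_graphs,
       species_map = species_map, nogs = nogs,
       annotations = ann, modules = modules_all)
}
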