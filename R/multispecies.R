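# Multi-species network assembly. Per-species networks are mutually
# disconnected blocks of the merged graph; clusters of orthologous proteins
# (NOGs) supply the cross-species links: after restricting each cluster to a
# chosen set of core species and keeping only the "consistent" clusters
# (exactly one protein per represented species), every pair of cluster
# members is connected by a clique edge, which lets annotations propagate
# from well-annotated species to poorly annotated ones.

#' Restrict NOG clusters to core species
#'
#' Removes from every cluster the proteins whose species is not in
#' `core_species`; clusters left empty are dropped.
#'
#' @param nogs named list: cluster id -> character vector of member
#'   accessions.
#' @param core_species character vector of species ids to keep.
#' @param species_map named character vector: accession -> species id. It
#'   must cover every cluster member.
#' @return filtered named list of clusters.
#' @export
filter_nog_members <- function(nogs, core_species, species_map) {
  members <- unlist(nogs, use.names = FALSE)
  unknown <- setdiff(members, names(species_map))
  if (length(unknown))
    stop("NOG member(s) missing from the species map: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  out <- lapply(nogs, function(m) m[species_map[m] %in% core_species])
  out[lengths(out) > 0L]
}

#' Select species-consistent NOG clusters
#'
#' Keeps the clusters in which the number of proteins equals the number of
#' distinct species represented, i.e. exactly one protein per species.
#'
#' @param nogs named list of clusters (accession vectors).
#' @param species_map named character vector: accession -> species id.
#' @return named list of retained clusters.
#' @export
select_consistent_nogs <- function(nogs, species_map) {
  keep <- vapply(nogs, function(m) {
    length(m) == length(unique(species_map[m]))
  }, logical(1))
  nogs[keep]
}

#' Add orthology clique edges to a network
#'
#' For every cluster of size `s`, all `s(s-1)/2` unordered member pairs are
#' ensured present. A pair already in the network keeps the larger of its
#' existing weight and `weight` (augmentation never lowers or removes an
#' edge); only genuinely new pairs count as added.
#'
#' @param network edge data frame (`src`, `dst`, `weight`, accessions).
#' @param nogs named list of (typically consistent) clusters.
#' @param weight positive weight for orthology edges (default 1).
#' @return list with `network` (augmented edge data frame) and
#'   `added_edges` (count of new pairs).
#' @export
add_ortholog_edges <- function(network, nogs, weight = 1) {
  if (weight <= 0) stop("orthology edge weight must be > 0")
  network <- as.data.frame(network)[, c("src", "dst", "weight")]
  pairs <- lapply(nogs, function(m) {
    m <- unique(m)
    if (length(m) < 2L) return(NULL)
    cmb <- utils::combn(sort(m), 2L)
    data.frame(src = cmb[1L, ], dst = cmb[2L, ])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(list(network = network, added_edges = 0L))
  pairs <- unique(pairs)
  net_key <- paste0(pmin(network$src, network$dst), "\r",
                    pmax(network$src, network$dst))
  pair_key <- paste0(pairs$src, "\r", pairs$dst)
  hit <- match(net_key, pair_key)
  # existing pairs: raise weight to max(existing, weight)
  network$weight[!is.na(hit)] <- pmax(network$weight[!is.na(hit)], weight)
  new <- pairs[!(pair_key %in% net_key), , drop = FALSE]
  if (nrow(new)) {
    new$weight <- weight
    network <- rbind(network, new)
  }
  rownames(network) <- NULL
  list(network = network, added_edges = nrow(new))
}

#' Connected components of a network
#'
#' @param network edge data frame (`src`, `dst`, accessions), or a
#'   [weighted_graph()].
#' @param vertices optional character vector declaring the full vertex set
#'   (so isolated vertices are counted); defaults to the union of edge
#'   endpoints.
#' @return list with `membership` (named integer component label per
#'   vertex), `sizes` (descending component sizes) and `density`
#'   (`2|E| / (n(n-1))`).
#' @export
connected_components <- function(network, vertices = NULL) {
  if (inherits(network, "weighted_graph")) {
    vertices <- network$id_map
    network <- data.frame(src = network$id_map[network$edges$src + 1L],
                          dst = network$id_map[network$edges$dst + 1L])
  }
  network <- as.data.frame(network)
  if (is.null(vertices))
    vertices <- unique(c(network$src, network$dst))
  g <- igraph::graph_from_data_frame(
    network[, c("src", "dst")], directed = FALSE,
    vertices = data.frame(name = vertices))
  comp <- igraph::components(g)
  n <- length(vertices)
  n_edges <- nrow(unique(data.frame(lo = pmin(network$src, network$dst),
                                    hi = pmax(network$src, network$dst))))
  list(membership = comp$membership,
       sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       density = if (n > 1L) 2 * n_edges / (n * (n - 1)) else 0)
}

#' Assemble an orthology-augmented multi-species graph
#'
#' Convenience composition of the full pipeline: restrict NOG clusters to
#' the core species, keep the species-consistent ones, add their clique
#' edges to the merged per-species network, and return the result as a
#' [weighted_graph()] over the same vertex set.
#'
#' @param graph merged multi-species [weighted_graph()].
#' @param nogs named list of NOG clusters (accession vectors).
#' @param species_map named character vector accession -> species.
#' @param core_species species to keep (default: all species present).
#' @param weight orthology edge weight (default 1).
#' @return list with `graph` (augmented [weighted_graph()]),
#'   `added_edges`, and `nogs` (the selected consistent clusters).
#' @export
assemble_multispecies <- function(graph, nogs, species_map,
                                  core_species = unique(species_map),
                                  weight = 1) {
  stopifnot(inherits(graph, "weighted_graph"))
  net <- data.frame(src = graph$id_map[graph$edges$src + 1L],
                    dst = graph$id_map[graph$edges$dst + 1L],
                    weight = graph$edges$weight)
  sel <- select_consistent_nogs(
    filter_nog_members(nogs, core_species, species_map), species_map)
  aug <- add_ortholog_edges(net, sel, weight)
  g2 <- weighted_graph(
    data.frame(src = match(aug$network$src, graph$id_map) - 1L,
               dst = match(aug$network$dst, graph$id_map) - 1L,
               weight = aug$network$weight),
    graph$id_map)
  list(graph = g2, added_edges = aug$added_edges, nogs = sel)
}

#' Read NOG clusters from TSV (`nog_id<TAB>accession`)
#' @param path input file.
#' @return named list: cluster id -> accession vector.
#' @export
read_nogs <- function(path) {
  if (!file.exists(path)) stop("NOG file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("nog", "accession"),
                           colClasses = "character")
  split(tab$accession, tab$nog)
}

#' Read a species map from TSV (`accession<TAB>species_id`)
#' @param path input file.
#' @return named character vector: accession -> species id.
#' @export
read_species_map <- function(path) {
  if (!file.exists(path)) stop("species map not found: ", path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("accession", "species"),
                           colClasses = "character")
  stats::setNames(tab$species, tab$accession)
}
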