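#' Construct a weighted undirected protein network
#'
#' The logical in-memory representation of a functional network: `n` vertices
#' with dense 0-based integer ids, an accession <-> id map, and a set of
#' weighted undirected edges stored once per unordered pair.
#'
#' @param edges data frame with integer columns `src`, `dst` (0-based vertex
#'   ids) and numeric `weight`. Each unordered pair appears once.
#' @param id_map character vector of protein accessions; position `k`
#'   corresponds to vertex id `k - 1`.
#' @return an object of class `weighted_graph` with elements `n`, `edges`
#'   (canonicalized so `src < dst`) and `id_map`.
#' @export
weighted_graph <- function(edges, id_map) {
  id_map <- as.character(id_map)
  n <- length(id_map)
  if (anyDuplicated(id_map)) stop("duplicate accessions in id map")
  edges <- as.data.frame(edges)[, c("src", "dst", "weight")]
  edges$src <- as.integer(edges$src)
  edges$dst <- as.integer(edges$dst)
  edges$weight <- as.numeric(edges$weight)
  if (nrow(edges)) {
    if (any(edges$src < 0L | edges$src >= n | edges$dst < 0L | edges$dst >= n))
      stop("vertex id out of range [0, n)")
    if (any(edges$src == edges$dst)) stop("self-loops are not allowed")
    if (any(!is.finite(edges$weight) | edges$weight <= 0))
      stop("edge weights must be finite and > 0")
    # canonical orientation src < dst, one row per unordered pair
    flip <- edges$src > edges$dst
    tmp <- edges$src[flip]
    edges$src[flip] <- edges$dst[flip]
    edges$dst[flip] <- tmp
    key <- paste(edges$src, edges$dst)
    if (anyDuplicated(key)) stop("duplicate edges for the same vertex pair")
    edges <- edges[order(edges$src, edges$dst), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(n = n, edges = edges, id_map = id_map),
            class = "weighted_graph")
}

#' Read a weighted edge list from a TSV file
#'
#' Expects three whitespace/tab separated columns: source accession, target
#' accession, positive weight. Lines starting with `#` are ignored.
#' Accessions are assigned dense 0-based ids in order of first appearance
#' (scanning each line source-first). Exact duplicate unordered pairs are
#' deduplicated; a pair repeated with conflicting weights, a self-loop, or a
#' non-positive/non-finite weight is rejected.
#'
#' @param path path to the TSV edge list.
#' @return a [weighted_graph()].
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"),
                           col.names = c("src", "dst", "weight"))
  if (any(tab$src == tab$dst))
    stop("self-loop in ", path, ": ", tab$src[tab$src == tab$dst][1])
  if (any(!is.finite(tab$weight) | tab$weight <= 0))
    stop("non-positive or non-finite weight in ", path)
  # first-appearance order over src, dst interleaved by row
  acc <- unique(as.vector(rbind(tab$src, tab$dst)))
  src <- match(tab$src, acc) - 1L
  dst <- match(tab$dst, acc) - 1L
  lo <- pmin(src, dst)
  hi <- pmax(src, dst)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    w_by_key <- split(tab$weight, key)
    bad <- vapply(w_by_key, function(w) length(unique(w)) > 1L, logical(1))
    if (any(bad))
      stop("conflicting weights for duplicated pair(s) in ", path)
    keep <- !duplicated(key)
    src <- src[keep]; dst <- dst[keep]
    tab <- tab[keep, , drop = FALSE]
  }
  weighted_graph(data.frame(src = src, dst = dst, weight = tab$weight),
                 id_map = acc)
}

#' Write a weighted graph (or similarity network) as a TSV edge list
#'
#' @param x a [weighted_graph()] or a data frame with columns
#'   `src`, `dst`, `weight` holding accession strings.
#' @param path output file.
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "weighted_graph")) {
    df <- data.frame(src = x$id_map[x$edges$src + 1L],
                     dst = x$id_map[x$edges$dst + 1L],
                     weight = x$edges$weight)
  } else {
    df <- as.data.frame(x)[, c("src", "dst", "weight")]
  }
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Weighted vertex degrees
#'
#' Sum of incident edge weights per vertex, in vertex-id order.
#'
#' @param graph a [weighted_graph()].
#' @return numeric vector of length `n`.
#' @export
weighted_degrees <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  deg <- numeric(graph$n)
  if (nrow(graph$edges)) {
    e <- graph$edges
    add <- rowsum(c(e$weight, e$weight), c(e$src, e$dst))
    deg[as.integer(rownames(add)) + 1L] <- add[, 1L]
  }
  deg
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d vertices, %d undirected edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

# resolve accessions or 0-based ids to 0-based ids
resolve_ids <- function(x, graph_or_map) {
  id_map <- if (is.character(graph_or_map)) graph_or_map else graph_or_map$id_map
  if (is.character(x)) {
    idx <- match(x, id_map)
    if (anyNA(idx)) stop("unknown accession(s): ",
                         paste(x[is.na(idx)], collapse = ", "))
    idx - 1L
  } else {
    as.integer(x)
  }
}
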