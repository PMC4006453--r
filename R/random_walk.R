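# Local (vertex-centric) t-step random walk for automated function
# prediction. The walk starts uniformly from the seed set C (p0 = 1/|C| on
# seeds), and each step applies
#
#   p_i(t+1) = sum_{j in N(i)} d_jj^{-1} * w_ji * p_j(t),
#
# i.e. the per-vertex resolution of the global update p(t+1) = Q' p(t) with
# Q = D^{-1} W. On an undirected network w_ji = w_ij, so only the incident
# edge list of each vertex is needed; the resulting scores rank vertices by
# relevance to the functional class of the seeds.

#' Inverse weighted degrees
#'
#' `inv_degree[j] = 1 / sum_i w_ji`; isolated (zero-degree) vertices get 0 by
#' convention, which makes their probability mass vanish at the next step.
#' Computed once as preprocessing.
#'
#' @param x a [weighted_graph()] or `sharded_graph`.
#' @return numeric vector of length `n`.
#' @export
compute_inverse_degrees <- function(x) UseMethod("compute_inverse_degrees")

#' @export
compute_inverse_degrees.weighted_graph <- function(x) {
  deg <- weighted_degrees(x)
  ifelse(deg > 0, 1 / deg, 0)
}

#' @export
compute_inverse_degrees.sharded_graph <- function(x) {
  deg <- numeric(x$n)
  sliding_window_pass(x, function(vid, src, w) {
    deg[vid + 1L] <<- sum(w)
  }, verify = FALSE)
  ifelse(deg > 0, 1 / deg, 0)
}

#' Initial probability vector for a seed set
#'
#' Probability `1/|C|` on each seed vertex, 0 elsewhere; sums to 1.
#'
#' @param n number of vertices.
#' @param seeds non-empty vector of 0-based seed vertex ids.
#' @return numeric vector of length `n`.
#' @export
init_probabilities <- function(n, seeds) {
  seeds <- unique(as.integer(seeds))
  if (length(seeds) == 0L) stop("seed set is empty")
  if (any(seeds < 0L | seeds >= n)) stop("seed id out of range [0, n)")
  p <- numeric(n)
  p[seeds + 1L] <- 1 / length(seeds)
  p
}

# cached sparse symmetric adjacency for the in-memory path
rw_adjacency <- function(graph) {
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e$src, e$dst) + 1L,
                       j = c(e$dst, e$src) + 1L,
                       x = c(e$weight, e$weight),
                       dims = c(graph$n, graph$n))
}

#' One random-walk step
#'
#' Applies the per-vertex update rule once; equivalent to the global
#' `p(t+1) = Q' p(t)` with `Q = D^{-1} W`.
#'
#' @param graph a [weighted_graph()].
#' @param p current probability vector.
#' @param inv_degree precomputed inverse degrees (defaults to computing them).
#' @param W optional cached adjacency matrix (internal use).
#' @return next probability vector.
#' @export
rw_step <- function(graph, p, inv_degree = compute_inverse_degrees(graph),
                    W = rw_adjacency(graph)) {
  as.numeric(W %*% (inv_degree * p))
}

# vertex program implementing the local update rule
rw_vertex_program <- function(p0) {
  vertex_program(
    start = function(vid) p0[vid + 1L],
    update = function(vid, src, w, p_src, d_src) sum(d_src * w * p_src)
  )
}

#' Run a t-step random walk from a seed set
#'
#' With a `weighted_graph` the walk runs in memory via sparse matrix
#' products; with a `sharded_graph` it runs out-of-core through the
#' vertex-centric engine. Both paths produce the same scores (up to floating
#' point round-off in summation order).
#'
#' @param x a [weighted_graph()] or `sharded_graph`.
#' @param seeds seed vertices: 0-based ids or accession strings.
#' @param steps number of steps (>= 0); `steps = 0` returns the initial
#'   vector.
#' @param tol optional early-stopping tolerance on the max-norm change
#'   between consecutive steps.
#' @param renormalize when `TRUE`, rescale the vector to sum 1 after each
#'   step (counteracts mass leaking through zero-degree vertices).
#' @return numeric score vector of length `n` (named by accession when an
#'   id map is available).
#' @export
run_rw <- function(x, seeds, steps, tol = NULL, renormalize = FALSE) {
  steps <- as.integer(steps)
  if (steps < 0L) stop("steps must be >= 0")
  seeds <- resolve_ids(seeds, x)
  p0 <- init_probabilities(x$n, seeds)
  if (inherits(x, "weighted_graph")) {
    inv_degree <- compute_inverse_degrees(x)
    W <- rw_adjacency(x)
    p <- p0
    if (steps > 0L) for (t in seq_len(steps)) {
      p_next <- rw_step(x, p, inv_degree, W)
      if (renormalize && sum(p_next) > 0) p_next <- p_next / sum(p_next)
      delta <- max(abs(p_next - p))
      p <- p_next
      if (!is.null(tol) && delta < tol) break
    }
  } else if (inherits(x, "sharded_graph")) {
    inv_degree <- compute_inverse_degrees(x)
    if (renormalize) {
      # renormalization is a global operation; run step-by-step
      p <- p0
      if (steps > 0L) for (t in seq_len(steps)) {
        res <- run_program(x, rw_vertex_program(p), 1L, inv_degree)
        p_next <- res$p
        if (sum(p_next) > 0) p_next <- p_next / sum(p_next)
        delta <- max(abs(p_next - p))
        p <- p_next
        if (!is.null(tol) && delta < tol) break
      }
    } else {
      p <- run_program(x, rw_vertex_program(p0), steps, inv_degree,
                       tol = tol)$p
    }
  } else {
    stop("x must be a weighted_graph or sharded_graph")
  }
  names(p) <- x$id_map
  p
}

#' Rank vertices by score
#'
#' Descending by score; ties broken ascending by vertex id, so the ranking
#' is deterministic.
#'
#' @param scores numeric score vector over all vertices (0-based id order).
#' @param exclude optional vertex ids to drop from the ranking.
#' @return data frame with columns `id` (0-based), `score`, ordered.
#' @export
rank_vertices <- function(scores, exclude = NULL) {
  ids <- seq_along(scores) - 1L
  keep <- if (is.null(exclude)) rep(TRUE, length(ids)) else !(ids %in% exclude)
  ids <- ids[keep]
  sc <- as.numeric(scores)[keep]
  ord <- order(-sc, ids)
  out <- data.frame(id = ids[ord], score = sc[ord])
  if (!is.null(names(scores))) out$accession <- names(scores)[keep][ord]
  out
}
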