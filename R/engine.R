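# Synchronous vertex-centric execution over a sharded graph.
#
# Per-vertex state (inverse weighted degree plus double-buffered
# probabilities) lives in an in-RAM global vector while arcs stream from the
# shard files. Updates are strictly synchronous (Jacobi): within an
# iteration every update reads only the *previous* buffer of its neighbours;
# buffers swap roles when the full pass completes, so the result is
# independent of the number of shards K and of visiting order.

#' Define a vertex program
#'
#' @param start `function(vid)` returning the vertex's initial probability.
#' @param update `function(vid, src, w, p_src, d_src)` returning the vertex's
#'   next probability given its in-arcs: source ids `src`, arc weights `w`,
#'   the sources' previous-step probabilities `p_src` and inverse weighted
#'   degrees `d_src`. It must not (and, by construction, cannot) observe any
#'   neighbour's current-step value.
#' @return a `vertex_program` object.
#' @export
vertex_program <- function(start, update) {
  stopifnot(is.function(start), is.function(update))
  structure(list(start = start, update = update), class = "vertex_program")
}

#' Run a vertex program over a sharded graph
#'
#' Applies `program$start` once to every vertex, then runs up to
#' `iterations` synchronous passes of `program$update` via
#' [sliding_window_pass()], swapping the probability buffers at the end of
#' each pass. With `tol` set, iteration stops early when the max-norm change
#' between consecutive buffers falls below `tol`.
#'
#' @param sharded a `sharded_graph`.
#' @param program a [vertex_program()].
#' @param iterations maximum number of passes (>= 0).
#' @param inv_degree per-vertex inverse weighted degree vector (see
#'   [compute_inverse_degrees()]).
#' @param tol optional early-stopping tolerance on the max-norm change.
#' @return list with the final probability vector `p`, `iterations_run`,
#'   and `pass_stats` (the last pass's traversal statistics).
#' @export
run_program <- function(sharded, program, iterations, inv_degree,
                        tol = NULL) {
  stopifnot(inherits(sharded, "sharded_graph"),
            inherits(program, "vertex_program"))
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0")
  n <- sharded$n
  if (length(inv_degree) != n) stop("inv_degree has wrong length")
  verify_shard_checksums(sharded)

  p_prev <- vapply(seq_len(n) - 1L, program$start, numeric(1))
  p_curr <- numeric(n)
  stats <- NULL
  iterations_run <- 0L
  if (iterations > 0L) {
    env <- environment()
    visitor <- function(vid, in_src, in_w) {
      k <- in_src + 1L
      env$p_curr[vid + 1L] <-
        program$update(vid, in_src, in_w, env$p_prev[k], inv_degree[k])
    }
    for (it in seq_len(iterations)) {
      stats <- sliding_window_pass(sharded, visitor, verify = FALSE)
      delta <- max(abs(p_curr - p_prev), 0)
      # swap buffer roles: current becomes previous for the next pass
      tmp <- p_prev; p_prev <- p_curr; p_curr <- tmp
      iterations_run <- it
      if (!is.null(tol) && delta < tol) break
    }
  }
  list(p = p_prev, iterations_run = iterations_run, pass_stats = stats)
}
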