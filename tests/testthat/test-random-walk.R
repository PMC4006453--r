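# The local t-step random walk: inverse degrees, seed initialization, the
# per-vertex update rule against a dense transition-matrix oracle, score
# conservation and deterministic ranking.

test_that("inverse degrees match the dense row-sum reciprocal oracle", {
  g <- weighted_graph(data.frame(src = c(0L, 0L), dst = c(1L, 2L),
                                 weight = c(2, 3)),
                      c("a", "b", "c"))
  expect_equal(compute_inverse_degrees(g), c(0.2, 0.5, 1 / 3))
  # isolated vertex convention: inverse degree 0
  g2 <- weighted_graph(data.frame(src = 0L, dst = 1L, weight = 1),
                       c("a", "b", "lonely"))
  expect_equal(compute_inverse_degrees(g2)[3L], 0)
  for (case in 1:5) {
    gr <- random_test_graph(sample(20:100, 1), dens = 0.1, seed = 300 + case)
    W <- dense_adjacency(gr)
    d <- rowSums(W)
    expect_equal(compute_inverse_degrees(gr),
                 ifelse(d > 0, 1 / d, 0), tolerance = 1e-14)
    sh <- build_shards(gr, 3L, dir = withr::local_tempdir())
    expect_equal(compute_inverse_degrees(sh),
                 compute_inverse_degrees(gr), tolerance = 1e-14)
  }
})

test_that("seed initialization puts 1/|C| on seeds and sums to one", {
  p <- init_probabilities(10L, c(0L, 2L, 5L, 7L))
  expect_equal(sum(p), 1)
  expect_equal(sort(unique(p)), c(0, 0.25))
  expect_equal(which(p > 0) - 1L, c(0L, 2L, 5L, 7L))
  expect_equal(init_probabilities(4L, 3L)[4L], 1)
  expect_error(init_probabilities(5L, integer(0)), "empty")
  expect_error(init_probabilities(5L, 5L), "range")
})

test_that("a single step follows the update rule on hand-checked graphs", {
  # two vertices, one edge: the probability swaps endpoints
  g <- weighted_graph(data.frame(src = 0L, dst = 1L, weight = 1),
                      c("a", "b"))
  expect_equal(rw_step(g, c(1, 0)), c(0, 1))
  # unweighted triangle: mass halves onto the two neighbours
  tri <- weighted_graph(data.frame(src = c(0L, 0L, 1L),
                                   dst = c(1L, 2L, 2L),
                                   weight = c(1, 1, 1)),
                        c("a", "b", "c"))
  expect_equal(rw_step(tri, c(1, 0, 0)), c(0, 0.5, 0.5))
})

test_that("rw_step matches the dense transition-matrix product", {
  for (case in 1:20) {
    n <- sample(20:200, 1)
    g <- random_test_graph(n, dens = 0.05, seed = 400 + case)
    set.seed(case)
    p <- stats::runif(n)
    p <- p / sum(p)
    expect_lt(max(abs(rw_step(g, p) - dense_rw_oracle(g, p, 1L))), 1e-12)
  }
})

test_that("sharded vertex-centric walks equal the dense iteration", {
  for (case in 1:10) {
    n <- sample(30:150, 1)
    g <- random_test_graph(n, dens = 0.05, seed = 500 + case)
    set.seed(case)
    seeds <- sample(n, sample(1:10, 1)) - 1L
    p0 <- init_probabilities(n, seeds)
    for (K in c(1L, 3L)) {
      sh <- build_shards(g, K, dir = withr::local_tempdir())
      for (steps in c(1L, 3L)) {
        ref <- dense_rw_oracle(g, p0, steps)
        expect_lt(max(abs(run_rw(sh, seeds, steps) - ref)), 1e-10)
        expect_lt(max(abs(run_rw(g, seeds, steps) - ref)), 1e-10)
      }
    }
  }
})

test_that("zero steps returns the initial vector; one step one update", {
  g <- random_test_graph(30, dens = 0.2, seed = 30)
  seeds <- c(1L, 4L)
  expect_equal(unname(run_rw(g, seeds, 0L)),
               init_probabilities(g$n, seeds))
  expect_equal(unname(run_rw(g, seeds, 1L)),
               rw_step(g, init_probabilities(g$n, seeds)))
})

test_that("probability mass is conserved on positive-degree graphs", {
  for (case in 1:5) {
    g <- random_test_graph(60, dens = 0.2, seed = 600 + case)
    deg <- weighted_degrees(g)
    skip_if(any(deg == 0))  # density 0.2 on 60 vertices: never in practice
    seeds <- sample(g$n, 5L) - 1L
    p <- init_probabilities(g$n, seeds)
    for (t in 1:3) {
      p <- rw_step(g, p)
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("dangling vertices leak mass, and renormalization restores it", {
  # star seed attached to a dangling pendant: mass entering the pendant
  # vanishes one step later
  g <- weighted_graph(data.frame(src = c(0L, 1L), dst = c(1L, 2L),
                                 weight = c(1, 1)),
                      c("hub", "mid", "end"))
  g_dangling <- weighted_graph(data.frame(src = 0L, dst = 1L, weight = 1),
                               c("a", "b", "dangling"))
  p <- run_rw(g_dangling, c(0L, 2L), 1L)  # half the mass starts dangling
  expect_equal(sum(p), 0.5)
  p2 <- run_rw(g_dangling, c(0L, 2L), 1L, renormalize = TRUE)
  expect_equal(sum(p2), 1)
})

test_that("scores on a cycle are symmetric about a single seed", {
  n <- 11L
  edges <- data.frame(src = 0:(n - 1L), dst = c(1:(n - 1L), 0L),
                      weight = 1)
  g <- weighted_graph(edges, sprintf("v%02d", seq_len(n)))
  p <- unname(run_rw(g, 0L, 3L))
  # vertex k and vertex n-k are equidistant from the seed
  for (k in 1:(n %/% 2)) expect_equal(p[1L + k], p[1L + n - k])
})

test_that("per-step work grows linearly with the arc count", {
  # instrument the engine path: out-arc window records + memory shard
  # records scanned per pass equal the arc count exactly
  for (n in c(40L, 80L, 160L)) {
    g <- random_test_graph(n, dens = 0.1, seed = n)
    sh <- build_shards(g, 4L, dir = withr::local_tempdir())
    arcs_seen <- 0L
    stats <- sliding_window_pass(sh, function(vid, src, w) {
      arcs_seen <<- arcs_seen + length(src)
    })
    expect_equal(arcs_seen, sh$manifest$arc_count)
    expect_lte(stats$out_arc_records, sh$manifest$arc_count)
  }
})

test_that("ranking is descending with deterministic id tie-breaks", {
  r <- rank_vertices(c(0.2, 0.9, 0.2))
  expect_equal(r$id, c(1L, 0L, 2L))
  r2 <- rank_vertices(c(0.2, 0.9, 0.2), exclude = 1L)
  expect_equal(r2$id, c(0L, 2L))
  set.seed(77)
  sc <- sample(stats::runif(20), 50, replace = TRUE)
  r3 <- rank_vertices(sc)
  ref <- order(-sc, seq_along(sc) - 1L) - 1L  # stable sort oracle
  expect_equal(r3$id, ref)
})
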