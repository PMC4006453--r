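# Independent oracles used to validate the package's implementations.
# Everything here is written the brute-force way on purpose and never calls
# the code path it checks.

# dense symmetric adjacency matrix straight from an edge table
dense_adjacency <- function(graph) {
  n <- graph$n
  W <- matrix(0, n, n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    W[e$src[r] + 1L, e$dst[r] + 1L] <- e$weight[r]
    W[e$dst[r] + 1L, e$src[r] + 1L] <- e$weight[r]
  }
  W
}

# t applications of the global update p(t+1) = Q' p(t), Q = D^-1 W, dense
dense_rw_oracle <- function(graph, p0, steps) {
  W <- dense_adjacency(graph)
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / d, 0)
  Q <- diag(dinv, nrow = length(dinv)) %*% W
  p <- matrix(p0, ncol = 1)
  for (t in seq_len(steps)) p <- t(Q) %*% p
  as.numeric(p)
}

# random simple weighted graph on n vertices with expected density `dens`
random_test_graph <- function(n, dens = 0.05, seed = 1) {
  set.seed(seed)
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < dens
  # guarantee at least one edge so the graph is never empty
  if (!any(keep)) keep[1L] <- TRUE
  edges <- data.frame(src = pairs[1L, keep] - 1L,
                      dst = pairs[2L, keep] - 1L,
                      weight = stats::runif(sum(keep), 0.1, 1))
  weighted_graph(edges, sprintf("N%04d", seq_len(n)))
}

# canonical sorted arc table (both directions) for multiset comparison
symmetrized_arcs <- function(graph) {
  e <- graph$edges
  arcs <- data.frame(src = c(e$src, e$dst), dst = c(e$dst, e$src),
                     w = c(e$weight, e$weight))
  arcs[order(arcs$src, arcs$dst), , drop = FALSE]
}

# union-find connected component labelling over accession endpoints
union_find_components <- function(edges, vertices) {
  parent <- stats::setNames(seq_along(vertices), vertices)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(match(edges$src[r], vertices))
    b <- find(match(edges$dst[r], vertices))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(vertices), find, numeric(1))
  stats::setNames(match(roots, unique(roots)), vertices)
}

# AUC by explicit positive/negative pair counting
auc_pair_counting <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  wins <- 0
  ties <- 0
  for (p in pos) {
    wins <- wins + sum(p > neg)
    ties <- ties + sum(p == neg)
  }
  (wins + ties / 2) / (length(pos) * length(neg))
}

# precision at recall by exhaustive cutoff enumeration over the same
# deterministic ranking (score desc, index asc)
precision_at_recall_enum <- function(scores, labels, R) {
  labels <- as.logical(labels)
  ord <- order(-scores, seq_along(scores))
  P <- sum(labels)
  for (k in seq_along(ord)) {
    tp <- sum(labels[ord[seq_len(k)]])
    if (tp / P >= R) return(tp / k)
  }
  stop("recall level unreachable")
}

# two-sided Wilcoxon signed-rank p by exhaustive sign-assignment
# enumeration (2^n patterns), valid under ties
wilcoxon_exact_enum <- function(a, b) {
  d <- (b - a)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  Ws <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    Ws[mask + 1] <- sum(r[signs])
  }
  mu <- sum(r) / 2
  lower <- mean(Ws <= W_obs)
  upper <- mean(Ws >= W_obs)
  min(1, 2 * min(lower, upper))
}

# brute-force all-pairs similarity network via the scalar measures
brute_force_network <- function(profiles, measure = "jaccard",
                                weights = NULL) {
  prots <- names(profiles)
  out <- NULL
  for (i in seq_along(prots)) for (j in seq_along(prots)) {
    if (j <= i) next
    s <- if (measure == "jaccard") jaccard(profiles[[i]], profiles[[j]])
         else hierarchical_jaccard(profiles[[i]], profiles[[j]], weights)
    if (s > 0)
      out <- rbind(out, data.frame(src = prots[i], dst = prots[j],
                                   weight = s))
  }
  if (is.null(out)) data.frame(src = character(0), dst = character(0),
                               weight = numeric(0))
  else out
}

# dense elementwise mean of sparse networks with missing pairs = 0
dense_mean_network <- function(networks, vertices, n_override = NULL) {
  n <- length(vertices)
  acc <- matrix(0, n, n, dimnames = list(vertices, vertices))
  for (net in networks) {
    for (r in seq_len(nrow(net))) {
      i <- net$src[r]; j <- net$dst[r]
      acc[i, j] <- acc[i, j] + net$weight[r]
      acc[j, i] <- acc[j, i] + net$weight[r]
    }
  }
  denom <- if (is.null(n_override)) length(networks) else n_override
  acc / denom
}

# edge data frame -> dense lookup matrix over given vertices
network_as_matrix <- function(net, vertices) {
  n <- length(vertices)
  M <- matrix(0, n, n, dimnames = list(vertices, vertices))
  for (r in seq_len(nrow(net))) {
    M[net$src[r], net$dst[r]] <- net$weight[r]
    M[net$dst[r], net$src[r]] <- net$weight[r]
  }
  M
}

# build the standard multi-species evaluation pair used in several tests:
# augmented multi-species graph + the first species' own graph/annotations
multispecies_case <- function(seed) {
  ms <- gen_multispecies(seed = seed)
  asm <- assemble_multispecies(ms$graph, ms$nogs, ms$species_map)
  sp1 <- names(ms$species_map)[ms$species_map == "sp1"]
  list(ms = ms, graph_aug = asm$graph, sp1 = sp1,
       ann_sp1 = ms$annotations[ms$annotations$accession %in% sp1, ,
                                drop = FALSE])
}
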