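# Similarity measures, network construction from profiles, unweighted-
# average integration and functional-class filtering.

test_that("classical Jaccard handles the boundary cases", {
  expect_equal(jaccard(c("f1", "f2"), c("f1", "f3")), 1 / 3)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(0), character(0)), 0)
  expect_equal(jaccard(character(0), "a"), 0)
})

test_that("leaf-distance weights follow 1/(d+1) on chains and trees", {
  chain <- data.frame(child = c("leaf", "mid"), parent = c("mid", "root"))
  w <- leaf_distance_weights(chain)
  expect_equal(w[["leaf"]], 1)
  expect_equal(w[["mid"]], 1 / 2)
  expect_equal(w[["root"]], 1 / 3)
  for (depth in 0:3) for (branching in c(2L, 3L)) {
    onto <- gen_toy_ontology(depth, branching)
    w <- leaf_distance_weights(onto)
    expect_equal(w[names(onto$expected_weights)], onto$expected_weights)
  }
  # a DAG: min over leaf paths wins
  dag <- data.frame(child = c("A", "A", "B"), parent = c("B", "C", "C"))
  w <- leaf_distance_weights(dag)
  expect_equal(w[["C"]], 1 / 2)  # one edge above leaf A via the short path
  cyc <- data.frame(child = c("A", "B"), parent = c("B", "A"))
  expect_error(leaf_distance_weights(cyc), "cycle")
})

test_that("hierarchical Jaccard weighs intersections and unions by term", {
  w <- c(leaf = 1, parent = 0.5)
  expect_equal(hierarchical_jaccard("leaf", c("leaf", "parent"), w), 2 / 3)
  expect_error(hierarchical_jaccard("leaf", "unknown", w), "weight")
  set.seed(42)
  terms <- sprintf("T%02d", 1:20)
  uw <- stats::setNames(rep(0.37, 20), terms)
  for (rep in 1:50) {
    A <- sample(terms, sample(0:8, 1))
    B <- sample(terms, sample(0:8, 1))
    # uniform weights reduce to the classical coefficient
    expect_equal(hierarchical_jaccard(A, B, uw), jaccard(A, B))
    # symmetry
    rw <- stats::setNames(stats::runif(20, 0.1, 1), terms)
    expect_equal(hierarchical_jaccard(A, B, rw),
                 hierarchical_jaccard(B, A, rw))
  }
})

test_that("similarity networks equal all-pairs brute force", {
  prots <- sprintf("P%02d", 1:30)
  set.seed(7)
  feats <- sprintf("F%02d", 1:25)
  profiles <- stats::setNames(
    lapply(prots, function(p) sample(feats, sample(0:8, 1))), prots)
  net <- build_similarity_network(profiles)
  ref <- brute_force_network(profiles)
  expect_equal(network_as_matrix(net, prots),
               network_as_matrix(ref, prots), tolerance = 1e-14)
  # hierarchical measure against the scalar evaluation
  w <- stats::setNames(stats::runif(25, 0.2, 1), feats)
  net_h <- build_similarity_network(profiles, "hierarchical", w)
  ref_h <- brute_force_network(profiles, "hierarchical", w)
  expect_equal(network_as_matrix(net_h, prots),
               network_as_matrix(ref_h, prots), tolerance = 1e-14)
  expect_true(all(net$weight > 0 & net$weight <= 1))
  expect_error(build_similarity_network(profiles, "hierarchical"),
               "weights")
})

test_that("degenerate profile tables build degenerate networks", {
  expect_equal(nrow(build_similarity_network(
    list(a = "f1", b = "f2", c = "f3"))), 0L)
  net <- build_similarity_network(list(a = c("f1", "f2"),
                                       b = c("f1", "f2")))
  expect_equal(net$weight, 1)
  expect_error(build_similarity_network(list(a = "f1")), "at least 2")
})

test_that("unweighted-average integration equals the dense mean", {
  one <- data.frame(src = "a", dst = "b", weight = 0.8)
  expect_equal(ua_integrate(list(one))$weight, 0.8)
  two <- ua_integrate(list(one, data.frame(src = "a", dst = "c",
                                           weight = 0.4)))
  expect_equal(two$weight[two$src == "a" & two$dst == "b"], 0.4)
  expect_error(ua_integrate(list()), "no networks")
  prots <- sprintf("P%02d", 1:12)
  set.seed(11)
  for (rep in 1:10) {
    nets <- lapply(1:5, function(d) {
      cmb <- utils::combn(prots, 2L)
      keep <- stats::runif(ncol(cmb)) < 0.3
      data.frame(src = cmb[1L, keep], dst = cmb[2L, keep],
                 weight = stats::runif(sum(keep)))
    })
    got <- network_as_matrix(ua_integrate(nets), prots)
    ref <- dense_mean_network(nets, prots)
    expect_equal(got, ref, tolerance = 1e-14)
    # bounded by the max input weight; idempotent on one network
    expect_lte(max(got), max(vapply(nets, function(x) max(x$weight),
                                    numeric(1))))
    expect_equal(network_as_matrix(ua_integrate(nets[1]), prots),
                 network_as_matrix(nets[[1]], prots), tolerance = 1e-14)
  }
  # n_override: a pair present in 1 of 2 logical networks averages down
  half <- ua_integrate(list(one), n_override = 2L)
  expect_equal(half$weight, 0.4)
})

test_that("class filtering respects both bounds", {
  ann <- data.frame(
    accession = c(sprintf("p%02d", 1:19), sprintf("q%02d", 1:20),
                  sprintf("r%02d", 1:25)),
    term = c(rep("small", 19), rep("edge", 20), rep("big", 25)))
  expect_equal(sort(filter_classes(ann, 20)), c("big", "edge"))
  expect_equal(filter_classes(ann, 20, max_positives = 24), "edge")
  set.seed(3)
  rnd <- data.frame(accession = sample(sprintf("p%03d", 1:60), 300,
                                       replace = TRUE),
                    term = sample(sprintf("GO:%04d", 1:12), 300,
                                  replace = TRUE))
  kept <- filter_classes(rnd, 15)
  counts <- table(unique(rnd)$term)
  expect_setequal(kept, names(counts)[counts >= 15])
})

test_that("profiles, ontologies and annotations round-trip through TSV", {
  dir <- withr::local_tempdir()
  profiles <- list(A = c("f1", "f2"), B = character(0), C = "f3")
  f <- file.path(dir, "p.tsv")
  write_profiles(profiles, f)
  expect_equal(read_profiles(f), profiles)
  ann_f <- file.path(dir, "ann.tsv")
  writeLines(c("P1\tGO:1\t5", "P2\tGO:1\t2", "P2\tGO:2\t4"), ann_f)
  expect_equal(nrow(read_annotations(ann_f)), 3L)
  expect_equal(nrow(read_annotations(ann_f, min_confidence = 4)), 2L)
})

test_that("ancestor propagation closes annotations upward", {
  onto <- data.frame(child = c("leaf", "mid"), parent = c("mid", "root"))
  ann <- data.frame(accession = "P1", term = "leaf")
  closed <- propagate_ancestors(ann, onto)
  expect_setequal(closed$term, c("leaf", "mid", "root"))
})
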