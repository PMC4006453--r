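# Construction of data-type specific similarity networks from sparse binary
# protein profiles, and their integration into a consensus network.
#
# Two similarity measures are provided: the classical Jaccard coefficient on
# feature sets, and a hierarchical Jaccard on Gene Ontology annotation sets
# in which each term is weighted by 1/(d+1), d being its minimum distance
# (in child edges) down to a leaf — leaves weigh 1, their parents 1/2, and
# so on, putting more emphasis on the most specific annotations. Networks
# built from different data types are combined by unweighted averaging, with
# a pair missing from a network contributing weight 0.

#' Classical Jaccard similarity of two feature sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty.
#'
#' @param A,B character (or atomic) vectors treated as sets.
#' @return a number in `[0, 1]`.
#' @export
jaccard <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0L) return(0)
  length(intersect(A, B)) / u
}

#' Leaf-distance term weights for an ontology
#'
#' For every term, `d` is the minimum number of child edges from the term
#' down to any leaf (a term with no children) and the weight is `1/(d+1)`:
#' leaves weigh 1, terms one level up 1/2, etc.
#'
#' @param ontology a data frame with columns `child`, `parent` (one edge per
#'   row), or a list with elements `edges` (that data frame) and optional
#'   `terms` declaring isolated terms.
#' @return named numeric vector of weights over all terms.
#' @export
leaf_distance_weights <- function(ontology) {
  if (is.data.frame(ontology)) ontology <- list(edges = ontology)
  edges <- ontology$edges
  terms <- unique(c(ontology$terms, edges$child, edges$parent))
  if (length(terms) == 0L) return(stats::setNames(numeric(0), character(0)))
  # cycle check: Kahn's algorithm on child -> parent edges
  indeg <- stats::setNames(integer(length(terms)), terms)  # children per term
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  queue <- terms[indeg == 0L]
  removed <- 0L
  parents_of <- split(edges$parent, edges$child)
  indeg_work <- indeg
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; removed <- removed + 1L
    for (p in parents_of[[t]]) {
      indeg_work[p] <- indeg_work[p] - 1L
      if (indeg_work[p] == 0L) queue <- c(queue, p)
    }
  }
  if (removed < length(terms)) stop("ontology contains a cycle")
  # multi-source BFS upward from the leaves along child -> parent edges
  dist <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  frontier <- terms[indeg == 0L]  # leaves: no children
  dist[frontier] <- 0L
  d <- 0L
  while (length(frontier)) {
    nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt) & is.na(dist[nxt])]
    d <- d + 1L
    dist[nxt] <- d
    frontier <- nxt
  }
  1 / (dist + 1)
}

#' Hierarchical (weighted) Jaccard similarity of two term sets
#'
#' `sum_{t in A intersect B} w_t / sum_{t in A union B} w_t`; 0 when both
#' sets are empty. With uniform weights it reduces to [jaccard()].
#'
#' @param A,B term-id vectors treated as sets.
#' @param weights named numeric weight per term (see
#'   [leaf_distance_weights()]).
#' @return a number in `[0, 1]`.
#' @export
hierarchical_jaccard <- function(A, B, weights) {
  A <- unique(A); B <- unique(B)
  uni <- union(A, B)
  if (length(uni) == 0L) return(0)
  if (anyNA(match(uni, names(weights))))
    stop("term(s) without a weight: ",
         paste(setdiff(uni, names(weights)), collapse = ", "))
  sum(weights[intersect(A, B)]) / sum(weights[uni])
}

#' Build an all-pairs similarity network from protein profiles
#'
#' Scores every unordered pair of proteins with the chosen measure and keeps
#' the pairs with non-zero similarity. The computation runs through sparse
#' incidence-matrix products, so only pairs sharing at least one feature are
#' materialized.
#'
#' @param profiles named list: accession -> character vector of feature (or
#'   term) ids; empty vectors are allowed.
#' @param measure `"jaccard"` or `"hierarchical"`.
#' @param weights term weights, required for the hierarchical measure.
#' @param min_weight optional cutoff; pairs scoring below it are dropped
#'   (default 0 keeps everything non-zero, matching the absence of any
#'   sparsification in the construction).
#' @return data frame with columns `src`, `dst`, `weight` (accessions,
#'   `src` before `dst` in input order), a sparse symmetric network.
#' @export
build_similarity_network <- function(profiles,
                                     measure = c("jaccard", "hierarchical"),
                                     weights = NULL, min_weight = 0) {
  measure <- match.arg(measure)
  if (length(profiles) < 2L) stop("need at least 2 protein profiles")
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    stop("profiles must be uniquely named by accession")
  feats <- unique(unlist(profiles, use.names = FALSE))
  prots <- names(profiles)
  if (measure == "hierarchical") {
    if (is.null(weights)) stop("hierarchical measure requires term weights")
    if (anyNA(match(feats, names(weights))))
      stop("term(s) without a weight: ",
           paste(setdiff(feats, names(weights)), collapse = ", "))
    wt <- as.numeric(weights[feats])
  } else {
    wt <- rep(1, length(feats))
  }
  if (length(feats) == 0L)
    return(data.frame(src = character(0), dst = character(0),
                      weight = numeric(0)))
  ii <- rep.int(seq_along(profiles),
                vapply(profiles, function(x) length(unique(x)), integer(1)))
  jj <- match(unlist(lapply(profiles, unique), use.names = FALSE), feats)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(prots), length(feats)))
  sizes <- as.numeric(M %*% wt)            # weighted set size per protein
  inter <- Matrix::tcrossprod(M %*% Matrix::Diagonal(x = wt), M)
  inter <- methods::as(Matrix::triu(inter, k = 1), "TsparseMatrix")
  if (length(inter@x) == 0L)
    return(data.frame(src = character(0), dst = character(0),
                      weight = numeric(0)))
  i <- inter@i + 1L
  j <- inter@j + 1L
  sim <- inter@x / (sizes[i] + sizes[j] - inter@x)
  keep <- if (min_weight > 0) sim >= min_weight else sim > 0
  out <- data.frame(src = prots[i][keep], dst = prots[j][keep],
                    weight = sim[keep])
  out <- out[order(match(out$src, prots), match(out$dst, prots)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate similarity networks by unweighted averaging
#'
#' The consensus weight of a pair is the mean of its weights across the `n`
#' input networks, a pair missing from a network contributing 0.
#'
#' @param networks non-empty list of edge data frames (`src`, `dst`,
#'   `weight`, accession strings).
#' @param n_override optional denominator overriding `length(networks)`.
#' @return consensus network as an edge data frame.
#' @export
ua_integrate <- function(networks, n_override = NULL) {
  if (length(networks) == 0L) stop("no networks to integrate")
  n <- if (is.null(n_override)) length(networks) else n_override
  all_edges <- do.call(rbind, lapply(networks, function(net) {
    net <- as.data.frame(net)[, c("src", "dst", "weight")]
    lo <- pmin(net$src, net$dst)
    hi <- pmax(net$src, net$dst)
    data.frame(src = lo, dst = hi, weight = net$weight)
  }))
  if (nrow(all_edges) == 0L)
    return(data.frame(src = character(0), dst = character(0),
                      weight = numeric(0)))
  agg <- rowsum(all_edges$weight, paste0(all_edges$src, "\r", all_edges$dst))
  key <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(src = vapply(key, `[[`, character(1), 1L),
                    dst = vapply(key, `[[`, character(1), 2L),
                    weight = agg[, 1L] / n)
  out <- out[out$weight > 0, , drop = FALSE]
  out <- out[order(out$src, out$dst), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter functional classes by number of annotated proteins
#'
#' Keeps the terms annotated to at least `min_positives` (and at most
#' `max_positives`) distinct proteins. The lower bound of 20 reflects the
#' need for enough seed vertices to start a walk; an upper bound supports
#' restricting to specific classes (e.g. a 20..100 positives window).
#'
#' @param annotations data frame with columns `accession`, `term`.
#' @param min_positives minimum number of annotated proteins (>= 1).
#' @param max_positives optional maximum (default unlimited).
#' @return character vector of retained term ids.
#' @export
filter_classes <- function(annotations, min_positives, max_positives = Inf) {
  stopifnot(min_positives >= 1)
  ann <- unique(as.data.frame(annotations)[, c("accession", "term")])
  counts <- table(ann$term)
  names(counts)[counts >= min_positives & counts <= max_positives]
}

#' Read protein profiles from TSV
#'
#' Format: `accession<TAB>comma-separated-feature-ids`; an accession with no
#' features may have an empty second field.
#'
#' @param path input file.
#' @return named list accession -> character feature vector.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profiles file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  acc <- vapply(parts, `[[`, character(1), 1L)
  feats <- lapply(parts, function(p)
    if (length(p) < 2L || !nzchar(p[2L])) character(0)
    else strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  stats::setNames(feats, acc)
}

#' Write protein profiles to TSV
#' @param profiles named list accession -> feature vector.
#' @param path output file.
#' @export
write_profiles <- function(profiles, path) {
  writeLines(paste0(names(profiles), "\t",
                    vapply(profiles, paste, character(1), collapse = ",")),
             path)
  invisible(path)
}

#' Read a child/parent ontology edge table from TSV
#' @param path TSV with columns child, parent.
#' @return list with element `edges` (data frame `child`, `parent`).
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  edges <- utils::read.table(path, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE,
                             col.names = c("child", "parent"),
                             colClasses = "character")
  list(edges = edges)
}

#' Read a protein annotation table from TSV
#'
#' Format: `accession<TAB>term[<TAB>confidence]`. When a confidence column
#' is present, `min_confidence` drops lower-confidence annotations.
#'
#' @param path input file.
#' @param min_confidence optional numeric threshold on the third column.
#' @return data frame with columns `accession`, `term`.
#' @export
read_annotations <- function(path, min_confidence = NULL) {
  if (!file.exists(path)) stop("annotations file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, fill = TRUE,
                           header = FALSE)
  names(tab)[1:2] <- c("accession", "term")
  if (!is.null(min_confidence)) {
    if (ncol(tab) < 3L) stop("no confidence column in ", path)
    tab <- tab[as.numeric(tab[[3L]]) >= min_confidence, , drop = FALSE]
  }
  unique(tab[, c("accession", "term")])
}

#' Close an annotation table upward through the ontology
#'
#' Adds every ancestor of each annotated term (true-path closure), so that a
#' protein annotated to a specific term is also annotated to all more
#' general terms above it.
#'
#' @param annotations data frame `accession`, `term`.
#' @param ontology as accepted by [leaf_distance_weights()].
#' @return closed annotation data frame.
#' @export
propagate_ancestors <- function(annotations, ontology) {
  if (is.data.frame(ontology)) ontology <- list(edges = ontology)
  parents_of <- split(ontology$edges$parent, ontology$edges$child)
  close_one <- function(terms) {
    seen <- unique(terms)
    frontier <- seen
    while (length(frontier)) {
      nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
      nxt <- setdiff(nxt[!is.na(nxt)], seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  by_acc <- split(annotations$term, annotations$accession)
  closed <- lapply(by_acc, close_one)
  data.frame(accession = rep.int(names(closed), lengths(closed)),
             term = unlist(closed, use.names = FALSE))
}
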