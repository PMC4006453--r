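# Per-term evaluation of random-walk scores by stratified 5-fold
# cross-validation. Each fold's seeds are the training-fold positives only;
# held-out vertices are scored, pooled across folds, and summarized by the
# area under the ROC curve (Mann-Whitney form, midranks for ties) and by
# precision at fixed recall levels. Two methods are compared term-by-term
# with a paired two-sided Wilcoxon signed-rank test.

# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified k-fold assignment
#'
#' Assigns every vertex a fold index in `[0, F)` such that per-fold positive
#' counts differ by at most 1, and likewise for negatives. Deterministic
#' given `rng_seed`.
#'
#' @param labels logical (or 0/1) vector over vertices; `TRUE` = positive.
#' @param F number of folds.
#' @param rng_seed integer seed controlling the shuffle.
#' @return integer vector of fold indices in `[0, F)`.
#' @export
stratified_kfold <- function(labels, F, rng_seed) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos < F) stop("fewer positives (", n_pos, ") than folds (", F, ")")
  if (n_neg < F) stop("fewer negatives (", n_neg, ") than folds (", F, ")")
  folds <- integer(length(labels))
  with_seed(rng_seed, {
    pos <- sample(which(labels))
    neg <- sample(which(!labels))
  })
  folds[pos] <- (seq_along(pos) - 1L) %% F
  folds[neg] <- (seq_along(neg) - 1L) %% F
  folds
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midranks for tied scores:
#' `(wins + ties/2) / (P * N)` over all positive/negative pairs.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) labels, at least one of each class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0L || N == 0L)
    stop("AUC needs at least one positive and one negative")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
}

#' Precision at a recall level
#'
#' Vertices are ranked descending by score (ties broken ascending by vertex
#' index, deterministically); precision is measured at the smallest cutoff
#' whose recall reaches `R`.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) labels with at least one positive.
#' @param R recall level in `(0, 1]`.
#' @return precision in `[0, 1]`.
#' @export
precision_at_recall <- function(scores, labels, R) {
  labels <- as.logical(labels)
  if (R <= 0 || R > 1) stop("recall level must be in (0, 1]")
  P <- sum(labels)
  if (P == 0L) stop("no positives")
  ord <- order(-scores, seq_along(scores))
  tp <- cumsum(labels[ord])
  cutoff <- which(tp / P >= R)[1L]
  tp[cutoff] / cutoff
}

#' Cross-validate the random walk for one functional term
#'
#' Runs stratified `F`-fold cross-validation: per fold, the walk is seeded
#' with the training-fold positives only, and the held-out vertices' scores
#' are recorded. The pooled held-out score vector (every vertex scored
#' exactly once, while held out) is evaluated against the term's labels.
#'
#' @param graph a [weighted_graph()] (or `sharded_graph`).
#' @param annotations data frame `accession`, `term`.
#' @param term the term to evaluate.
#' @param F number of folds (default 5).
#' @param steps random-walk steps (default 1).
#' @param rng_seed integer seed for the fold shuffle.
#' @param recall_levels recall levels for precision (default 0.2 and 0.4).
#' @param eval_vertices optional accession vector; metrics are computed on
#'   this subset of held-out vertices only (used e.g. to score a single
#'   species inside a multi-species network).
#' @param renormalize passed to [run_rw()].
#' @return object of class `term_evaluation`: term, `auc`,
#'   `precision_at` (named by recall level), `n_pos`, fold assignment and
#'   pooled scores.
#' @export
cross_validate_term <- function(graph, annotations, term, F = 5L,
                                steps = 1L, rng_seed = 42L,
                                recall_levels = c(0.2, 0.4),
                                eval_vertices = NULL,
                                renormalize = FALSE) {
  ann <- annotations[annotations$term == term, , drop = FALSE]
  pos_ids <- resolve_ids(unique(ann$accession), graph)
  labels <- rep(FALSE, graph$n)
  labels[pos_ids + 1L] <- TRUE
  if (all(labels)) stop("term annotated on every vertex: no negatives")
  folds <- stratified_kfold(labels, F, rng_seed)
  pooled <- numeric(graph$n)
  fold_seeds <- vector("list", F)
  for (f in seq_len(F) - 1L) {
    train_pos <- which(labels & folds != f) - 1L
    if (length(train_pos) == 0L) stop("fold without training positives")
    scores <- run_rw(graph, train_pos, steps, renormalize = renormalize)
    held <- folds == f
    pooled[held] <- scores[held]
    fold_seeds[[f + 1L]] <- graph$id_map[train_pos + 1L]
  }
  if (!is.null(eval_vertices)) {
    idx <- resolve_ids(eval_vertices, graph) + 1L
    eval_scores <- pooled[idx]
    eval_labels <- labels[idx]
  } else {
    eval_scores <- pooled
    eval_labels <- labels
  }
  prec <- vapply(recall_levels, function(R)
    precision_at_recall(eval_scores, eval_labels, R), numeric(1))
  structure(list(term = term,
                 auc = auc_score(eval_scores, eval_labels),
                 precision_at = stats::setNames(prec,
                                                paste0("P@", recall_levels)),
                 n_pos = sum(eval_labels),
                 folds = folds,
                 fold_seeds = fold_seeds,
                 pooled_scores = stats::setNames(pooled, graph$id_map)),
            class = "term_evaluation")
}

#' @export
print.term_evaluation <- function(x, ...) {
  cat(sprintf("term %s: AUC = %.4f, %s (n_pos = %d)\n", x$term, x$auc,
              paste(names(x$precision_at),
                    sprintf("%.4f", x$precision_at),
                    sep = " = ", collapse = ", "),
              x$n_pos))
  invisible(x)
}

# exact null distribution of the signed-rank statistic W+ for given
# (mid)ranks: convolution over independent fair signs. Ranks are doubled so
# midranks (x.5) stay integral.
signed_rank_exact_p <- function(W, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  probs <- numeric(total + 1L)  # probs[v + 1] = P(2*W+ = v)
  probs[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), probs[seq_len(total + 1L - r)])
    probs <- (probs + shifted) / 2
  }
  W2 <- round(2 * W)
  mu2 <- total / 2
  # two-sided: double the smaller tail (including the observed value)
  lower <- sum(probs[seq_len(W2 + 1L)])
  upper <- sum(probs[(W2 + 1L):(total + 1L)])
  min(1, 2 * min(lower, upper))
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided test on paired per-term metrics. Zero differences are dropped;
#' ties among absolute differences get midranks. With at most 25 non-zero
#' pairs the p-value comes from the exact null distribution of the
#' signed-rank sum (computed by convolution, valid under ties); otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param metric_a,metric_b equal-length numeric vectors (e.g. per-term
#'   AUC of two methods).
#' @param alpha significance level (default 0.01).
#' @return list with `statistic` (W+, the sum of ranks of positive
#'   differences `b - a`), `p_value`, `significant`, `n_nonzero`.
#' @export
compare_paired <- function(metric_a, metric_b, alpha = 0.01) {
  if (length(metric_a) != length(metric_b))
    stop("paired vectors must have equal length")
  d <- metric_b - metric_a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, significant = FALSE,
                n_nonzero = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    p <- signed_rank_exact_p(W, r)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = W, p_value = p, significant = p < alpha, n_nonzero = n)
}
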