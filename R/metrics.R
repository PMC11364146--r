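# non-trivial clade keys (root excluded) of a ranked tree
nontrivial_keys <- function(t) {
  cl <- t$clusters
  n1 <- length(cl)
  if (n1 < 2L) return(character(0))
  vapply(cl[seq_len(n1 - 1L)], paste, character(1), collapse = ",")
}

#' Clade age error (CAE)
#'
#' Truth-referenced mean absolute height discrepancy: for each of the `n-1`
#' clades `C` of `truth` (including the root), the height of the most
#' recent common ancestor of `C` in `summary` is compared with the height
#' of `C` in `truth`; the mean absolute difference is returned (time
#' units).  The mrca lookup makes the measure total: clades of the truth
#' absent from the summary are matched to their smallest containing
#' summary clade.  `symmetrize = TRUE` averages the measure computed in
#' both directions.
#'
#' @param summary,truth `time_tree`s on the same taxon set.
#' @param symmetrize average with the roles of the trees swapped.
#' @return non-negative real.
#' @export
clade_age_error <- function(summary, truth, symmetrize = FALSE) {
  stopifnot(inherits(summary, "time_tree"), inherits(truth, "time_tree"))
  if (!identical(summary$topology$taxa, truth$topology$taxa))
    tc_stop_validation("trees are on different taxon sets")
  one_way <- function(s, tr) {
    mean(vapply(seq_along(tr$topology$clusters), function(i) {
      C <- tr$topology$clusters[[i]]
      abs(s$heights[mrca_rank(s$topology$clusters, C)] - tr$heights[i])
    }, numeric(1)))
  }
  if (symmetrize) (one_way(summary, truth) + one_way(truth, summary)) / 2
  else one_way(summary, truth)
}

#' Clade rank error (CRE)
#'
#' As [clade_age_error()] with heights replaced by ranks: the mean over the
#' truth's clades of the absolute difference between the clade's rank in
#' the truth and the rank of its mrca in the summary.
#'
#' @param summary,truth `ranked_tree`s (or `time_tree`s) on the same taxa.
#' @inheritParams clade_age_error
#' @return non-negative real (rank units).
#' @export
clade_rank_error <- function(summary, truth, symmetrize = FALSE) {
  s <- as_ranked(summary); tr <- as_ranked(truth)
  if (!identical(s$taxa, tr$taxa))
    tc_stop_validation("trees are on different taxon sets")
  one_way <- function(a, b) {
    mean(vapply(seq_along(b$clusters), function(i)
      abs(mrca_rank(a$clusters, b$clusters[[i]]) - i), numeric(1)))
  }
  if (symmetrize) (one_way(s, tr) + one_way(tr, s)) / 2 else one_way(s, tr)
}

#' Rooted Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' non-trivial clade
#' sets (leaves and the root clade excluded); an even integer in
#' `[0, 2(n-2)]`.  Rankings are ignored.
#'
#' @param a,b `ranked_tree`s (or `time_tree`s) on the same taxon set.
#' @return non-negative even integer.
#' @export
rf_distance <- function(a, b) {
  a <- as_ranked(a); b <- as_ranked(b)
  if (!identical(a$taxa, b$taxa))
    tc_stop_validation("trees are on different taxon sets")
  ka <- nontrivial_keys(a); kb <- nontrivial_keys(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Weighted Robinson-Foulds distance
#'
#' Sum over the union of the two trees' non-trivial clades of the absolute
#' difference of the clade's subtending branch length (parent height minus
#' node height), taking length 0 for a clade absent from a tree.  The root
#' has no parent branch and is excluded.
#'
#' @param a,b `time_tree`s on the same taxon set.
#' @return non-negative real (time units).
#' @export
weighted_rf <- function(a, b) {
  stopifnot(inherits(a, "time_tree"), inherits(b, "time_tree"))
  if (!identical(a$topology$taxa, b$topology$taxa))
    tc_stop_validation("trees are on different taxon sets")
  blen <- function(t) {
    cl <- t$topology$clusters
    n1 <- length(cl)
    if (n1 < 2L) return(stats::setNames(numeric(0), character(0)))
    lens <- vapply(seq_len(n1 - 1L), function(i) {
      parent <- i + 1L
      while (!all(cl[[i]] %in% cl[[parent]])) parent <- parent + 1L
      t$heights[parent] - t$heights[i]
    }, numeric(1))
    stats::setNames(lens, vapply(cl[seq_len(n1 - 1L)], paste, character(1),
                                 collapse = ","))
  }
  la <- blen(a); lb <- blen(b)
  keys <- union(names(la), names(lb))
  ga <- ifelse(keys %in% names(la), la[keys], 0)
  gb <- ifelse(keys %in% names(lb), lb[keys], 0)
  sum(abs(ga - gb))
}

#' Full comparison report between a summary tree and a reference tree
#'
#' Computes the clade age error (CAE), clade rank error (CRE), RNNI
#' distance and its normalisation by the maximum possible RNNI distance,
#' and the rooted Robinson-Foulds and weighted Robinson-Foulds distances.
#' CAE and CRE are truth-referenced (directional); the others are
#' symmetric.
#'
#' @param summary,truth `time_tree`s on the same taxon set.
#' @param metrics subset of `c("cae","cre","rnni","rf","wrf")` to compute;
#'   `rnni_normalized` accompanies `rnni`.
#' @return a `comparison_report` (named list of numeric values).
#' @export
compare_trees <- function(summary, truth,
                          metrics = c("cae", "cre", "rnni", "rf", "wrf")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list()
  if ("cae" %in% metrics) out$cae <- clade_age_error(summary, truth)
  if ("cre" %in% metrics) out$cre <- clade_rank_error(summary, truth)
  if ("rnni" %in% metrics) {
    out$rnni <- rnni_distance(summary, truth)
    diam <- rnni_diameter(length(as_ranked(truth)$taxa))
    out$rnni_normalized <- if (diam > 0) out$rnni / diam else 0
  }
  if ("rf" %in% metrics) out$rf <- rf_distance(summary, truth)
  if ("wrf" %in% metrics) out$wrf <- weighted_rf(summary, truth)
  structure(out, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Per-metric win counts between two summary methods
#'
#' For replicate triples (summary A, summary B, truth), tallies per metric
#' how often each summary is strictly closer to the truth (smaller error),
#' with ties counted separately.
#'
#' @param summaries_a,summaries_b,truths lists of `time_tree`s of equal
#'   length: replicate `i` compares `summaries_a[[i]]` and
#'   `summaries_b[[i]]` against `truths[[i]]`.
#' @inheritParams compare_trees
#' @return data frame with columns `metric`, `a_wins`, `b_wins`, `ties`.
#' @export
tally_wins <- function(summaries_a, summaries_b, truths,
                       metrics = c("cae", "cre", "rnni", "rf", "wrf")) {
  stopifnot(length(summaries_a) == length(truths),
            length(summaries_b) == length(truths))
  metrics <- match.arg(metrics, several.ok = TRUE)
  counts <- matrix(0L, nrow = length(metrics), ncol = 3L,
                   dimnames = list(metrics, c("a_wins", "b_wins", "ties")))
  for (i in seq_along(truths)) {
    ra <- compare_trees(summaries_a[[i]], truths[[i]], metrics)
    rb <- compare_trees(summaries_b[[i]], truths[[i]], metrics)
    for (mt in metrics) {
      d <- ra[[mt]] - rb[[mt]]
      col <- if (d < 0) "a_wins" else if (d > 0) "b_wins" else "ties"
      counts[mt, col] <- counts[mt, col] + 1L
    }
  }
  data.frame(metric = metrics, counts, row.names = NULL)
}

#' SoS-versus-score correlation diagnostics
#'
#' Probes how well the geometry of the treespace tracks an externally
#' supplied per-tree score (e.g. a log-likelihood).  Two modes:
#'
#' * `"sos_vs_score"`: one point per tree, pairing the tree's SoS value
#'   against the whole sample with its score;
#' * `"pairwise"`: one point per unordered tree pair, pairing the RNNI
#'   distance and the absolute score difference, each normalised by its
#'   largest observed value.
#'
#' @param sample a [tree_sample()] carrying `scores`.
#' @param mode `"sos_vs_score"` or `"pairwise"`.
#' @return a `correlation_report`: list with `pearson`, `spearman`,
#'   `n_points`, `mode` and the underlying points matrix `xy`.
#' @export
correlation_diagnostics <- function(sample, mode = c("sos_vs_score", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "tree_sample"))
  if (is.null(sample$scores))
    tc_stop_validation("sample has no scores")
  m <- length(sample$trees)
  if (m < 3L) tc_stop_validation("need at least 3 trees")
  if (mode == "sos_vs_score") {
    cache <- new.env(parent = emptyenv())
    x <- vapply(sample$trees, sos, numeric(1), sample = sample, cache = cache)
    y <- sample$scores
  } else {
    rts <- sample_ranked(sample)
    pairs <- utils::combn(m, 2L)
    d <- vapply(seq_len(ncol(pairs)), function(j)
      as.numeric(rnni_distance(rts[[pairs[1L, j]]], rts[[pairs[2L, j]]])),
      numeric(1))
    dy <- abs(sample$scores[pairs[1L, ]] - sample$scores[pairs[2L, ]])
    if (max(d) == 0 || max(dy) == 0)
      tc_stop_validation("constant distances or scores: correlation undefined")
    x <- d / max(d)
    y <- dy / max(dy)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0)
    tc_stop_validation("constant scores or SoS values: correlation undefined")
  structure(list(
    pearson = stats::cor(x, y, method = "pearson"),
    spearman = stats::cor(x, y, method = "spearman"),
    n_points = length(x), mode = mode, xy = cbind(x = x, y = y)
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation (%s, %d points): Pearson %.3f, Spearman %.3f\n",
              x$mode, x$n_points, x$pearson, x$spearman))
  invisible(x)
}
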