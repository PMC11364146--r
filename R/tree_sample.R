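#' Samples of trees on a shared taxon set
#'
#' A `tree_sample` is an ordered collection of `ranked_tree` / `time_tree`
#' objects on one common taxon set, optionally carrying a per-tree scalar
#' score (e.g. a log-likelihood or log-posterior supplied externally).
#'
#' @param trees list of `ranked_tree` or `time_tree` objects.
#' @param scores optional numeric vector, one score per tree.
#' @return an object of class `tree_sample`.
#' @export
tree_sample <- function(trees, scores = NULL) {
  if (!is.list(trees) || length(trees) < 1L)
    tc_stop_validation("a tree sample needs at least one tree")
  taxa <- as_ranked(trees[[1L]])$taxa
  for (i in seq_along(trees)) {
    ti <- trees[[i]]
    if (!inherits(ti, "ranked_tree") && !inherits(ti, "time_tree"))
      tc_stop_validation("element %d is not a ranked_tree or time_tree", i)
    if (!identical(as_ranked(ti)$taxa, taxa))
      tc_stop_validation("tree %d has a different taxon set", i)
  }
  if (!is.null(scores)) {
    scores <- as.numeric(scores)
    if (length(scores) != length(trees))
      tc_stop_validation("scores length (%d) must match number of trees (%d)",
                         length(scores), length(trees))
  }
  structure(list(trees = trees, scores = scores, taxa = taxa),
            class = "tree_sample")
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("Tree sample: %d trees on %d taxa%s\n",
              length(x$trees), length(x$taxa),
              if (is.null(x$scores)) "" else " (with scores)"))
  invisible(x)
}

# internal: sample trees coerced to ranked topologies
sample_ranked <- function(sample) lapply(sample$trees, as_ranked)
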