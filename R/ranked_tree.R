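#' Ranked phylogenetic trees
#'
#' A ranked tree is a rooted binary tree on `n` leaves whose internal nodes
#' carry unique ranks `1..n-1`, increasing towards the root: the rank records
#' the temporal order of the divergence events, with all leaves at rank 0.
#' The canonical encoding used throughout this package is the rank-ordered
#' *cluster sequence*: `clusters[[i]]` is the set of leaves descending from
#' the node of rank `i`, so `clusters[[n-1]]` is always the full taxon set.
#' The sequence is a laminar family (any two clusters are nested or
#' disjoint) and every cluster is the union of exactly two children.
#'
#' @param clusters list of length `n-1`; element `i` gives the leaf set of
#'   the rank-`i` node, either as a character vector of taxon labels or as
#'   integer indices into the sorted `taxa` vector.
#' @param taxa character vector of leaf labels; defaults to the sorted union
#'   of the cluster elements when clusters are given as labels.
#' @return an object of class `ranked_tree` with fields `taxa` (sorted
#'   character) and `clusters` (list of sorted integer vectors).
#' @examples
#' t <- ranked_tree(list(c("A", "B"), c("A", "B", "C")))
#' n_taxa(t)
#' @export
ranked_tree <- function(clusters, taxa = NULL) {
  if (!is.list(clusters) || length(clusters) < 1L)
    tc_stop_validation("clusters must be a non-empty list")
  if (is.null(taxa)) {
    if (!all(vapply(clusters, is.character, logical(1))))
      tc_stop_validation("taxa must be supplied when clusters are not label vectors")
    taxa <- unique(unlist(clusters, use.names = FALSE))
  }
  taxa <- sort(as.character(taxa))
  cl <- lapply(clusters, function(C) {
    if (is.character(C)) {
      idx <- match(C, taxa)
      if (anyNA(idx))
        tc_stop_validation("unknown taxon label(s): %s",
                           paste(C[is.na(idx)], collapse = ", "))
    } else {
      idx <- as.integer(C)
    }
    sort.int(unique(idx))
  })
  x <- new_ranked_tree(taxa, cl)
  validate_ranked_tree(x)
  x
}

# fast constructor, no validation (internal hot path)
new_ranked_tree <- function(taxa, clusters) {
  structure(list(taxa = taxa, clusters = clusters), class = "ranked_tree")
}

#' @rdname ranked_tree
#' @param x object to validate/query.
#' @export
validate_ranked_tree <- function(x) {
  n <- length(x$taxa)
  if (n < 2L) tc_stop_validation("a ranked tree needs at least 2 taxa")
  cl <- x$clusters
  if (length(cl) != n - 1L)
    tc_stop_validation("expected %d clusters for %d taxa, got %d",
                       n - 1L, n, length(cl))
  for (C in cl) {
    if (length(C) < 2L || any(C < 1L) || any(C > n) || anyDuplicated(C))
      tc_stop_validation("invalid cluster: must be >= 2 distinct taxon indices")
  }
  if (!identical(cl[[n - 1L]], seq_len(n)))
    tc_stop_validation("root cluster (rank %d) must contain all taxa", n - 1L)
  # laminar family
  for (i in seq_len(length(cl) - 1L)) {
    for (j in seq.int(i + 1L, length(cl))) {
      inter <- any(cl[[i]] %in% cl[[j]])
      if (inter && !all(cl[[i]] %in% cl[[j]]))
        tc_stop_validation("clusters of rank %d and %d overlap without nesting", i, j)
      if (length(cl[[i]]) >= length(cl[[j]]) && inter)
        tc_stop_validation("cluster of rank %d is not strictly inside rank %d", i, j)
    }
  }
  # binary: every cluster decomposes into exactly two children
  for (i in seq_along(cl)) {
    if (length(node_children(cl, i)) != 2L)
      tc_stop_validation("node of rank %d does not have exactly two children", i)
  }
  invisible(x)
}

# Children of the rank-i node: maximal lower-ranked clusters inside it plus
# uncovered leaves.  Returns a list of lists with fields type ("node"/"leaf"),
# rank or leaf, and members (integer vector).  Relies on laminarity.
node_children <- function(clusters, i) {
  rem <- clusters[[i]]
  kids <- list()
  j <- i - 1L
  while (j >= 1L && length(rem) > 0L) {
    cj <- clusters[[j]]
    if (cj[1L] %in% rem) {
      kids[[length(kids) + 1L]] <- list(type = "node", rank = j, members = cj)
      rem <- rem[!(rem %in% cj)]
    }
    j <- j - 1L
  }
  for (l in rem)
    kids[[length(kids) + 1L]] <- list(type = "leaf", leaf = l, members = l)
  kids
}

# children ordered canonically by smallest member index
node_children_sorted <- function(clusters, i) {
  kids <- node_children(clusters, i)
  kids[order(vapply(kids, function(k) k$members[1L], integer(1)))]
}

#' @rdname ranked_tree
#' @export
n_taxa <- function(x) UseMethod("n_taxa")

#' @export
n_taxa.ranked_tree <- function(x) length(x$taxa)

#' @export
n_taxa.time_tree <- function(x) length(x$topology$taxa)

# canonical string key (hashing / equality)
tree_key <- function(x) {
  cl <- if (inherits(x, "time_tree")) x$topology$clusters else x$clusters
  paste(vapply(cl, function(C) paste(C, collapse = ","), character(1)),
        collapse = ";")
}

#' Test equality of ranked trees
#'
#' Two ranked trees are equal iff they share the taxon set and have
#' identical rank-ordered cluster sequences.
#'
#' @param a,b `ranked_tree` or `time_tree` objects.
#' @return logical.
#' @export
trees_equal <- function(a, b) {
  a <- as_ranked(a); b <- as_ranked(b)
  identical(a$taxa, b$taxa) && identical(a$clusters, b$clusters)
}

#' Extract the ranked topology
#'
#' @param x a `ranked_tree` or `time_tree`.
#' @return a `ranked_tree`.
#' @export
as_ranked <- function(x) UseMethod("as_ranked")

#' @export
as_ranked.ranked_tree <- function(x) x

#' @export
as_ranked.time_tree <- function(x) x$topology

#' @export
print.ranked_tree <- function(x, ...) {
  cat(sprintf("Ranked tree on %d taxa\n", length(x$taxa)))
  for (i in seq_along(x$clusters))
    cat(sprintf("  rank %d: {%s}\n", i,
                paste(x$taxa[x$clusters[[i]]], collapse = ",")))
  invisible(x)
}

#' Time trees
#'
#' A time tree is a ranked tree together with strictly increasing internal
#' node heights: `heights[i]` is the time (measured from the leaves, which
#' sit at height 0 after ultrametricisation) of the node of rank `i`.
#'
#' @param topology a `ranked_tree`.
#' @param heights numeric vector of length `n-1`, strictly increasing,
#'   positive.
#' @return an object of class `time_tree`.
#' @export
time_tree <- function(topology, heights) {
  stopifnot(inherits(topology, "ranked_tree"))
  heights <- as.numeric(heights)
  n1 <- length(topology$clusters)
  if (length(heights) != n1)
    tc_stop_validation("need %d heights, got %d", n1, length(heights))
  if (any(!is.finite(heights)) || any(heights <= 0))
    tc_stop_validation("heights must be finite and positive")
  if (n1 > 1L && any(diff(heights) <= 0))
    tc_stop_validation("heights must be strictly increasing with rank")
  structure(list(topology = topology, heights = heights), class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("Time tree on %d taxa; root height %.6g\n",
              length(x$topology$taxa), max(x$heights)))
  invisible(x)
}
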