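#' RNNI moves
#'
#' The RNNI graph on ranked trees has two kinds of edges, both acting on a
#' pair of nodes with consecutive ranks `i`, `i+1`:
#'
#' * a **rank move** swaps the ranks of the two nodes; it is legal only when
#'   they are not in a parent-child relation, which for the cluster encoding
#'   means the two clusters are disjoint;
#' * an **NNI move** acts when the rank-`i` node is a child of the rank-`i+1`
#'   node: one of the two sister clades below the bottom node is moved to the
#'   other side of the top node, preserving all ranks.
#'
#' Moves are represented positionally: `rnni_move("rank", i)` or
#' `rnni_move("nni", i, variant)`.  The two children of the bottom node are
#' ordered by their smallest taxon index (`child_0`, `child_1`); `variant = v`
#' produces the tree whose new bottom cluster is `child_v` united with the
#' top node's other subtree.
#'
#' @param kind `"rank"` or `"nni"`.
#' @param rank the lower rank `i` of the pair acted on, `1 <= i <= n-2`.
#' @param variant 0 or 1 for NNI moves; ignored for rank moves.
#' @return an object of class `rnni_move`.
#' @export
rnni_move <- function(kind = c("rank", "nni"), rank, variant = NA_integer_) {
  kind <- match.arg(kind)
  rank <- as.integer(rank)
  variant <- as.integer(variant)
  if (kind == "nni" && (is.na(variant) || !variant %in% c(0L, 1L)))
    tc_stop_validation("an NNI move needs variant 0 or 1")
  structure(list(kind = kind, rank = rank, variant = variant),
            class = "rnni_move")
}

#' @export
print.rnni_move <- function(x, ...) {
  cat(format_move(x), "\n")
  invisible(x)
}

format_move <- function(mv) {
  if (mv$kind == "rank") sprintf("rank %d", mv$rank)
  else sprintf("nni %d %d", mv$rank, mv$variant)
}

#' Apply an RNNI move to a ranked tree
#'
#' @param t a `ranked_tree`.
#' @param mv an [rnni_move()].
#' @return the resulting `ranked_tree`.
#' @export
apply_move <- function(t, mv) {
  t <- as_ranked(t)
  cl <- t$clusters
  n1 <- length(cl)
  i <- mv$rank
  if (i < 1L || i > n1 - 1L)
    tc_stop_validation("move rank %d out of range [1, %d]", i, n1 - 1L)
  adjacent <- cl[[i]][1L] %in% cl[[i + 1L]]  # laminar: nested iff adjacent
  if (mv$kind == "rank") {
    if (adjacent)
      tc_stop_validation(
        "illegal rank move: nodes of ranks %d and %d are parent and child", i, i + 1L)
    tmp <- cl[[i]]; cl[[i]] <- cl[[i + 1L]]; cl[[i + 1L]] <- tmp
  } else {
    if (!adjacent)
      tc_stop_validation(
        "illegal NNI move: nodes of ranks %d and %d are not adjacent", i, i + 1L)
    Z <- cl[[i + 1L]][!(cl[[i + 1L]] %in% cl[[i]])]
    kids <- node_children_sorted(cl, i)
    keep <- kids[[mv$variant + 1L]]$members
    cl[[i]] <- sort.int(c(keep, Z))
  }
  new_ranked_tree(t$taxa, cl)
}

#' Enumerate the RNNI neighbourhood of a tree
#'
#' Returns every tree at RNNI distance exactly 1 from `t`.  The
#' neighbourhood has between `n-2` and `2(n-2)` members: each of the `n-2`
#' consecutive-rank pairs contributes one rank-move neighbour (if the pair
#' is unconnected) or two NNI neighbours (if parent and child).
#'
#' @param t a `ranked_tree` (or `time_tree`, whose topology is used).
#' @return a list of `ranked_tree`s, with the generating moves attached as
#'   attribute `"moves"`.
#' @export
rnni_neighbours <- function(t) {
  t <- as_ranked(t)
  cl <- t$clusters
  n1 <- length(cl)
  out <- list()
  mvs <- list()
  if (n1 < 2L) return(structure(out, moves = mvs))
  for (i in seq_len(n1 - 1L)) {
    lo <- cl[[i]]; hi <- cl[[i + 1L]]
    if (lo[1L] %in% hi) {
      Z <- hi[!(hi %in% lo)]
      kids <- node_children_sorted(cl, i)
      for (v in 0:1) {
        cl2 <- cl
        cl2[[i]] <- sort.int(c(kids[[v + 1L]]$members, Z))
        out[[length(out) + 1L]] <- new_ranked_tree(t$taxa, cl2)
        mvs[[length(mvs) + 1L]] <- rnni_move("nni", i, v)
      }
    } else {
      cl2 <- cl
      tmp <- cl2[[i]]; cl2[[i]] <- cl2[[i + 1L]]; cl2[[i + 1L]] <- tmp
      out[[length(out) + 1L]] <- new_ranked_tree(t$taxa, cl2)
      mvs[[length(mvs) + 1L]] <- rnni_move("rank", i)
    }
  }
  structure(out, moves = mvs)
}
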