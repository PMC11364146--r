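#' Shortest RNNI paths via FindPath
#'
#' FindPath computes a shortest path between two ranked trees in RNNI space
#' in O(n^2) time.  It processes the destination's clusters in rank order
#' `k = 1..n-2`; for each, the most recent common ancestor of cluster `C_k`
#' in the working tree is pulled down one rank at a time: by a rank move
#' when the nodes at ranks `r-1`, `r` are unconnected, and otherwise by the
#' unique NNI move on that edge after which the ancestor of `C_k` has rank
#' `r-1`.  Paths produced this way satisfy the *cluster property*: every
#' cluster shared by the endpoints is present in every intermediate tree.
#'
#' @param src,dst `ranked_tree`s (or `time_tree`s) on the same taxon set.
#' @return for `rnni_findpath`, an object of class `move_path`: a list with
#'   `trees` (the `d+1` trees along the path, starting at `src`) and `moves`
#'   (the `d` moves).  For `rnni_distance`, the integer path length.
#' @examples
#' a <- ranked_tree(list(c("A","B"), c("A","B","C"), c("A","B","C","D")))
#' b <- ranked_tree(list(c("C","D"), c("B","C","D"), c("A","B","C","D")))
#' rnni_distance(a, b)
#' @export
rnni_findpath <- function(src, dst) {
  res <- findpath_core(as_ranked(src), as_ranked(dst), collect = TRUE)
  structure(list(trees = res$trees, moves = res$moves), class = "move_path")
}

#' @rdname rnni_findpath
#' @export
rnni_distance <- function(src, dst) {
  findpath_core(as_ranked(src), as_ranked(dst), collect = FALSE)$count
}

#' @export
print.move_path <- function(x, ...) {
  cat(sprintf("RNNI path of length %d (%s)\n", length(x$moves),
              paste(vapply(x$moves, format_move, character(1)),
                    collapse = "; ")))
  invisible(x)
}

findpath_core <- function(src, dst, collect = FALSE) {
  if (!identical(src$taxa, dst$taxa))
    tc_stop_validation("trees are on different taxon sets")
  U <- src$clusters
  n1 <- length(U)
  count <- 0L
  trees <- if (collect) list(src)
  moves <- if (collect) list()
  if (n1 >= 2L) {
    for (k in seq_len(n1 - 1L)) {
      C <- dst$clusters[[k]]
      r <- k
      while (!all(C %in% U[[r]])) r <- r + 1L
      while (r > k) {
        below <- U[[r - 1L]]
        if (below[1L] %in% U[[r]]) {
          # parent-child pair: NNI move lowering the mrca of C to rank r-1
          Z <- U[[r]][!(U[[r]] %in% below)]
          kids <- node_children_sorted(U, r - 1L)
          inA <- any(C %in% kids[[1L]]$members)
          inB <- any(C %in% kids[[2L]]$members)
          if (inA == inB)
            stop("internal error in FindPath: no unique NNI variant lowers the mrca; please report")
          v <- if (inA) 0L else 1L
          U[[r - 1L]] <- sort.int(c(kids[[v + 1L]]$members, Z))
          mv <- rnni_move("nni", r - 1L, v)
        } else {
          tmp <- U[[r]]; U[[r]] <- U[[r - 1L]]; U[[r - 1L]] <- tmp
          mv <- rnni_move("rank", r - 1L)
        }
        count <- count + 1L
        r <- r - 1L
        if (collect) {
          trees[[length(trees) + 1L]] <- new_ranked_tree(src$taxa, U)
          moves[[length(moves) + 1L]] <- mv
        }
      }
      if (!identical(U[[k]], C))
        stop("internal error in FindPath: working tree missed a destination cluster; please report")
    }
  }
  list(count = count, trees = trees, moves = moves)
}

#' Serialise a move path
#'
#' Writes the trees along a path as a NEXUS trees block (one tree per step,
#' unit rank increments as branch lengths) together with a sidecar move
#' list, one move per line (`"rank i"` / `"nni i v"`).
#'
#' @param path a `move_path`.
#' @param file path for the NEXUS output.
#' @param moves_file path for the move list; defaults to `file` + ".moves".
#' @return invisibly, the move lines.
#' @export
write_move_path <- function(path, file, moves_file = paste0(file, ".moves")) {
  stopifnot(inherits(path, "move_path"))
  write_trees(tree_sample(path$trees), file, format = "nexus")
  lines <- vapply(path$moves, format_move, character(1))
  writeLines(lines, moves_file)
  invisible(lines)
}
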