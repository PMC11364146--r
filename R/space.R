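#' Exhaustive enumeration of RNNI treespace
#'
#' There are `n!(n-1)!/2^(n-1)` ranked trees on `n` leaves; each corresponds
#' to a unique sequence of `n-1` coalescence (pair-merge) events.
#' Enumeration and the BFS oracle built on it are only feasible for small
#' `n` (the space has 2700 trees at n = 6 and 56 700 at n = 7) and refuse
#' to run beyond `n = 7`.
#'
#' @param taxa character vector of leaf labels, `2 <= n <= 7`.
#' @return `enumerate_space`: list of all `ranked_tree`s on `taxa`.
#' @export
enumerate_space <- function(taxa) {
  taxa <- sort(as.character(taxa))
  n <- length(taxa)
  if (n < 2L) tc_stop_validation("need at least 2 taxa")
  if (n > 7L)
    tc_stop_validation(
      "refusing to enumerate RNNI space for n = %d: it has n!(n-1)!/2^(n-1) trees", n)
  out <- vector("list", ranked_tree_count(n))
  pos <- 0L
  recurse <- function(blocks, clusters) {
    L <- length(blocks)
    if (L == 1L) {
      pos <<- pos + 1L
      out[[pos]] <<- new_ranked_tree(taxa, clusters)
      return(invisible())
    }
    for (i in seq_len(L - 1L)) for (j in seq.int(i + 1L, L)) {
      merged <- sort.int(c(blocks[[i]], blocks[[j]]))
      recurse(c(blocks[-c(i, j)], list(merged)), c(clusters, list(merged)))
    }
  }
  recurse(as.list(seq_len(n)), list())
  out
}

#' @rdname enumerate_space
#' @param n number of leaves.
#' @return `ranked_tree_count`: the number of ranked trees on `n` leaves.
#' @export
ranked_tree_count <- function(n) {
  # n!(n-1)!/2^(n-1), computed incrementally: prod over k=2..n of choose(k,2)
  if (n < 2) return(if (n == 1) 1 else 0)
  prod(choose(seq.int(2L, n), 2L))
}

#' RNNI graph and breadth-first-search distance oracle
#'
#' Builds the full RNNI graph on a small taxon set (vertices: all ranked
#' trees, edges: single moves, via [rnni_neighbours()]) and computes exact
#' shortest-path lengths with \pkg{igraph} breadth-first search.  This is
#' an independent correctness oracle for [rnni_distance()]; it does not use
#' FindPath.
#'
#' @param taxa character vector of leaf labels (`n <= 7`).
#' @return `rnni_graph`: a list with `trees`, `keys`, and the `igraph`
#'   object `graph` (vertex i of the graph is `trees[[i]]`).
#' @export
rnni_graph <- function(taxa) {
  trees <- enumerate_space(taxa)
  keys <- vapply(trees, tree_key, character(1))
  idx <- seq_along(trees)
  names(idx) <- keys
  edges <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    js <- vapply(rnni_neighbours(trees[[i]]),
                 function(nb) idx[[tree_key(nb)]], integer(1))
    js <- js[js > i]
    edges[[i]] <- rbind(rep.int(i, length(js)), js)
  }
  g <- igraph::make_graph(as.integer(unlist(edges)), n = length(trees),
                          directed = FALSE)
  list(trees = trees, keys = keys, index = idx, graph = g)
}

#' @rdname rnni_graph
#' @param src,dst `ranked_tree`s on the same small taxon set.
#' @param graph optional precomputed [rnni_graph()] on that taxon set (built
#'   on the fly when missing).
#' @return `bfs_distance`: exact shortest-path length (integer).
#' @export
bfs_distance <- function(src, dst, graph = NULL) {
  src <- as_ranked(src); dst <- as_ranked(dst)
  if (!identical(src$taxa, dst$taxa))
    tc_stop_validation("trees are on different taxon sets")
  if (is.null(graph)) graph <- rnni_graph(src$taxa)
  i <- graph$index[[tree_key(src)]]
  j <- graph$index[[tree_key(dst)]]
  as.integer(igraph::distances(graph$graph, v = i, to = j))
}

# cache of BFS-certified diameters (filled lazily, n <= 7)
.diameter_cache <- new.env(parent = emptyenv())

# exact diameter by all-pairs BFS on the full graph
diameter_bfs <- function(n) {
  key <- as.character(n)
  if (!is.null(.diameter_cache[[key]])) return(.diameter_cache[[key]])
  g <- rnni_graph(paste0("t", seq_len(n)))
  d <- as.integer(igraph::diameter(g$graph, directed = FALSE, unconn = FALSE))
  .diameter_cache[[key]] <- d
  d
}

#' Maximum possible RNNI distance on n leaves
#'
#' Used to normalise RNNI distances to `[0, 1]`.  For `n <= 6` the value is
#' certified by exhaustive all-pairs BFS over the full treespace (and
#' cached).  For larger `n` the closed form `(n-1)(n-2)/2` is used; it is
#' validated against the BFS values for `n = 3..6` in the package test
#' suite, which gates its use.
#'
#' @param n number of leaves, `n >= 2`.
#' @param method `"auto"` (BFS-certified for `n <= 6`, closed form above),
#'   `"closed_form"`, or `"bfs"` (refuses `n > 7`).
#' @return integer diameter; 0 for `n = 2`.
#' @export
rnni_diameter <- function(n, method = c("auto", "closed_form", "bfs")) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (n < 2L) tc_stop_validation("n must be >= 2")
  if (n == 2L) return(0L)
  cf <- as.integer((n - 1L) * (n - 2L) / 2L)
  switch(method,
    closed_form = cf,
    bfs = diameter_bfs(n),
    auto = if (n <= 6L) diameter_bfs(n) else cf)
}
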