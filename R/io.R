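#' Read a sample of time trees from Newick or NEXUS
#'
#' Parses rooted binary trees with branch lengths from a plain Newick file
#' (one tree per line) or a NEXUS trees block (BEAST/BEAST2 dialect;
#' translate tables are resolved to taxon labels by \pkg{ape}).  Each tree
#' is ultrametricised by extending leaf branches to the maximum root-to-leaf
#' depth, so leaves sit at height 0, and internal nodes are ranked by their
#' heights.
#'
#' @param source a file path, or a character scalar/vector holding the file
#'   content directly.
#' @param format `"newick"` or `"nexus"`.
#' @param burnin fraction in `[0, 1)`; the first `floor(burnin * m)` trees
#'   are discarded before any computation.
#' @param tie_policy how to rank tied node heights: `"error"` aborts,
#'   `"perturb"` breaks ties by the lexicographically smallest leaf label of
#'   each cluster (nudging heights by a tiny epsilon) with a warning.
#' @return a [tree_sample()] of `time_tree` objects, in file order.
#' @export
parse_trees <- function(source, format = c("newick", "nexus"), burnin = 0,
                        tie_policy = c("error", "perturb")) {
  format <- match.arg(format)
  tie_policy <- match.arg(tie_policy)
  if (!is.numeric(burnin) || length(burnin) != 1L || burnin < 0 || burnin >= 1)
    tc_stop_validation("burnin must be a single fraction in [0, 1)")
  is_path <- length(source) == 1L && !grepl("[(\n#]", source) && file.exists(source)
  phys <- if (format == "newick") {
    text <- if (is_path) readLines(source, warn = FALSE) else
      unlist(strsplit(source, "\n", fixed = TRUE))
    text <- trimws(text)
    text <- text[nzchar(text) & !startsWith(text, "[")]
    if (length(text) == 0L) tc_stop_io("no trees found in input")
    lapply(seq_along(text), function(i) {
      phy <- tryCatch(ape::read.tree(text = text[[i]]),
                      error = function(e) NULL, warning = function(w) NULL)
      if (is.null(phy) || !inherits(phy, "phylo"))
        tc_stop_io("tree %d: malformed Newick string", i)
      phy
    })
  } else {
    path <- if (is_path) source else {
      tf <- tempfile(fileext = ".nex")
      writeLines(source, tf)
      tf
    }
    res <- tryCatch(ape::read.nexus(path), error = function(e)
      tc_stop_io("failed to parse NEXUS input: %s", conditionMessage(e)))
    if (inherits(res, "phylo")) list(res)
    else lapply(seq_along(res), function(i) res[[i]])  # restores TipLabel
  }
  if (length(phys) == 0L) tc_stop_io("no trees found in input")
  drop <- floor(burnin * length(phys))
  if (drop > 0L) phys <- phys[-seq_len(drop)]
  trees <- lapply(seq_along(phys), function(i)
    phylo_to_time_tree(phys[[i]], tie_policy = tie_policy, index = i))
  tree_sample(trees)
}

# Convert an ape phylo (rooted, binary, with edge lengths) to a time_tree.
# Leaf branches are implicitly extended so all leaves are at height 0.
phylo_to_time_tree <- function(phy, tie_policy = "error", index = NA) {
  where <- if (is.na(index)) "tree" else sprintf("tree %d", index)
  if (!inherits(phy, "phylo")) tc_stop_validation("%s: not a phylo object", where)
  n <- length(phy$tip.label)
  if (n < 2L) tc_stop_validation("%s: fewer than 2 taxa", where)
  if (is.null(phy$edge.length))
    tc_stop_validation("%s: branch lengths are required", where)
  if (any(phy$edge.length < 0))
    tc_stop_validation("%s: negative branch length", where)
  if (!ape::is.rooted(phy)) tc_stop_validation("%s: tree is not rooted", where)
  if (phy$Nnode != n - 1L)
    tc_stop_validation("%s: tree is not binary (%d internal nodes for %d taxa)",
                       where, phy$Nnode, n)
  taxa <- sort(phy$tip.label)
  if (anyDuplicated(taxa)) tc_stop_validation("%s: duplicated taxon labels", where)
  depths <- ape::node.depth.edgelength(phy)
  maxd <- max(depths[seq_len(n)])
  # descendant taxon-index sets per node, postorder accumulation
  desc <- vector("list", n + phy$Nnode)
  tipidx <- match(phy$tip.label, taxa)
  for (i in seq_len(n)) desc[[i]] <- tipidx[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  internal <- seq.int(n + 1L, n + phy$Nnode)
  heights <- maxd - depths[internal]
  clus <- lapply(desc[internal], sort.int)
  rank_clades(taxa, clus, heights, tie_policy, where)
}

# Order unranked (cluster, height) pairs into a time_tree under a tie policy.
rank_clades <- function(taxa, clusters, heights, tie_policy, where = "tree") {
  n1 <- length(clusters)
  if (anyDuplicated(heights)) {
    if (tie_policy == "error")
      tc_stop_validation("%s: tied internal node heights (use tie_policy = \"perturb\")",
                         where)
    # deterministic total order: height, then smallest leaf label of cluster
    minlab <- vapply(clusters, function(C) taxa[min(C)], character(1))
    ord <- order(heights, minlab)
    eps <- 1e-9 * max(heights, 1)
    heights <- heights[ord]
    for (i in seq_len(n1 - 1L)) {
      if (heights[i + 1L] <= heights[i]) heights[i + 1L] <- heights[i] + eps
    }
    warning(sprintf("%s: tied node heights broken deterministically", where),
            call. = FALSE)
    clusters <- clusters[ord]
  } else {
    ord <- order(heights)
    clusters <- clusters[ord]
    heights <- heights[ord]
  }
  topo <- new_ranked_tree(taxa, clusters)
  validate_ranked_tree(topo)
  time_tree(topo, heights)
}

#' Rank a time tree's topology
#'
#' For a `time_tree` this simply extracts the stored topology.  For an
#' \pkg{ape} `phylo` object the internal nodes are ranked by height
#' (ultrametricising first), applying the tie policy.
#'
#' @param t a `time_tree` or `phylo`.
#' @inheritParams parse_trees
#' @return a `ranked_tree`.
#' @export
to_ranked <- function(t, tie_policy = c("error", "perturb")) {
  tie_policy <- match.arg(tie_policy)
  if (inherits(t, "ranked_tree")) return(t)
  if (inherits(t, "time_tree")) return(t$topology)
  if (inherits(t, "phylo"))
    return(phylo_to_time_tree(t, tie_policy = tie_policy)$topology)
  tc_stop_validation("cannot rank an object of class %s", class(t)[1])
}

#' Make a tree ultrametric by extending leaf branches
#'
#' Every terminal branch is lengthened so that all root-to-leaf depths equal
#' the maximum depth; internal node times relative to the root are unchanged.
#'
#' @param phy an \pkg{ape} `phylo` with branch lengths (a `time_tree` is
#'   returned unchanged: it is ultrametric by construction).
#' @return object of the same class as the input.
#' @export
ultrametricize <- function(phy) {
  if (inherits(phy, "time_tree")) return(phy)
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) tc_stop_validation("branch lengths are required")
  if (any(phy$edge.length < 0)) tc_stop_validation("negative branch length")
  n <- length(phy$tip.label)
  d <- ape::node.depth.edgelength(phy)
  maxd <- max(d[seq_len(n)])
  term <- match(seq_len(n), phy$edge[, 2L])
  phy$edge.length[term] <- phy$edge.length[term] + (maxd - d[seq_len(n)])
  phy
}

# ---- writing ---------------------------------------------------------------

fmt_num <- function(x) sprintf("%.12g", x)

# Newick string from clusters + heights (children ordered by smallest taxon).
build_newick <- function(topology, heights, labels = topology$taxa) {
  cl <- topology$clusters
  node_str <- function(rank) {
    kids <- node_children_sorted(cl, rank)
    parts <- vapply(kids, function(k) {
      if (k$type == "leaf")
        paste0(labels[k$leaf], ":", fmt_num(heights[rank]))
      else
        paste0(node_str(k$rank), ":", fmt_num(heights[rank] - heights[k$rank]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(node_str(length(cl)), ";")
}

tree_to_newick <- function(x, labels = NULL) {
  if (inherits(x, "time_tree")) {
    topo <- x$topology; h <- x$heights
  } else {
    topo <- x; h <- seq_along(x$clusters)  # unit rank increments
  }
  build_newick(topo, h, labels %||% topo$taxa)
}

#' Write trees to Newick or NEXUS text
#'
#' Time trees are written with their branch lengths; bare ranked trees are
#' written with unit rank increments as branch lengths (flagged by a comment
#' in NEXUS output).  Output is round-trip safe: `parse_trees(write_trees(x))`
#' recovers identical cluster sequences and heights to within 1e-9.
#'
#' The NEXUS writer emits a taxa block and a translate table and,
#' deliberately, no timestamp, so identical inputs give byte-identical files.
#'
#' @param x a `tree_sample`, `time_tree` or `ranked_tree`.
#' @param file optional path; when `NULL` the text is returned.
#' @param format `"newick"` or `"nexus"`.
#' @return invisibly (or visibly when `file` is `NULL`) the character vector
#'   of output lines.
#' @export
write_trees <- function(x, file = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (inherits(x, "ranked_tree") || inherits(x, "time_tree"))
    x <- tree_sample(list(x))
  stopifnot(inherits(x, "tree_sample"))
  taxa <- x$taxa
  ranked_only <- any(!vapply(x$trees, inherits, logical(1), "time_tree"))
  lines <- if (format == "newick") {
    vapply(x$trees, tree_to_newick, character(1))
  } else {
    n <- length(taxa)
    hdr <- c("#NEXUS", "",
             if (ranked_only) "[ranked topologies: branch lengths are unit rank increments]",
             "BEGIN TAXA;",
             sprintf("\tDIMENSIONS NTAX=%d;", n),
             "\tTAXLABELS",
             paste0("\t\t", taxa),
             "\t;", "END;", "", "BEGIN TREES;", "\tTRANSLATE")
    trl <- sprintf("\t\t%d %s%s", seq_len(n), taxa,
                   c(rep(",", n - 1L), ""))
    body <- vapply(seq_along(x$trees), function(i)
      sprintf("\tTREE tree_%d = [&R] %s", i,
              tree_to_newick(x$trees[[i]], labels = as.character(seq_len(n)))),
      character(1))
    c(hdr, trl, "\t;", body, "END;")
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
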