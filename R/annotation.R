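# mrca rank of a taxon-index set C in a ranked tree's cluster sequence
mrca_rank <- function(clusters, C) {
  for (r in seq_along(clusters)) {
    if (length(clusters[[r]]) >= length(C) && all(C %in% clusters[[r]]))
      return(r)
  }
  tc_stop_validation("mrca lookup failed (taxon indices out of range?)")
}

# frequency in the sample of each cluster of `topology` (by clade identity,
# ranks ignored)
clade_support <- function(topology, sample) {
  keys <- vapply(topology$clusters, paste, character(1), collapse = ",")
  counts <- stats::setNames(numeric(length(keys)), keys)
  for (s in sample_ranked(sample)) {
    sk <- unique(vapply(s$clusters, paste, character(1), collapse = ","))
    hit <- keys %in% sk
    counts[hit] <- counts[hit] + 1
  }
  counts / length(sample$trees)
}

new_annotated_summary <- function(topology, heights, method, support,
                                  monotonic, extra = list()) {
  structure(c(list(topology = topology, heights = heights, method = method,
                   support = support, monotonic = monotonic,
                   tree = if (monotonic) time_tree(topology, heights)),
              extra),
            class = "annotated_summary")
}

#' @export
print.annotated_summary <- function(x, ...) {
  cat(sprintf("Annotated summary (%s) on %d taxa; root height %.6g%s\n",
              x$method, length(x$topology$taxa), max(x$heights),
              if (x$monotonic) "" else " [heights violate rank order]"))
  invisible(x)
}

#' Rank-height annotation of a ranked summary tree
#'
#' Annotates a ranked topology with node heights by averaging the sample's
#' *t-coordinates*: the height assigned to the rank-`i` node is the
#' arithmetic mean over the sample of each tree's rank-`i` node height,
#' irrespective of the leaf labels below that node.  Because column means
#' of strictly increasing height vectors are strictly increasing, the
#' annotation never reorders the nodes: the ranked topology is preserved
#' exactly, which is the point of this scheme (clade-based annotators can
#' change the ranking).
#'
#' @param topology the ranked summary topology.
#' @param sample a [tree_sample()] of `time_tree`s (ultrametric by
#'   construction; route non-ultrametric input through [parse_trees()] /
#'   [ultrametricize()] first).
#' @return an `annotated_summary` with `method = "rank_heights"`, the
#'   annotated `time_tree` in `$tree`, and per-clade posterior support
#'   frequencies in `$support`.
#' @export
annotate_rank_heights <- function(topology, sample) {
  topology <- as_ranked(topology)
  stopifnot(inherits(sample, "tree_sample"))
  if (!identical(topology$taxa, sample$taxa))
    tc_stop_validation("topology and sample are on different taxon sets")
  if (!all(vapply(sample$trees, inherits, logical(1), "time_tree")))
    tc_stop_validation("rank-height annotation needs time trees with heights")
  H <- do.call(rbind, lapply(sample$trees, function(t) t$heights))
  heights <- colMeans(H)
  new_annotated_summary(topology, heights, "rank_heights",
                        clade_support(topology, sample), monotonic = TRUE)
}

#' Maximum clade credibility topology
#'
#' The MCC baseline: among the distinct rooted topologies occurring in the
#' sample, returns the one maximising the product of the posterior
#' frequencies of its non-trivial clades (equivalently the sum of log
#' frequencies, which is what `score` reports; the root clade and leaves
#' have frequency 1 and are excluded, which does not change the argmax).
#' Ties are broken towards the earliest occurrence in the sample and
#' flagged.
#'
#' @param sample a [tree_sample()].
#' @return list with `tree` (the winning topology as first sampled, with
#'   its ranking), `score` (sum of log clade frequencies, `<= 0`), `index`
#'   (first occurrence), `tied` (logical) and `clade_freq` (named vector of
#'   clade frequencies over the whole sample).
#' @export
mcc_topology <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  rts <- sample_ranked(sample)
  m <- length(rts)
  n1 <- length(rts[[1L]]$clusters)
  # clade frequencies over the sample
  all_keys <- lapply(rts, function(t)
    vapply(t$clusters, paste, character(1), collapse = ","))
  freq <- table(unlist(lapply(all_keys, unique))) / m
  # candidate topologies = distinct clade sets, keyed order-independently
  topo_key <- vapply(all_keys, function(k) paste(sort(k), collapse = "|"),
                     character(1))
  first_idx <- which(!duplicated(topo_key))
  root_key <- paste(seq_along(sample$taxa), collapse = ",")
  scores <- vapply(first_idx, function(i) {
    k <- setdiff(all_keys[[i]], root_key)  # non-trivial clades only
    sum(log(as.numeric(freq[k])))
  }, numeric(1))
  best <- max(scores)
  winners <- first_idx[scores >= best - 1e-12]
  idx <- min(winners)
  list(tree = rts[[idx]], score = best, index = idx,
       tied = length(winners) > 1L,
       clade_freq = stats::setNames(as.numeric(freq), names(freq)))
}

#' Common-ancestor height annotation (MCC baseline)
#'
#' Annotates each internal node of `topology` with the mean, over all
#' sample trees, of the height of the most recent common ancestor of that
#' node's leaf set in the sample tree.  This is the conventional
#' common-ancestor annotation; it ignores the topology's ranking, and the
#' resulting heights can violate the rank order (in which case `monotonic`
#' is `FALSE` and `$tree` is absent) - the behaviour rank-height annotation
#' is designed to avoid.
#'
#' @param topology the summary topology (`ranked_tree`).
#' @param sample a [tree_sample()] of `time_tree`s.
#' @return an `annotated_summary` with `method = "mcc_common_ancestor"`.
#' @export
common_ancestor_heights <- function(topology, sample) {
  topology <- as_ranked(topology)
  stopifnot(inherits(sample, "tree_sample"))
  if (!identical(topology$taxa, sample$taxa))
    tc_stop_validation("topology and sample are on different taxon sets")
  if (!all(vapply(sample$trees, inherits, logical(1), "time_tree")))
    tc_stop_validation("common-ancestor annotation needs time trees with heights")
  heights <- vapply(topology$clusters, function(C) {
    mean(vapply(sample$trees, function(s)
      s$heights[mrca_rank(s$topology$clusters, C)], numeric(1)))
  }, numeric(1))
  monotonic <- all(diff(heights) > 0) && all(heights > 0)
  if (!monotonic)
    warning("common-ancestor heights violate the summary tree's rank order",
            call. = FALSE)
  new_annotated_summary(topology, heights, "mcc_common_ancestor",
                        clade_support(topology, sample), monotonic = monotonic)
}

#' Write an annotated summary tree
#'
#' NEXUS output carries per-node BEAST-style comment fields
#' (`[&posterior=..,height=..]`) on internal nodes; Newick output carries
#' heights only.  Annotated NEXUS is export-oriented (viewers such as
#' FigTree read the comments; plain NEXUS parsers may not).
#'
#' @param x an `annotated_summary`.
#' @param file optional output path.
#' @param format `"newick"` or `"nexus"`.
#' @return invisibly (or visibly when `file` is `NULL`) the output lines.
#' @export
write_annotated <- function(x, file = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "annotated_summary"))
  topo <- x$topology; h <- x$heights
  taxa <- topo$taxa
  if (format == "newick") {
    lines <- build_newick(topo, h)
  } else {
    n <- length(taxa)
    node_str <- function(rank) {
      kids <- node_children_sorted(topo$clusters, rank)
      parts <- vapply(kids, function(k) {
        if (k$type == "leaf")
          paste0(k$leaf, ":", fmt_num(h[rank]))
        else
          paste0(node_str(k$rank), ":", fmt_num(h[rank] - h[k$rank]))
      }, character(1))
      paste0("(", paste(parts, collapse = ","),
             sprintf(")[&posterior=%s,height=%s]",
                     fmt_num(x$support[rank]), fmt_num(h[rank])))
    }
    nwk <- paste0(node_str(length(topo$clusters)), ";")
    lines <- c("#NEXUS", "",
               "BEGIN TAXA;",
               sprintf("\tDIMENSIONS NTAX=%d;", n),
               "\tTAXLABELS", paste0("\t\t", taxa), "\t;", "END;", "",
               "BEGIN TREES;", "\tTRANSLATE",
               sprintf("\t\t%d %s%s", seq_len(n), taxa,
                       c(rep(",", n - 1L), "")),
               "\t;",
               sprintf("\tTREE summary_%s = [&R] %s", x$method, nwk),
               "END;")
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
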