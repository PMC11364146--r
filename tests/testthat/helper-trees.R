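# Shared fixtures and small-space oracles.  Graphs are cached per session:
# building the full RNNI graph is the exhaustive BFS oracle used throughout.

tx <- function(n) paste0("t", seq_len(n))

# caterpillar: ((..((l1,l2),l3)..,lk)
caterpillar_tree <- function(labels) {
  ranked_tree(lapply(seq.int(2L, length(labels)), function(k) labels[1:k]))
}

balanced4_tree <- function(labels = c("A", "B", "C", "D")) {
  ranked_tree(list(labels[1:2], labels[3:4], labels))
}

.graph_cache <- new.env(parent = emptyenv())
get_graph <- function(n) {
  key <- as.character(n)
  if (is.null(.graph_cache[[key]]))
    .graph_cache[[key]] <- rnni_graph(tx(n))
  .graph_cache[[key]]
}

# Frozen two-basin instance on 5 taxa: a 6-tree sample for which the
# Centroid descent has several distinct local optima (verified exhaustively
# when first constructed; re-verified by the acceptance test).
two_basin_sample <- function() {
  tree_sample(list(
    ranked_tree(list(c("t1","t3"), c("t1","t3","t5"), c("t2","t4"),
                     c("t1","t2","t3","t4","t5"))),
    ranked_tree(list(c("t3","t5"), c("t1","t3","t5"), c("t1","t3","t4","t5"),
                     c("t1","t2","t3","t4","t5"))),
    ranked_tree(list(c("t3","t4"), c("t3","t4","t5"), c("t2","t3","t4","t5"),
                     c("t1","t2","t3","t4","t5"))),
    ranked_tree(list(c("t2","t5"), c("t1","t4"), c("t1","t3","t4"),
                     c("t1","t2","t3","t4","t5"))),
    ranked_tree(list(c("t1","t4"), c("t2","t3"), c("t1","t4","t5"),
                     c("t1","t2","t3","t4","t5"))),
    ranked_tree(list(c("t1","t5"), c("t2","t4"), c("t1","t2","t4","t5"),
                     c("t1","t2","t3","t4","t5")))))
}

# starts from which the descent reaches the global optimum (SoS 61) and a
# strictly worse local optimum (SoS 88) on two_basin_sample()
two_basin_start_global <- function() {
  ranked_tree(list(c("t1","t2"), c("t3","t4"), c("t1","t2","t5"),
                   c("t1","t2","t3","t4","t5")))
}
two_basin_start_local <- function() {
  ranked_tree(list(c("t1","t2"), c("t3","t5"), c("t1","t2","t4"),
                   c("t1","t2","t3","t4","t5")))
}
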