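#' Uniform random ranked trees
#'
#' Draws a ranked tree uniformly over all `n!(n-1)!/2^(n-1)` ranked
#' topologies by iterated uniform pair-merging: starting from the `n`
#' leaves, at each of the `n-1` merge events an unordered pair of extant
#' lineages is chosen uniformly and merged (the k-th merge receives rank
#' k).  Every ranked tree corresponds to exactly one merge sequence, each
#' with probability `prod_k 1/choose(k, 2)`, so the distribution is exactly
#' uniform.  This is also the distribution of ranked topologies under the
#' coalescent.
#'
#' @param taxa character vector of leaf labels (`n >= 2`).
#' @param seed optional integer; when given, the draw is made under a
#'   private RNG stream and is bit-reproducible.
#' @return a `ranked_tree`.
#' @export
random_ranked_tree <- function(taxa, seed = NULL) {
  taxa <- sort(as.character(taxa))
  n <- length(taxa)
  if (n < 2L) tc_stop_validation("need at least 2 taxa")
  draw <- function() {
    blocks <- as.list(seq_len(n))
    clusters <- vector("list", n - 1L)
    for (k in seq_len(n - 1L)) {
      pair <- sample.int(length(blocks), 2L)
      merged <- sort.int(c(blocks[[pair[1L]]], blocks[[pair[2L]]]))
      clusters[[k]] <- merged
      blocks <- c(blocks[-pair], list(merged))
    }
    new_ranked_tree(taxa, clusters)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Random-walk tree samples around a focal tree
#'
#' Generates `m` trees independently, each obtained from `centre` by `s`
#' uniform single moves on the current tree (an unbiased nearest-neighbour
#' walk in RNNI space), where `s` is fixed (`steps`) or Poisson(`lambda`)
#' per tree.  Every output tree is within RNNI distance `s` of the centre;
#' moves can cancel, so realised distances are typically smaller.  Emulates
#' a posterior sample concentrated around a focal topology.  With
#' `stay_prob > 0` each step is skipped with that probability (lazy walk).
#'
#' @param centre focal `ranked_tree`.
#' @param m number of trees.
#' @param steps fixed number of moves per tree (ignored when `lambda` is
#'   given).
#' @param lambda Poisson mean number of moves per tree.
#' @param stay_prob per-step probability of staying put.
#' @param seed integer seed.
#' @return a [tree_sample()] of `ranked_tree`s.
#' @export
random_walk_sample <- function(centre, m, steps = NULL, lambda = NULL,
                               stay_prob = 0, seed = 1L) {
  centre <- as_ranked(centre)
  if (m < 1L) tc_stop_validation("m must be >= 1")
  if (is.null(steps) && is.null(lambda))
    tc_stop_validation("give either steps (fixed) or lambda (Poisson)")
  with_seed(seed, {
    trees <- vector("list", m)
    for (i in seq_len(m)) {
      s <- if (!is.null(lambda)) stats::rpois(1L, lambda) else as.integer(steps)
      cur <- centre
      if (s > 0L) for (j in seq_len(s)) {
        if (stay_prob > 0 && stats::runif(1L) < stay_prob) next
        nbs <- rnni_neighbours(cur)
        cur <- nbs[[sample.int(length(nbs), 1L)]]
      }
      trees[[i]] <- cur
    }
    tree_sample(trees)
  })
}

#' Height-jittered samples on a fixed topology
#'
#' Produces `m` time trees sharing `topology`, with the rank-`i` node at
#' base height `i` plus truncated Gaussian noise: noise vectors violating
#' the strict height ordering (or positivity) are resampled wholesale, so
#' every emitted tree is a valid time tree.  Used to exercise the
#' rank-height annotation.
#'
#' @param topology a `ranked_tree`.
#' @param m number of trees.
#' @param noise_sd standard deviation of the (pre-truncation) Gaussian
#'   noise, in height units.
#' @param seed integer seed.
#' @return a [tree_sample()] of `time_tree`s.
#' @export
jitter_heights <- function(topology, m, noise_sd = 0.1, seed = 1L) {
  topology <- as_ranked(topology)
  if (noise_sd < 0) tc_stop_validation("noise_sd must be >= 0")
  n1 <- length(topology$clusters)
  base <- as.numeric(seq_len(n1))
  with_seed(seed, {
    trees <- vector("list", m)
    for (i in seq_len(m)) {
      repeat {
        h <- base + stats::rnorm(n1, 0, noise_sd)
        if (all(h > 0) && (n1 == 1L || all(diff(h) > 0))) break
      }
      trees[[i]] <- time_tree(topology, h)
    }
    tree_sample(trees)
  })
}
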