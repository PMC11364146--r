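#' Sum of squared RNNI distances (Frechet variance)
#'
#' @param t candidate `ranked_tree` (or `time_tree`).
#' @param sample a [tree_sample()] on the same taxon set.
#' @param cache optional environment memoising SoS values by canonical tree
#'   key; useful when evaluating many candidates against one fixed sample
#'   (e.g. multi-start searches).
#' @return the integer-valued sum over the sample of squared RNNI distances
#'   from `t` (returned as numeric to avoid integer overflow).
#' @export
sos <- function(t, sample, cache = NULL) {
  t <- as_ranked(t)
  stopifnot(inherits(sample, "tree_sample"))
  if (!identical(t$taxa, sample$taxa))
    tc_stop_validation("candidate tree and sample are on different taxon sets")
  if (!is.null(cache)) {
    key <- tree_key(t)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  val <- sum(vapply(sample$trees, function(s)
    as.numeric(rnni_distance(t, as_ranked(s)))^2, numeric(1)))
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Approximate the mean tree by Centroid local search
#'
#' Hill descent over RNNI neighbourhoods: starting from `start`, the SoS
#' value of every neighbour of the current tree is evaluated (in parallel
#' across `workers` when > 1; the result never depends on `workers`), and
#' the search moves to a neighbour with strictly lower SoS, picking the
#' minimum and breaking exact ties uniformly at random with the seeded RNG.
#' The search stops at a local optimum: a tree none of whose neighbours has
#' lower SoS.  The returned tree approximates the Frechet mean (centroid)
#' of the sample; it may be a non-global local optimum depending on the
#' starting tree.
#'
#' @inheritParams sos
#' @param start starting `ranked_tree`.
#' @param seed integer seed governing tie-breaks (the only randomness).
#' @param workers number of parallel workers for neighbour evaluation.
#' @return an object of class `centroid_result`: list with `tree`, `sos`,
#'   `iterations`, `trajectory` (matrix of iteration and SoS, starting at
#'   iteration 0), `seed`, `start_tree` and `tie_events` (data frame with
#'   the iteration index and number of tied minimal neighbours whenever a
#'   random tie-break occurred).
#' @export
centroid <- function(sample, start, seed = 1L, workers = 1L, cache = NULL) {
  stopifnot(inherits(sample, "tree_sample"))
  start <- as_ranked(start)
  if (!identical(start$taxa, sample$taxa))
    tc_stop_validation("start tree and sample are on different taxon sets")
  eval_sos <- function(trees) {
    if (workers > 1L && is.null(cache)) {
      unlist(parallel::mclapply(trees, sos, sample = sample,
                                mc.cores = workers))
    } else {
      vapply(trees, sos, numeric(1), sample = sample, cache = cache)
    }
  }
  with_seed(seed, {
    cur <- start
    cur_sos <- sos(cur, sample, cache = cache)
    traj <- list(c(0, cur_sos))
    ties <- list()
    iter <- 0L
    repeat {
      nbs <- rnni_neighbours(cur)
      if (length(nbs) == 0L) break
      vals <- eval_sos(nbs)
      best <- min(vals)
      if (best >= cur_sos) break  # local optimum: strict improvement required
      iter <- iter + 1L
      cand <- which(vals == best)
      pick <- if (length(cand) > 1L) {
        ties[[length(ties) + 1L]] <- c(iter, length(cand))
        cand[sample.int(length(cand), 1L)]
      } else cand
      cur <- nbs[[pick]]
      cur_sos <- best
      traj[[length(traj) + 1L]] <- c(iter, cur_sos)
    }
    structure(list(
      tree = cur, sos = cur_sos, iterations = iter,
      trajectory = do.call(rbind, traj),
      seed = as.integer(seed), start_tree = start,
      tie_events = if (length(ties))
        stats::setNames(as.data.frame(do.call(rbind, ties)),
                        c("iteration", "n_tied"))
      else data.frame(iteration = integer(0), n_tied = integer(0))
    ), class = "centroid_result")
  })
}

#' @export
print.centroid_result <- function(x, ...) {
  cat(sprintf("Centroid result: SoS %g after %d iterations (seed %d)\n",
              x$sos, x$iterations, x$seed))
  invisible(x)
}

#' Sturm-style starting tree
#'
#' Iterative shrinking-step approximation of the mean, adapted to RNNI: the
#' sample is consumed in a seeded random order without replacement.  The
#' first drawn tree initialises the estimate `T`; at iteration
#' `k = 2, ..., m`, with `R` the next drawn tree and `p` the FindPath path
#' from `T` to `R`, the estimate moves to the tree at distance
#' `floor(d(T, R) / k)` from `T` along `p` (a step that shrinks as `1/k`,
#' so later draws perturb the estimate less and less; once the step length
#' reaches 0 the estimate no longer changes).  Complexity O(m n^2).
#'
#' @inheritParams centroid
#' @return a `ranked_tree` on the sample's taxa.
#' @export
sturm_start <- function(sample, seed = 1L) {
  stopifnot(inherits(sample, "tree_sample"))
  m <- length(sample$trees)
  with_seed(seed, {
    ord <- sample.int(m)
    cur <- as_ranked(sample$trees[[ord[1L]]])
    if (m >= 2L) for (k in seq.int(2L, m)) {
      R <- as_ranked(sample$trees[[ord[k]]])
      p <- rnni_findpath(cur, R)
      step <- (length(p$trees) - 1L) %/% k
      if (step > 0L) cur <- p$trees[[step + 1L]]
    }
    cur
  })
}

#' Summarise a tree sample by a centroid tree
#'
#' Composes a starting-tree policy with the Centroid descent.  The default
#' policy computes a Sturm-style start; `"random"` draws a uniform ranked
#' tree on the sample's taxa; `"given"` uses `start` as supplied.
#'
#' @inheritParams centroid
#' @param start_policy `"sturm"`, `"given"` or `"random"`.
#' @param start starting tree, required for `start_policy = "given"`.
#' @return a `centroid_result` (see [centroid()]); `start_tree` records the
#'   realised starting tree.
#' @export
summarize_trees <- function(sample, start_policy = c("sturm", "given", "random"),
                            start = NULL, seed = 1L, workers = 1L,
                            cache = NULL) {
  start_policy <- match.arg(start_policy)
  stopifnot(inherits(sample, "tree_sample"))
  start <- switch(start_policy,
    sturm = sturm_start(sample, seed = seed),
    random = random_ranked_tree(sample$taxa, seed = seed),
    given = {
      if (is.null(start)) tc_stop_validation("start_policy = \"given\" needs a start tree")
      as_ranked(start)
    })
  centroid(sample, start, seed = seed, workers = workers, cache = cache)
}
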