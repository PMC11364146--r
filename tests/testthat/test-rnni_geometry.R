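test_that("rank and NNI moves behave as defined on 4-leaf fixtures", {
  bal <- balanced4_tree()  # clusters {A,B},{C,D},{ABCD}
  swapped <- apply_move(bal, rnni_move("rank", 1))
  expect_equal(swapped$clusters, list(3:4, 1:2, 1:4))
  # rank move on a parent-child pair is illegal
  expect_error(apply_move(bal, rnni_move("rank", 2)), "parent and child")
  cat4 <- caterpillar_tree(c("A", "B", "C", "D"))
  # NNI at rank 1: both variants are valid trees adjacent to the input
  nni0 <- apply_move(cat4, rnni_move("nni", 1, 0))
  nni1 <- apply_move(cat4, rnni_move("nni", 1, 1))
  expect_equal(nni0$clusters[[1]], c(1L, 3L))  # {A,C}
  expect_equal(nni1$clusters[[1]], c(2L, 3L))  # {B,C}
  for (nb in list(nni0, nni1)) {
    expect_silent(validate_ranked_tree(nb))
    expect_equal(nb$clusters[[2]], 1:3)
    expect_equal(rnni_distance(cat4, nb), 1L)
  }
  # NNI on an unconnected pair is illegal
  expect_error(apply_move(bal, rnni_move("nni", 1, 0)), "not adjacent")
})

test_that("3-leaf neighbourhoods are the whole space minus the tree itself", {
  space <- enumerate_space(c("A", "B", "C"))
  expect_length(space, 3L)
  for (t in space) {
    nbs <- rnni_neighbours(t)
    expect_length(nbs, 2L)
    keys <- sort(vapply(nbs, treecentroid:::tree_key, character(1)))
    others <- sort(setdiff(vapply(space, treecentroid:::tree_key, character(1)),
                           treecentroid:::tree_key(t)))
    expect_equal(keys, others)
  }
})

test_that("4-leaf neighbourhood sizes match the exhaustive adjacency oracle", {
  expect_length(rnni_neighbours(balanced4_tree()), 3L)          # 1 rank + 2 NNI
  expect_length(rnni_neighbours(caterpillar_tree(c("A","B","C","D"))), 4L)
  # oracle: in the full n=4 graph each vertex degree equals |neighbours|
  g <- get_graph(4)
  degs <- igraph::degree(g$graph)
  for (i in seq_along(g$trees))
    expect_equal(length(rnni_neighbours(g$trees[[i]])), unname(degs[i]))
})

test_that("neighbourhood size bounds and symmetry hold on random trees", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(4:10, 1)
    t <- random_ranked_tree(tx(n))
    nbs <- rnni_neighbours(t)
    expect_gte(length(nbs), n - 2)
    expect_lte(length(nbs), 2 * (n - 2))
    keys <- vapply(nbs, treecentroid:::tree_key, character(1))
    expect_false(anyDuplicated(keys) > 0)
    expect_false(treecentroid:::tree_key(t) %in% keys)
    # symmetry: t is a neighbour of each of its neighbours
    for (nb in nbs[seq_len(min(3, length(nbs)))]) {
      back <- vapply(rnni_neighbours(nb), treecentroid:::tree_key, character(1))
      expect_true(treecentroid:::tree_key(t) %in% back)
    }
  }
})

test_that("findpath returns shortest paths with legal consecutive moves", {
  expect_length(rnni_findpath(balanced4_tree(), balanced4_tree())$moves, 0L)
  space3 <- enumerate_space(c("A", "B", "C"))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(rnni_distance(space3[[i]], space3[[j]]), 1L)
  # consecutive trees along a path differ by exactly the recorded move
  set.seed(31)
  for (rep in 1:20) {
    a <- random_ranked_tree(tx(7))
    b <- random_ranked_tree(tx(7))
    p <- rnni_findpath(a, b)
    expect_true(trees_equal(p$trees[[1]], a))
    expect_true(trees_equal(p$trees[[length(p$trees)]], b))
    expect_length(p$moves, length(p$trees) - 1L)
    for (k in seq_along(p$moves))
      expect_true(trees_equal(apply_move(p$trees[[k]], p$moves[[k]]),
                              p$trees[[k + 1]]))
  }
  expect_error(rnni_distance(balanced4_tree(),
                             random_ranked_tree(tx(4), seed = 1)),
               "taxon")
})

test_that("findpath length equals the BFS oracle on n = 4 (all pairs)", {
  g <- get_graph(4)
  D <- igraph::distances(g$graph)
  for (i in seq_along(g$trees)) for (j in seq_along(g$trees))
    expect_identical(rnni_distance(g$trees[[i]], g$trees[[j]]),
                     as.integer(D[i, j]))
})

test_that("distance satisfies the metric axioms on random triples", {
  set.seed(99)
  for (rep in 1:100) {
    x <- random_ranked_tree(tx(8)); y <- random_ranked_tree(tx(8))
    z <- random_ranked_tree(tx(8))
    dxy <- rnni_distance(x, y)
    expect_identical(dxy, rnni_distance(y, x))
    expect_lte(rnni_distance(x, z), dxy + rnni_distance(y, z))
    expect_identical(rnni_distance(x, x), 0L)
    if (dxy == 0L) expect_true(trees_equal(x, y))
  }
  # d(t, move(t)) = 1 for every legal move
  t <- random_ranked_tree(tx(8), seed = 5)
  for (nb in rnni_neighbours(t)) expect_identical(rnni_distance(t, nb), 1L)
})

test_that("shared clusters persist along findpath paths (cluster property)", {
  set.seed(123)
  for (rep in 1:30) {
    a <- random_ranked_tree(tx(8)); b <- random_ranked_tree(tx(8))
    shared <- intersect(vapply(a$clusters, paste, character(1), collapse = ","),
                        vapply(b$clusters, paste, character(1), collapse = ","))
    p <- rnni_findpath(a, b)
    for (t in p$trees) {
      keys <- vapply(t$clusters, paste, character(1), collapse = ",")
      expect_true(all(shared %in% keys))
    }
  }
})

test_that("enumerate_space produces exactly the closed-form number of trees", {
  for (n in 3:5) {
    space <- enumerate_space(tx(n))
    expect_length(space, ranked_tree_count(n))
    expect_equal(ranked_tree_count(n),
                 factorial(n) * factorial(n - 1) / 2^(n - 1))
    keys <- vapply(space, treecentroid:::tree_key, character(1))
    expect_false(anyDuplicated(keys) > 0)
  }
  expect_error(enumerate_space(tx(8)), "refus")
})

test_that("bfs_distance matches hand-checkable values and refuses large n", {
  space3 <- enumerate_space(c("A", "B", "C"))
  g3 <- rnni_graph(c("A", "B", "C"))
  expect_identical(bfs_distance(space3[[1]], space3[[2]], g3), 1L)
  expect_identical(bfs_distance(space3[[1]], space3[[1]], g3), 0L)
  expect_error(bfs_distance(random_ranked_tree(tx(8), seed = 1),
                            random_ranked_tree(tx(8), seed = 2)), "refus")
})

test_that("diameter closed form is gated by BFS for n = 3..5", {
  expect_identical(rnni_diameter(2), 0L)
  for (n in 3:5)
    expect_identical(rnni_diameter(n, "closed_form"), rnni_diameter(n, "bfs"))
  expect_identical(rnni_diameter(3), 1L)
})

test_that("distance cost scales quadratically, not cubically, in n", {
  # empirical scaling of FindPath work (move count is the dominant term):
  # distances grow ~ n^2; a quadratic fit must dominate a cubic term
  set.seed(7)
  ns <- c(6, 9, 12, 15, 18)
  med <- vapply(ns, function(n) {
    stats::median(vapply(1:12, function(i)
      rnni_distance(random_ranked_tree(tx(n)), random_ranked_tree(tx(n))),
      numeric(1)))
  }, numeric(1))
  fit <- stats::lm(med ~ I(ns^2) + I(ns^3))
  expect_gt(summary(fit)$coefficients["I(ns^2)", 1], 0)
  # cubic contribution negligible relative to quadratic at the largest n
  co <- stats::coef(fit)
  expect_lt(abs(co["I(ns^3)"] * max(ns)^3), abs(co["I(ns^2)"] * max(ns)^2))
})
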