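test_that("all report fields vanish for identical time trees", {
  topo <- random_ranked_tree(tx(6), seed = 1)
  t <- time_tree(topo, seq_len(5))
  rep <- compare_trees(t, t)
  expect_equal(unlist(unclass(rep)),
               c(cae = 0, cre = 0, rnni = 0, rnni_normalized = 0, rf = 0,
                 wrf = 0))
})

test_that("clade age error matches hand computations", {
  topo <- caterpillar_tree(c("A", "B", "C", "D"))
  truth <- time_tree(topo, c(1, 2, 3))
  shifted <- time_tree(topo, c(1.5, 2.5, 3.5))
  expect_equal(clade_age_error(shifted, truth), 0.5)
  # summary lacking truth's clade {A,B,C}: balanced summary,
  # mrca lookups: {A,B}->rank1 (h 1), {A,B,C}->root (h 3), root->root (h 3)
  bal_t <- time_tree(balanced4_tree(), c(1, 2, 3))
  expect_equal(clade_age_error(bal_t, truth),
               mean(c(abs(1 - 1), abs(3 - 2), abs(3 - 3))))
  # truth-referenced by design; symmetrised variant averages both directions
  expect_equal(clade_age_error(bal_t, truth, symmetrize = TRUE),
               (clade_age_error(bal_t, truth) +
                clade_age_error(truth, bal_t)) / 2)
})

test_that("clade rank error matches hand computations", {
  cat5 <- caterpillar_tree(tx(5))
  expect_equal(clade_rank_error(cat5, cat5), 0)
  # swapping ranks 1 and 2 moves two clades by one rank each: mean 2/(n-1)
  bal <- balanced4_tree(tx(4))
  sw <- apply_move(bal, rnni_move("rank", 1))
  expect_equal(clade_rank_error(sw, bal), 2 / 3)
  # 4-leaf fixture via explicit mrca/rank table:
  # truth caterpillar {t1,t2}:1 {t1,t2,t3}:2 root:3; summary balanced
  # {t1,t2}:1, {t1,t2,t3}->root rank 3, root:3 -> errors 0,1,0
  cat4 <- caterpillar_tree(tx(4))
  expect_equal(clade_rank_error(bal, cat4), mean(c(0, 1, 0)))
})

test_that("rooted RF distance is the clade symmetric difference", {
  cat4 <- caterpillar_tree(c("A", "B", "C", "D"))
  bal <- balanced4_tree()
  expect_equal(rf_distance(cat4, cat4), 0)
  # rankings are ignored: a rank move changes no clades
  expect_equal(rf_distance(bal, apply_move(bal, rnni_move("rank", 1))), 0)
  # {AB, ABC} vs {AB, CD}
  expect_equal(rf_distance(cat4, bal), 2)
  # no shared non-trivial clades: 2(n-2)
  disjoint <- ranked_tree(list(c("A", "D"), c("A", "C", "D"),
                               c("A", "B", "C", "D")))
  expect_equal(rf_distance(cat4, disjoint), 4)
  expect_equal(rf_distance(disjoint, cat4), 4)  # symmetric
})

test_that("weighted RF sums absolute branch-length differences over the clade union", {
  topo <- caterpillar_tree(c("A", "B", "C", "D"))
  a <- time_tree(topo, c(1, 2, 3))
  expect_equal(weighted_rf(a, a), 0)
  # moving the rank-2 node by delta changes its parent branch and its child
  # branch: |(3-2.4)-(3-2)| + |(2.4-1)-(2-1)| = 0.4 + 0.4
  b <- time_tree(topo, c(1, 2.4, 3))
  expect_equal(weighted_rf(a, b), 0.8)
  expect_equal(weighted_rf(b, a), 0.8)
  # disjoint clade sets: sum of all non-trivial branch lengths of both trees
  d <- time_tree(ranked_tree(list(c("A", "D"), c("A", "C", "D"),
                                  c("A", "B", "C", "D"))), c(1, 2, 3))
  expect_equal(weighted_rf(a, d), (2 - 1) + (3 - 2) + (2 - 1) + (3 - 2))
})

test_that("rnni_normalized lies in [0,1] and uses the validated diameter", {
  set.seed(41)
  for (rep in 1:20) {
    a <- time_tree(random_ranked_tree(tx(5)), 1:4)
    b <- time_tree(random_ranked_tree(tx(5)), 1:4)
    rep_ <- compare_trees(a, b, metrics = "rnni")
    expect_gte(rep_$rnni_normalized, 0)
    expect_lte(rep_$rnni_normalized, 1)
    expect_equal(rep_$rnni_normalized, rep_$rnni / rnni_diameter(5))
  }
})

test_that("tally_wins recomputes per-metric win counts", {
  set.seed(55)
  truths <- lapply(1:6, function(i) time_tree(random_ranked_tree(tx(5)), 1:4))
  # summary A = truth: wins or ties every metric
  sums_b <- lapply(truths, function(t) {
    nb <- rnni_neighbours(t$topology)[[1]]
    time_tree(nb, t$heights + 0.1)
  })
  tw <- tally_wins(truths, sums_b, truths)
  expect_true(all(tw$b_wins == 0))
  expect_equal(tw$a_wins + tw$ties, rep(6L, nrow(tw)))
})

test_that("correlation diagnostics recover engineered correlations", {
  ctr <- random_ranked_tree(tx(6), seed = 71)
  base <- random_walk_sample(ctr, 25, lambda = 2, seed = 72)
  cache <- new.env(parent = emptyenv())
  sosv <- vapply(base$trees, sos, numeric(1), sample = base, cache = cache)
  # scores = -SoS: perfect anticorrelation; scores = +SoS: perfect correlation
  r_neg <- correlation_diagnostics(tree_sample(base$trees, scores = -sosv))
  expect_equal(r_neg$pearson, -1)
  expect_equal(r_neg$spearman, -1)
  r_pos <- correlation_diagnostics(tree_sample(base$trees, scores = sosv))
  expect_equal(r_pos$pearson, 1)
  expect_equal(r_pos$n_points, 25)
  # pairwise mode normalises by the largest observed values
  r_pw <- correlation_diagnostics(tree_sample(base$trees, scores = -sosv),
                                  mode = "pairwise")
  expect_equal(max(r_pw$xy[, 1]), 1)
  expect_equal(max(r_pw$xy[, 2]), 1)
  expect_equal(r_pw$n_points, choose(25, 2))
  # undefined correlation errors
  expect_error(correlation_diagnostics(
    tree_sample(base$trees, scores = rep(1, 25))), "constant")
  expect_error(correlation_diagnostics(tree_sample(base$trees)), "scores")
})

test_that("permuted scores show no correlation with SoS (Monte-Carlo null)", {
  ctr <- random_ranked_tree(tx(6), seed = 81)
  base <- random_walk_sample(ctr, 100, lambda = 3, seed = 82)
  cache <- new.env(parent = emptyenv())
  sosv <- vapply(base$trees, sos, numeric(1), sample = base, cache = cache)
  set.seed(83)
  small <- vapply(1:100, function(i) {
    y <- sample(sosv)
    abs(stats::cor(sosv, y))
  }, numeric(1))
  expect_gte(mean(small < 0.3), 0.95)
})
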