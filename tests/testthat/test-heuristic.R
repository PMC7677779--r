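bipartition_key <- labeledRF:::bipartition_key

test_that("preprocessing contracts exactly the non-mixed bad edges", {
  p <- fig3_pair()
  # t_prime is uniformly SPE: its 17 bad edges all contract
  r <- contract_nonmixed_bad_edges(p$t_prime, p$t)
  expect_length(r$ops, 17L)
  expect_length(internal_nodes(r$tree), 2L)
  e <- tree_edges(r$tree, internal_only = TRUE)
  expect_equal(nrow(e), 1L)
  expect_true(bipartition_key(r$tree, e[1L, 1L], e[1L, 2L],
                              sort(leaf_names(r$tree))) %in%
                bipartition_set(p$t))

  # t is fully mixed: nothing to contract
  expect_length(contract_nonmixed_bad_edges(p$t, p$t_prime)$ops, 0L)
})

test_that("minimum flips equal half the diameter, rounded up, minus one", {
  expect_equal(min_flips(parse_newick("(A,B,C,D)Spe;")), 0L)
  expect_equal(min_flips(quartet("SPE", "DUP")), 1L)
  expect_equal(min_flips(fig3_pair()$t), 6L)
  expect_error(min_flips(quartet("SPE", "SPE")), "non-mixed")
})

test_that("contract_tree contracts optimally and can steer the star label", {
  star <- parse_newick("(A,B,C,D)Dup;")
  cs <- contract_tree(star)
  expect_length(cs$script, 0L)
  expect_equal(cs$final_label, "DUP")

  p <- fig3_pair()
  ct <- contract_tree(p$t)
  cnt <- script_counts(ct$script)
  expect_equal(unname(cnt[c("flips", "contractions", "extensions")]),
               c(6L, 18L, 0L))
  expect_equal(ct$final_label, "SPE")
  expect_length(internal_nodes(ct$star), 1L)
  expect_true(tree_isomorphic(replay(ct$script, p$t), ct$star))

  # uniformly labeled tree: phase 1 contracts everything, no flips
  cu <- contract_tree(p$t_prime)
  expect_equal(unname(script_counts(cu$script)[c("flips", "contractions")]),
               c(0L, 18L))
  expect_equal(cu$final_label, "SPE")
})

test_that("contract_tree flip counts match a brute-force search on mixed trees", {
  set.seed(91)
  for (i in 1:10) {
    t <- make_mixed(random_labeled_tree(sample(5:7, 1L), 0.25))
    bf <- brute_min_flips(t)
    expect_equal(min_flips(t), bf)
    expect_equal(unname(script_counts(contract_tree(t)$script)[["flips"]]), bf)
  }
})

test_that("the per-pair heuristic reproduces hand-checked totals", {
  t <- random_labeled_tree(8, 0.3, seed = 14)
  expect_equal(methodology2(t, t)$total, 0L)

  # same topology, both internal labels swapped: one flip per singleton pair
  d <- methodology2(quartet("SPE", "DUP"), quartet("DUP", "SPE"))
  expect_equal(d$total, 2L)
  expect_equal(d$n_flips, 2L)
  expect_equal(d$total, exact_distance(quartet("SPE", "DUP"),
                                       quartet("DUP", "SPE")))

  p <- fig3_pair()
  m2 <- methodology2(p$t, p$t_prime)
  expect_equal(m2$total, 43L)
  expect_equal(c(m2$n_flips, m2$n_contractions, m2$n_extensions),
               c(9L, 17L, 17L))
})

test_that("the star path matches its closed-form costs", {
  p <- fig3_pair()
  sp <- star_path_cost(p$t, p$t_prime)
  expect_equal(sp$total, 42L)
  expect_equal(c(sp$n_flips, sp$n_contractions, sp$n_extensions),
               c(6L, 18L, 18L))

  # identical uniformly labeled trees with m internal edges cost 2m
  t <- random_labeled_tree(9, 0.2, seed = 6)
  t$label[internal_nodes(t)] <- "SPE"
  m <- nrow(tree_edges(t, internal_only = TRUE))
  expect_equal(star_path_cost(t, t)$total, 2L * m)

  s1 <- parse_newick("(A,B,C,D)Spe;")
  s2 <- parse_newick("(A,B,C,D)Dup;")
  expect_equal(star_path_cost(s1, s2)$total, 1L)
})

test_that("the estimate takes the better strategy and reduces to RF for uniform labels", {
  p <- fig3_pair()
  est <- labeled_rf_estimate(p$t, p$t_prime)
  expect_equal(est$total, 42L)
  expect_equal(est$method_tag, "star_path")
  expect_equal(unname(est$alt_totals), c(43L, 42L))

  set.seed(52)
  for (i in 1:10) {
    n <- sample(6:10, 1L)
    t1 <- random_labeled_tree(n, 0.3)
    t2 <- random_labeled_tree(n, 0.3)
    t1$label[internal_nodes(t1)] <- "DUP"
    t2$label[internal_nodes(t2)] <- "DUP"
    expect_equal(labeled_rf_estimate(t1, t2)$total, rf_distance(t1, t2))
  }
})

test_that("rooted pairs are compared through a shared dummy leaf", {
  r1 <- parse_newick("((A,B)Spe,(C,D)Dup)Spe;")
  r2 <- parse_newick("((A,C)Dup,(B,D)Dup)Spe;")
  est <- labeled_rf_estimate(r1, r2)
  expect_gt(est$total, 0L)
  expect_equal(est$rf_classical, rf_distance(r1, r2))
})

test_that("every witness script replays its source into its target", {
  set.seed(35)
  p <- fig3_pair()
  cases <- list(list(p$t, p$t_prime))
  for (i in 1:10) {
    n <- sample(5:9, 1L)
    cases <- c(cases, list(list(random_labeled_tree(n, 0.3),
                                random_labeled_tree(n, 0.3))))
  }
  for (cs in cases) {
    m2 <- methodology2(cs[[1]], cs[[2]])
    sp <- star_path_cost(cs[[1]], cs[[2]])
    est <- labeled_rf_estimate(cs[[1]], cs[[2]])
    expect_true(tree_isomorphic(replay(m2$script, cs[[1]]), cs[[2]]))
    expect_true(tree_isomorphic(replay(sp$script, cs[[1]]), cs[[2]]))
    expect_true(tree_isomorphic(replay(est$script, cs[[1]]), cs[[2]]))
    expect_equal(est$total, min(m2$total, sp$total))
    expect_gte(est$total, est$rf_classical)
  }
})

test_that("the general upper bound is additive in bad edges and nodes", {
  expect_equal(labeled_rf_upper_bound(8, 8, 9), 25L)
  expect_equal(labeled_rf_upper_bound(0, 0, 5), 5L)
  expect_error(labeled_rf_upper_bound(-1, 0, 2), "non-negative")
})

test_that("estimates respect the bound chain against the exact distance", {
  for (i in 1:10) {
    t1 <- random_labeled_tree(6, 0, seed = 700 + i)
    t2 <- random_labeled_tree(6, 0, seed = 800 + i)
    cls <- classify_edges(t1, t2)
    bound <- labeled_rf_upper_bound(sum(cls$t1$internal & !cls$t1$good),
                                    sum(cls$t2$internal & !cls$t2$good),
                                    length(internal_nodes(t1)))
    ex <- exact_distance(t1, t2)
    est <- labeled_rf_estimate(t1, t2)$total
    m2 <- methodology2(t1, t2)$total
    expect_true(ex <= est && est <= m2 && m2 <= bound)
  }
})
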