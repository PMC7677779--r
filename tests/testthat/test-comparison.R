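test_that("bipartition sets enumerate internal edges", {
  expect_equal(bipartition_set(quartet()), "A,B")
  expect_length(bipartition_set(parse_newick("(A,B,C,D)Spe;")), 0L)
  expect_length(bipartition_set(fig3_pair()$t), 18L)
})

test_that("clade sets exclude trivial clades", {
  expect_setequal(clade_set(parse_newick("((A,B)Spe,(C,D)Dup)Spe;")),
                  c("A,B", "C,D"))
  expect_setequal(clade_set(parse_newick("(((A,B)Spe,C)Dup,D)Spe;")),
                  c("A,B", "A,B,C"))
  expect_error(clade_set(quartet()), "rooted")
  expect_error(bipartition_set(parse_newick("((A,B)Spe,(C,D)Dup)Spe;")),
               "unrooted")
})

test_that("classical RF distance on basic pairs", {
  expect_equal(rf_distance(quartet(), quartet("DUP", "SPE")), 0L)
  q_swapped <- labeled_tree(rbind(c("x", "A"), c("x", "C"), c("x", "y"),
                                  c("y", "B"), c("y", "D")),
                            labels = c(x = "SPE", y = "SPE"))
  expect_equal(rf_distance(quartet(), q_swapped), 2L)
  expect_error(rf_distance(quartet(), quartet(leaves = c("A", "B", "C", "E"))),
               "leaf set")
  expect_error(rf_distance(quartet(), parse_newick("((A,B)Spe,(C,D)Dup)Spe;")),
               "rooted")
})

test_that("unrooted RF agrees with phangorn on random binary pairs", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:12, 1L)
    t1 <- random_labeled_tree(n, 0)
    t2 <- random_labeled_tree(n, 0)
    p1 <- ape::unroot(ape::read.tree(text = write_newick(t1)))
    p2 <- ape::unroot(ape::read.tree(text = write_newick(t2)))
    expect_equal(rf_distance(t1, t2), as.integer(phangorn::RF.dist(p1, p2)))
  }
})

test_that("RF is a metric on random triples", {
  set.seed(44)
  for (i in 1:100) {
    n <- sample(5:9, 1L)
    ts <- replicate(3, random_labeled_tree(n, 0.3), simplify = FALSE)
    d12 <- rf_distance(ts[[1]], ts[[2]])
    d13 <- rf_distance(ts[[1]], ts[[3]])
    d23 <- rf_distance(ts[[2]], ts[[3]])
    expect_equal(d12, rf_distance(ts[[2]], ts[[1]]))
    expect_true(d12 <= d13 + d23)
    expect_equal(rf_distance(ts[[1]], ts[[1]]), 0L)
  }
})

test_that("clade RF of rooted pairs equals bipartition RF after dummy unrooting", {
  set.seed(66)
  for (i in 1:10) {
    n <- sample(5:9, 1L)
    t1 <- random_rooted(n)
    t2 <- random_rooted(n)
    expect_equal(rf_distance(t1, t2),
                 rf_distance(unroot_with_dummy(t1), unroot_with_dummy(t2)))
  }
})

test_that("edge classification separates good, bad and mixed edges", {
  # same topology, any labels: everything good
  cls <- classify_edges(quartet(), quartet("DUP", "SPE"))
  expect_true(all(cls$t1$good))
  expect_true(all(cls$t2$good))
  expect_true(all(cls$t1$mixed[cls$t1$internal]))

  # quartet against star: the quartet's internal edge is bad
  cls2 <- classify_edges(quartet(), parse_newick("(A,B,C,D)Spe;"))
  expect_false(any(cls2$t1$good[cls2$t1$internal]))
  expect_true(all(cls2$t1$good[!cls2$t1$internal]))

  p <- fig3_pair()
  cls3 <- classify_edges(p$t, p$t_prime)
  expect_equal(sum(cls3$t1$internal & cls3$t1$good), 1L)
  expect_equal(sum(cls3$t1$internal & !cls3$t1$good), 17L)
  expect_equal(sum(cls3$t2$internal & cls3$t2$good), 1L)
  expect_equal(sum(cls3$t2$internal & !cls3$t2$good), 17L)
})

test_that("bad-subtree decomposition pairs subtrees by their boundaries", {
  # identical topologies: one singleton pair per internal node
  t <- random_labeled_tree(8, 0.3, seed = 5)
  dec <- decompose_bad_subtrees(t, t)
  expect_length(dec, length(internal_nodes(t)))
  expect_true(all(vapply(dec, function(p) length(p$nodes1) == 1L, logical(1))))

  # swapped quartets: a single pair covering both internal nodes
  q2 <- labeled_tree(rbind(c("x", "A"), c("x", "C"), c("x", "y"),
                           c("y", "B"), c("y", "D")),
                     labels = c(x = "SPE", y = "SPE"))
  dec2 <- decompose_bad_subtrees(quartet(), q2)
  expect_length(dec2, 1L)
  expect_length(dec2[[1]]$nodes1, 2L)
  expect_length(dec2[[1]]$nodes2, 2L)

  # worked example: the single good edge splits off the P chain
  p <- fig3_pair()
  dec3 <- decompose_bad_subtrees(p$t, p$t_prime)
  expect_length(dec3, 2L)
  expect_setequal(vapply(dec3, function(x) x$n_bad1, integer(1)), c(5L, 12L))
})

test_that("decomposition covers all internal nodes and matches boundaries", {
  set.seed(88)
  for (i in 1:10) {
    n <- sample(6:10, 1L)
    t1 <- random_labeled_tree(n, 0.3)
    t2 <- random_labeled_tree(n, 0.3)
    dec <- decompose_bad_subtrees(t1, t2)
    expect_setequal(unlist(lapply(dec, function(p) p$nodes1)),
                    internal_nodes(t1))
    expect_setequal(unlist(lapply(dec, function(p) p$nodes2)),
                    internal_nodes(t2))
    # RF equals the bad internal edge count summed over both trees
    cls <- classify_edges(t1, t2)
    expect_equal(rf_distance(t1, t2),
                 sum(cls$t1$internal & !cls$t1$good) +
                   sum(cls$t2$internal & !cls$t2$good))
  }
})
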