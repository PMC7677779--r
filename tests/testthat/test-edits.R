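test_that("contraction merges equal-label endpoints and rejects the rest", {
  q <- quartet("SPE", "SPE")
  e <- tree_edges(q, internal_only = TRUE)
  star <- apply_contraction(q, e[1L, ])
  expect_true(tree_isomorphic(star, parse_newick("(A,B,C,D)Spe;")))
  expect_length(validate_tree(star), 0L)

  mixed <- quartet("SPE", "DUP")
  em <- tree_edges(mixed, internal_only = TRUE)
  expect_error(apply_contraction(mixed, em[1L, ]), "mixed")
  v <- internal_nodes(q)[1L]
  lf <- tree_leaves(q)[1L]
  expect_error(apply_contraction(q, c(v, lf)), "terminal")
})

test_that("extension is the inverse of contraction and enforces the size rule", {
  star <- parse_newick("(A,B,C,D)Spe;")
  hub <- internal_nodes(star)
  ab <- tree_leaves(star)[order(star$leaf[tree_leaves(star)])][1:2]
  q <- apply_extension(star, hub, ab)
  expect_true(tree_isomorphic(q, quartet("SPE", "SPE")))

  expect_error(apply_extension(star, hub, ab[1L]), "at least 2")
  expect_error(apply_extension(star, hub, star$adj[[hub]][1:3]), "degree < 3")
  expect_error(apply_extension(star, hub, c(99L, 98L)), "neighbors")
})

test_that("flips change exactly one label and refuse no-ops", {
  q <- quartet()
  v <- internal_nodes(q)[1L]
  f <- apply_flip(q, v)
  expect_equal(f$label[v], flip_label(q$label[v]))
  expect_equal(f$label[-v], q$label[-v])
  expect_identical(f$adj, q$adj)
  expect_error(apply_flip(q, v, q$label[v]), "other label")
  expect_error(apply_flip(q, tree_leaves(q)[1L]), "internal")
})

test_that("extension then contraction (and vice versa) restores the tree", {
  set.seed(12)
  for (i in 1:20) {
    t <- random_labeled_tree(sample(5:9, 1L), 0.5)
    iv <- internal_nodes(t)
    wide <- iv[vapply(iv, function(v) node_degree(t, v) > 3L, logical(1L))]
    if (!length(wide)) next
    v <- wide[sample.int(length(wide), 1L)]
    X <- sample(t$adj[[v]], 2L)
    t2 <- apply_extension(t, v, X)
    y <- length(t2$adj)
    expect_true(tree_isomorphic(apply_contraction(t2, c(v, y)), t))
  }
})

test_that("replay applies scripts stepwise and reports the failing index", {
  q <- quartet("SPE", "SPE")
  expect_true(tree_isomorphic(replay(edit_script(), q), q))
  e <- tree_edges(q, internal_only = TRUE)
  bad <- edit_script(list(
    labeledRF:::op_flip(internal_nodes(q)[1L], "DUP"),
    labeledRF:::op_contract(e[1L, 1L], e[1L, 2L])))
  expect_error(replay(bad, q), "index 2")
})

test_that("scripts round-trip through the text format", {
  m <- mutate(random_labeled_tree(8, 0.3, seed = 3), k = 6, seed = 9)
  lines <- format_edit_script(m$script)
  expect_length(lines, 6L)
  back <- read_edit_script(lines)
  t0 <- random_labeled_tree(8, 0.3, seed = 3)
  expect_true(tree_isomorphic(replay(back, t0), m$tree))
})

test_that("random edits preserve the leaf set and respect the pools", {
  set.seed(21)
  for (i in 1:30) {
    t <- random_labeled_tree(sample(4:10, 1L), 0.4)
    step <- random_edit(t)
    expect_setequal(unname(leaf_names(step$tree)), unname(leaf_names(t)))
    expect_length(validate_tree(step$tree), 0L)
    if (step$op$kind == "FLIP") {
      expect_equal(sum(step$tree$label != t$label, na.rm = TRUE), 1L)
      expect_identical(step$tree$adj, t$adj)
    }
  }
})

test_that("a binary fully-mixed tree can only be flipped", {
  t <- make_mixed(random_labeled_tree(7, 0, seed = 8))
  set.seed(4)
  for (i in 1:10) expect_equal(random_edit(t)$op$kind, "FLIP")
})

test_that("mutate is deterministic under a seed and replayable", {
  base <- random_labeled_tree(10, 0.3, seed = 17)
  m0 <- mutate(base, k = 0, seed = 1)
  expect_length(m0$script, 0L)
  expect_true(tree_isomorphic(m0$tree, base))

  m1 <- mutate(base, k = 5, seed = 123)
  m2 <- mutate(base, k = 5, seed = 123)
  expect_identical(format_edit_script(m1$script), format_edit_script(m2$script))
  expect_equal(canonical_key(m1$tree), canonical_key(m2$tree))
  expect_true(tree_isomorphic(replay(m1$script, base), m1$tree))
})

test_that("exact distance between a tree and its k-mutated version is at most k", {
  for (i in 1:8) {
    base <- random_labeled_tree(6, 0.3, seed = 300 + i)
    k <- (i %% 4L) + 1L
    m <- mutate(base, k = k, seed = 400 + i)
    expect_lte(exact_distance(base, m$tree), k)
  }
})
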