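# ---- Lemma-style preprocessing ----------------------------------------

#' Contract all non-mixed bad edges
#'
#' A bad edge whose endpoints share a label can always be contracted
#' first: doing so reduces the true labeled distance by exactly 1, so an
#' optimal path exists that starts this way. Contracting a bad edge
#' removes only its own bipartition and no labels change, so the good/bad
#' and mixed status of every other edge is unaffected; the edges to
#' contract can therefore be listed once and contracted in canonical
#' order, tracking endpoint merges. Afterwards every remaining bad
#' subtree is mixed.
#'
#' @param t the tree to reduce (unrooted).
#' @param other the reference tree defining good and bad edges.
#' @return A list with `tree` (the reduced tree) and `ops` (the recorded
#'   contraction operations, with the displaced neighbor sets annotated).
#' @export
contract_nonmixed_bad_edges <- function(t, other) {
  check_comparable(t, other)
  if (is_rooted(t)) stop("preprocessing runs on unrooted trees")
  cls <- classify_edges(t, other)$t1
  bad <- cls[cls$internal & !cls$good, , drop = FALSE]
  merged_into <- seq_along(t$adj)
  find <- function(x) {
    while (merged_into[x] != x) x <- merged_into[x]
    x
  }
  ops <- list()
  for (i in seq_len(nrow(bad))) {
    a <- find(bad$a[i]); b <- find(bad$b[i])
    if (t$label[a] != t$label[b]) next  # mixed bad edges stay for the flips stage
    moved <- setdiff(t$adj[[b]], a)
    t <- apply_contraction(t, c(a, b))
    merged_into[b] <- a
    ops <- c(ops, list(op_contract(a, b, moved = moved)))
  }
  list(tree = t, ops = ops)
}

#' Minimum flips to contract a mixed tree to a star
#'
#' For a tree all of whose internal edges are mixed, the minimum number
#' of flips in an optimal contraction sequence is
#' `ceiling(diameter / 2) - 1`: contracting outward from a node of
#' minimum eccentricity spends one flip per distance ring.
#'
#' @param t an unrooted mixed [lrf_tree].
#' @return Integer flip count.
#' @export
#' @examples
#' min_flips(parse_newick("((A,B)Dup,C,D)Spe;"))
min_flips <- function(t) {
  if (is_rooted(t)) stop("flip counts are defined for unrooted trees")
  if (!is_mixed_tree(t)) {
    stop("tree has a non-mixed internal edge; contract non-mixed edges first")
  }
  as.integer(ceiling(tree_geometry(t)$diameter / 2) - 1L)
}

# ---- region machinery --------------------------------------------------
# A region is a connected set of internal nodes (a bad subtree, or the
# whole tree). The region's subtree has the region's outside neighbors as
# leaves; contracting the region merges it into one node without touching
# any edge leaving the region.

region_phase1 <- function(t, region) {
  # contract non-mixed edges inside the region until the region is mixed
  ops <- list()
  repeat {
    e <- tree_edges(t, internal_only = TRUE)
    inreg <- e[, 1L] %in% region & e[, 2L] %in% region
    cand <- which(inreg & t$label[e[, 1L]] == t$label[e[, 2L]])
    if (!length(cand)) break
    a <- e[cand[1L], 1L]; b <- e[cand[1L], 2L]
    moved <- setdiff(t$adj[[b]], a)
    t <- apply_contraction(t, c(a, b))
    region <- setdiff(region, b)
    ops <- c(ops, list(op_contract(a, b, moved = moved)))
  }
  list(tree = t, ops = ops, region = region)
}

region_geometry <- function(t, region) {
  inreg <- rep(FALSE, length(t$adj))
  inreg[region] <- TRUE
  boundary <- sort(unique(unlist(
    lapply(region, function(v) t$adj[[v]][!inreg[t$adj[[v]]]]))))
  dist_in_s <- function(v) {
    dist <- rep(NA_integer_, length(t$adj))
    dist[v] <- 0L
    queue <- v
    while (length(queue)) {
      x <- queue[1L]; queue <- queue[-1L]
      for (u in t$adj[[x]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[x] + 1L
          if (inreg[u]) queue <- c(queue, u)  # boundary nodes are leaves of S
        }
      }
    }
    dist
  }
  dists <- lapply(region, dist_in_s)
  ecc <- vapply(dists, function(d) max(d[boundary]), integer(1L))
  names(ecc) <- region
  attach_of <- vapply(boundary, function(b) intersect(t$adj[[b]], region)[1L],
                      integer(1L))
  diam <- max(vapply(seq_along(boundary), function(i) {
    d <- dists[[match(attach_of[i], region)]]
    1L + max(d[setdiff(boundary, boundary[i])])
  }, integer(1L)))
  stopifnot(min(ecc) == ceiling(diam / 2))
  list(diameter = diam, eccentricity = ecc,
       midpoints = region[ecc == min(ecc)])
}

# Which star labels this region can end on, and a witnessing midpoint for
# each: contracting from midpoint m uses ecc(m) - 1 flips, all applied to
# m, so the final label is m's label flipped that many times. A
# single-node region is forced to its own label.
region_plan <- function(t, region) {
  ph <- region_phase1(t, region)
  if (length(ph$region) == 1L) {
    v <- ph$region
    choices <- stats::setNames(v, ph$tree$label[v])
  } else {
    geo <- region_geometry(ph$tree, ph$region)
    mids <- sort(geo$midpoints)
    finals <- vapply(mids, function(m) {
      flips <- geo$eccentricity[[as.character(m)]] - 1L
      if (flips %% 2L == 0L) ph$tree$label[m] else flip_label(ph$tree$label[m])
    }, character(1L))
    choices <- stats::setNames(mids[!duplicated(finals)],
                               finals[!duplicated(finals)])
  }
  list(tree = ph$tree, ops = ph$ops, region = ph$region, choices = choices)
}

region_exec <- function(t, region, v) {
  # flip the chosen midpoint and contract its incident region edges,
  # ring by ring, until the region is a single node
  ops <- list()
  repeat {
    ring <- sort(intersect(t$adj[[v]], setdiff(region, v)))
    if (!length(ring)) break
    t <- apply_flip(t, v)
    ops <- c(ops, list(op_flip(v, t$label[v])))
    for (u in ring) {
      moved <- setdiff(t$adj[[u]], v)
      t <- apply_contraction(t, c(v, u))
      ops <- c(ops, list(op_contract(v, u, moved = moved)))
    }
    region <- setdiff(region, ring)
  }
  list(tree = t, ops = ops, node = v, final_label = t$label[v])
}

pick_label <- function(choices, preferred = NULL) {
  if (!is.null(preferred) && preferred %in% names(choices)) {
    preferred
  } else {
    names(choices)[1L]
  }
}

#' Optimally contract a tree to a star
#'
#' Phase 1 contracts all non-mixed internal edges (no flips needed);
#' phase 2 contracts the resulting mixed tree outward from a node of
#' minimum eccentricity, alternating one flip with the contraction of the
#' flipped node's incident internal edges. The flip count equals
#' [min_flips()] of the phase-2 tree and the total operation count is the
#' internal-edge count plus the flips. When the mixed tree admits
#' midpoints realizing both star labels (always the case for odd
#' diameter), `preferred_final_label` selects among them.
#'
#' @param t an unrooted [lrf_tree].
#' @param preferred_final_label `"SPE"` or `"DUP"`; used when achievable.
#' @return A list with `script` (the [edit_script()]), `star` (the
#'   resulting star tree), `final_label`, and `label_choices` (the
#'   achievable star labels).
#' @export
#' @examples
#' ct <- contract_tree(fig3_pair()$t)
#' script_counts(ct$script)
contract_tree <- function(t, preferred_final_label = NULL) {
  if (is_rooted(t)) stop("contraction runs on unrooted trees")
  plan <- region_plan(t, internal_nodes(t))
  lab <- pick_label(plan$choices, preferred_final_label)
  ex <- region_exec(plan$tree, plan$region, plan$choices[[lab]])
  list(script = edit_script(c(plan$ops, ex$ops)), star = ex$tree,
       final_label = ex$final_label, label_choices = names(plan$choices))
}

# ---- node correspondence and reversal ---------------------------------

# clade-key -> node id for every internal node, from the vantage of the
# smallest-named leaf; used to align two isomorphic trees node by node
clade_index <- function(t) {
  lv <- tree_leaves(t)
  vantage <- lv[order(t$leaf[lv])][1L]
  out <- list()
  walk <- function(v, parent) {
    if (!is.na(t$leaf[v])) return(t$leaf[v])
    below <- sort(unlist(lapply(setdiff(t$adj[[v]], parent), walk, parent = v)))
    out[[paste(below, collapse = ",")]] <<- v
    below
  }
  walk(t$adj[[vantage]][1L], vantage)
  out
}

# map: node ids of tA -> node ids of tB (tA, tB isomorphic labeled trees)
match_nodes <- function(tA, tB) {
  map <- integer(length(tA$adj))
  idB <- stats::setNames(tree_leaves(tB), tB$leaf[tree_leaves(tB)])
  for (v in tree_leaves(tA)) map[v] <- idB[[tA$leaf[v]]]
  cA <- clade_index(tA)
  cB <- clade_index(tB)
  if (!setequal(names(cA), names(cB))) {
    stop("internal error: trees to align are not isomorphic")
  }
  for (key in names(cA)) map[cA[[key]]] <- cB[[key]]
  map
}

# Replay the reverse of `ops` (applied earlier to some other tree) onto
# `t`, translating node ids through `map`; contractions become
# extensions and flips are undone. Grows `map` as reversed extensions
# recreate nodes.
reverse_ops_onto <- function(ops, map, t) {
  out <- vector("list", length(ops))
  k <- 0L
  for (op in rev(ops)) {
    k <- k + 1L
    if (op$kind == "CONTRACT") {
      x <- map[op$a]
      mv <- map[op$moved]
      t <- apply_extension(t, x, mv)
      map[op$b] <- length(t$adj)
      out[[k]] <- op_extend(x, mv)
    } else if (op$kind == "FLIP") {
      old <- flip_label(op$new_label)
      t <- apply_flip(t, map[op$node], old)
      out[[k]] <- op_flip(map[op$node], old)
    } else {
      stop("internal error: cannot reverse an extension")
    }
  }
  list(ops = out, tree = t, map = map)
}

# ---- distance reports --------------------------------------------------

new_dist_report <- function(script, method_tag, extra = list()) {
  cnt <- script_counts(script)
  structure(c(list(total = unname(cnt[["total"]]),
                   n_flips = unname(cnt[["flips"]]),
                   n_contractions = unname(cnt[["contractions"]]),
                   n_extensions = unname(cnt[["extensions"]]),
                   script = script, method_tag = method_tag),
              extra),
            class = "lrf_dist_report")
}

#' @export
print.lrf_dist_report <- function(x, ...) {
  cat(sprintf("Labeled RF distance estimate (%s): %d operations\n",
              x$method_tag, x$total))
  cat(sprintf("  %d flips, %d contractions, %d extensions\n",
              x$n_flips, x$n_contractions, x$n_extensions))
  if (!is.null(x$rf_classical)) {
    cat(sprintf("  classical RF distance: %d\n", x$rf_classical))
  }
  if (!is.null(x$alt_totals)) {
    cat(sprintf("  strategy totals: %s\n",
                paste(names(x$alt_totals), x$alt_totals,
                      sep = " = ", collapse = ", ")))
  }
  invisible(x)
}

coordinate_labels <- function(choices1, choices2) {
  common <- intersect(names(choices1), names(choices2))
  if (length(common)) {
    lab <- sort(common)[1L]
    list(lab1 = lab, lab2 = lab, residual = FALSE)
  } else {
    list(lab1 = names(choices1)[1L], lab2 = names(choices2)[1L],
         residual = TRUE)
  }
}

#' Heuristic labeled distance by per-pair contraction
#'
#' The main heuristic: (i) contract all non-mixed bad edges of both trees
#' ([contract_nonmixed_bad_edges()]); (ii) decompose into matched pairs
#' of maximal (now mixed) bad subtrees; (iii) contract both sides of each
#' pair to a single node with the flip-optimal procedure, coordinating
#' the final labels so a pair needs a closing flip only when neither side
#' can reach the other's label; (iv) one flip per pair whose labels still
#' differ. Good edges are never contracted. The returned witness script
#' replays `t1` into `t2` (t1-side operations, pair flips, then the
#' t2-side operations reversed as extensions). The total is guaranteed to
#' be at most twice the exact labeled distance.
#'
#' @param t1,t2 unrooted [lrf_tree] objects on the same leaf set.
#' @return An `lrf_dist_report`.
#' @export
#' @examples
#' p <- fig3_pair()
#' methodology2(p$t, p$t_prime)$total
methodology2 <- function(t1, t2) {
  check_comparable(t1, t2)
  if (is_rooted(t1)) stop("heuristic runs on unrooted trees (see unroot_with_dummy)")
  r1 <- contract_nonmixed_bad_edges(t1, t2)
  r2 <- contract_nonmixed_bad_edges(t2, t1)
  T1 <- r1$tree; T2 <- r2$tree
  pairs <- decompose_bad_subtrees(T1, T2)
  ops1 <- r1$ops
  ops2 <- r2$ops
  for (p in pairs) {
    plan1 <- region_plan(T1, p$nodes1)
    plan2 <- region_plan(T2, p$nodes2)
    T1 <- plan1$tree; T2 <- plan2$tree
    co <- coordinate_labels(plan1$choices, plan2$choices)
    ex1 <- region_exec(T1, plan1$region, plan1$choices[[co$lab1]])
    ex2 <- region_exec(T2, plan2$region, plan2$choices[[co$lab2]])
    T1 <- ex1$tree; T2 <- ex2$tree
    ops1 <- c(ops1, plan1$ops, ex1$ops)
    ops2 <- c(ops2, plan2$ops, ex2$ops)
    if (ex1$final_label != ex2$final_label) {
      T1 <- apply_flip(T1, ex1$node, ex2$final_label)
      ops1 <- c(ops1, list(op_flip(ex1$node, ex2$final_label)))
    }
  }
  rev2 <- reverse_ops_onto(ops2, match_nodes(T2, T1), T1)
  new_dist_report(edit_script(c(ops1, rev2$ops)), "methodology2")
}

#' Labeled distance via full contraction to a star
#'
#' The alternative global strategy: contract `t1` entirely to a star
#' (good edges included), contract `t2` entirely to a star, coordinate
#' the two star labels, and replay the second contraction backwards as
#' extensions; one flip joins the stars if their labels must differ.
#' On some instances (when contracting a good edge lets separate bad
#' subtrees share flips) this beats [methodology2()].
#'
#' @param t1,t2 unrooted [lrf_tree] objects on the same leaf set.
#' @return An `lrf_dist_report`.
#' @export
star_path_cost <- function(t1, t2) {
  check_comparable(t1, t2)
  if (is_rooted(t1)) stop("heuristic runs on unrooted trees (see unroot_with_dummy)")
  plan1 <- region_plan(t1, internal_nodes(t1))
  plan2 <- region_plan(t2, internal_nodes(t2))
  co <- coordinate_labels(plan1$choices, plan2$choices)
  ex1 <- region_exec(plan1$tree, plan1$region, plan1$choices[[co$lab1]])
  ex2 <- region_exec(plan2$tree, plan2$region, plan2$choices[[co$lab2]])
  T1 <- ex1$tree
  ops1 <- c(plan1$ops, ex1$ops)
  ops2 <- c(plan2$ops, ex2$ops)
  if (ex1$final_label != ex2$final_label) {
    T1 <- apply_flip(T1, ex1$node, ex2$final_label)
    ops1 <- c(ops1, list(op_flip(ex1$node, ex2$final_label)))
  }
  rev2 <- reverse_ops_onto(ops2, match_nodes(ex2$tree, T1), T1)
  new_dist_report(edit_script(c(ops1, rev2$ops)), "star_path")
}

#' Labeled Robinson-Foulds distance estimate
#'
#' Runs both strategies ([methodology2()] and [star_path_cost()]) and
#' returns the cheaper witness (ties go to the per-pair heuristic).
#' Rooted pairs are converted with [unroot_with_dummy()] using a shared
#' dummy leaf, which preserves the distance. The result is always an
#' upper bound on the exact labeled edit distance, since its script is a
#' valid edit path.
#'
#' @param t1,t2 [lrf_tree] objects on the same leaf set, both rooted or
#'   both unrooted.
#' @param dummy_name dummy leaf name used for rooted pairs.
#' @return An `lrf_dist_report` with the classical RF distance and both
#'   strategy totals attached.
#' @export
#' @examples
#' p <- fig3_pair()
#' labeled_rf_estimate(p$t, p$t_prime)
labeled_rf_estimate <- function(t1, t2, dummy_name = "__ROOT__") {
  check_comparable(t1, t2)
  if (is_rooted(t1)) {
    t1 <- unroot_with_dummy(t1, dummy_name)
    t2 <- unroot_with_dummy(t2, dummy_name)
  }
  m2 <- methodology2(t1, t2)
  sp <- star_path_cost(t1, t2)
  best <- if (sp$total < m2$total) sp else m2
  best$rf_classical <- rf_distance(t1, t2)
  best$alt_totals <- c(methodology2 = m2$total, star_path = sp$total)
  best
}

#' General upper bound on the labeled distance
#'
#' For two trees with `n` internal nodes each and `e`, `e_prime` internal
#' bad edges, the labeled distance is at most `e + e_prime + n`:
#' contract all bad edges of one tree, flip at most the minority label
#' class of each tree, and extend to rebuild the other.
#'
#' @param e,e_prime bad internal edge counts of the two trees.
#' @param n internal node count.
#' @return Integer bound.
#' @export
#' @examples
#' labeled_rf_upper_bound(8, 8, 9)
labeled_rf_upper_bound <- function(e, e_prime, n) {
  if (any(c(e, e_prime, n) < 0)) stop("counts must be non-negative")
  as.integer(e + e_prime + n)
}
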