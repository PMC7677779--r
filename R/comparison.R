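# ---- bipartitions and clades ------------------------------------------

# Leaf names on b's side of the edge {a,b}
side_leaves <- function(t, a, b) {
  seen <- rep(FALSE, length(t$adj))
  seen[c(a, b)] <- TRUE
  queue <- b
  out <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (!is.na(t$leaf[v])) out <- c(out, t$leaf[v])
    nb <- t$adj[[v]]
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  out
}

# Canonical string form of the bipartition induced by the edge {a,b}:
# the side containing the globally smallest leaf name, sorted and joined.
# Using the canonical side makes bipartitions comparable as plain strings.
bipartition_key <- function(t, a, b, universe) {
  sb <- side_leaves(t, a, b)
  sa <- setdiff(universe, sb)
  side <- if (min(universe) %in% sa) sa else sb
  paste(sort(side), collapse = ",")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One bipartition per internal edge, in canonical string form (the side
#' holding the smallest leaf name, comma-joined). Terminal edges induce
#' trivial bipartitions and are excluded.
#'
#' @param t an unrooted [lrf_tree].
#' @return Character vector of bipartition keys (sorted, no duplicates).
#' @export
#' @examples
#' bipartition_set(parse_newick("((A,B)Spe,(C,D)Dup,E)Spe;"))
bipartition_set <- function(t) {
  if (is_rooted(t)) stop("bipartitions are defined for unrooted trees")
  u <- sort(leaf_names(t))
  e <- tree_edges(t, internal_only = TRUE)
  keys <- vapply(seq_len(nrow(e)),
                 function(i) bipartition_key(t, e[i, 1L], e[i, 2L], u),
                 character(1L))
  sort(unique(keys))
}

#' Non-trivial clades of a rooted tree
#'
#' The clade of an internal node is the leaf set of the subtree below it;
#' clades of size 1 and the full leaf set (the root clade) are trivial and
#' excluded.
#'
#' @param t a rooted [lrf_tree].
#' @return Character vector of clade keys (sorted leaf names, comma-joined).
#' @export
#' @examples
#' clade_set(parse_newick("(((A,B)Dup,C)Spe,D)Spe;"))
clade_set <- function(t) {
  if (!is_rooted(t)) stop("clades are defined for rooted trees")
  n <- length(tree_leaves(t))
  keys <- character(0)
  walk <- function(v, parent) {
    if (!is.na(t$leaf[v])) return(t$leaf[v])
    below <- unlist(lapply(setdiff(t$adj[[v]], parent), walk, parent = v))
    if (v != t$root && length(below) >= 2L && length(below) < n) {
      keys <<- c(keys, paste(sort(below), collapse = ","))
    }
    below
  }
  walk(t$root, 0L)
  sort(unique(keys))
}

check_comparable <- function(t1, t2) {
  if (is_rooted(t1) != is_rooted(t2)) {
    stop("cannot compare a rooted with an unrooted tree")
  }
  if (!setequal(leaf_names(t1), leaf_names(t2))) {
    stop("trees are not on the same leaf set")
  }
}

#' Classical Robinson-Foulds distance
#'
#' Symmetric-difference size of the bipartition sets (unrooted pair) or
#' clade sets (rooted pair). Event labels play no role.
#'
#' @param t1,t2 [lrf_tree] objects on the same leaf set, both rooted or
#'   both unrooted.
#' @return Integer distance.
#' @export
#' @examples
#' rf_distance(parse_newick("((A,B)Spe,(C,D)Spe,E)Spe;"),
#'             parse_newick("((A,C)Spe,(B,D)Spe,E)Spe;"))
rf_distance <- function(t1, t2) {
  check_comparable(t1, t2)
  s1 <- if (is_rooted(t1)) clade_set(t1) else bipartition_set(t1)
  s2 <- if (is_rooted(t2)) clade_set(t2) else bipartition_set(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# ---- edge classification ----------------------------------------------

classify_one <- function(t, other_bips, universe) {
  e <- tree_edges(t)
  n <- nrow(e)
  internal <- logical(n); good <- logical(n); mixed <- logical(n)
  bip <- character(n)
  for (i in seq_len(n)) {
    a <- e[i, 1L]; b <- e[i, 2L]
    internal[i] <- is.na(t$leaf[a]) && is.na(t$leaf[b])
    bip[i] <- bipartition_key(t, a, b, universe)
    good[i] <- if (internal[i]) bip[i] %in% other_bips else TRUE
    mixed[i] <- internal[i] && t$label[a] != t$label[b]
  }
  data.frame(a = e[, 1L], b = e[, 2L], internal = internal, good = good,
             mixed = mixed, bipartition = bip)
}

#' Classify edges as good or bad against another tree
#'
#' An internal edge is *good* when its bipartition also occurs in the
#' other tree, *bad* otherwise; terminal edges are always good. The
#' classification also reports which edges are mixed (endpoint labels
#' differ), the precondition gate for contraction.
#'
#' @param t1,t2 unrooted [lrf_tree] objects on the same leaf set.
#' @return A list with elements `t1` and `t2`, each a data frame with one
#'   row per edge: node ids `a`, `b`, and logicals `internal`, `good`,
#'   `mixed`, plus the canonical `bipartition` key.
#' @export
classify_edges <- function(t1, t2) {
  check_comparable(t1, t2)
  if (is_rooted(t1)) stop("classification is defined for unrooted trees")
  u <- sort(leaf_names(t1))
  list(t1 = classify_one(t1, bipartition_set(t2), u),
       t2 = classify_one(t2, bipartition_set(t1), u))
}

# Connected components of internal nodes under bad internal edges,
# plus the multiset of boundary (good or terminal) edge bipartitions.
bad_components <- function(t, cls) {
  iv <- internal_nodes(t)
  # union-find over positions in iv
  parent <- seq_along(iv)
  pos <- stats::setNames(seq_along(iv), iv)
  root_of <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  badrows <- cls[cls$internal & !cls$good, , drop = FALSE]
  for (i in seq_len(nrow(badrows))) {
    ra <- root_of(pos[[as.character(badrows$a[i])]])
    rb <- root_of(pos[[as.character(badrows$b[i])]])
    if (ra != rb) parent[rb] <- ra
  }
  groups <- split(iv, vapply(seq_along(iv), root_of, integer(1L)))
  lapply(unname(groups), function(nodes) {
    inb <- cls$a %in% nodes | cls$b %in% nodes
    boundary <- cls$bipartition[inb & cls$good]
    list(nodes = sort(nodes), boundary = sort(boundary),
         n_bad = sum(cls$internal & !cls$good &
                       cls$a %in% nodes & cls$b %in% nodes))
  })
}

#' Decompose two trees into matched pairs of maximal bad subtrees
#'
#' A maximal bad subtree contains only bad internal edges and is bounded
#' by good (or terminal) edges. Its boundary bipartitions identify a
#' unique counterpart subtree in the other tree, and the pairing covers
#' every internal node of both trees; a node all of whose incident edges
#' are good forms a singleton subtree. These pairs are the units the
#' heuristic distance works on.
#'
#' @param t1,t2 unrooted [lrf_tree] objects on the same leaf set.
#' @return A list of pairs, each a list with `nodes1`, `nodes2` (internal
#'   node ids of the matched subtrees in each tree), `boundary` (sorted
#'   boundary bipartition keys), and `n_bad1`, `n_bad2` (bad internal edge
#'   counts on each side).
#' @export
decompose_bad_subtrees <- function(t1, t2) {
  cls <- classify_edges(t1, t2)
  c1 <- bad_components(t1, cls$t1)
  c2 <- bad_components(t2, cls$t2)
  key2 <- vapply(c2, function(g) paste(g$boundary, collapse = "|"), character(1L))
  pairs <- lapply(c1, function(g) {
    hit <- which(key2 == paste(g$boundary, collapse = "|"))
    if (length(hit) != 1L) {
      stop("bad-subtree boundary has no unique counterpart; trees may not be comparable")
    }
    list(nodes1 = g$nodes, nodes2 = c2[[hit]]$nodes, boundary = g$boundary,
         n_bad1 = g$n_bad, n_bad2 = c2[[hit]]$n_bad)
  })
  matched2 <- unlist(lapply(pairs, function(p) p$nodes2))
  if (!setequal(matched2, internal_nodes(t2)) ||
      length(matched2) != length(internal_nodes(t2))) {
    stop("bad-subtree pairing does not cover the second tree")
  }
  pairs
}
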