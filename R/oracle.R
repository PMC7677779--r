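# Session-level cache of explored edit graphs, one per leaf-name
# universe. Exact distances on small trees are BFS queries on this graph;
# caching the adjacency makes repeated queries (simulation studies,
# property tests) cheap after the first exploration.
lrf_cache <- new.env(parent = emptyenv())

#' Canonical fingerprint of a labeled unrooted tree
#'
#' A deterministic string, invariant under internal-node renaming: the
#' lexicographically smallest of the recursive serializations rooted at
#' each internal node (leaf names anchor the recursion, labels appear at
#' every internal position). Two trees on the same leaf set have equal
#' keys exactly when they are isomorphic as labeled trees.
#'
#' @param t an unrooted [lrf_tree].
#' @return A character scalar.
#' @export
#' @examples
#' canonical_key(parse_newick("((A,B)Spe,C,D)Dup;"))
canonical_key <- function(t) {
  if (is_rooted(t)) stop("canonical keys are defined for unrooted trees")
  iv <- internal_nodes(t)
  min(vapply(iv, function(v) rooted_serial(t, v, 0L), character(1L)))
}

#' All trees one edit operation away
#'
#' Enumerates every legal flip, every legal contraction (non-mixed
#' internal edges) and every legal extension (internal nodes of degree
#' at least 4, moved subsets of size `2:(degree - 2)`), deduplicated by
#' [canonical_key()]. This is the neighborhood in the edit graph whose
#' shortest paths define the exact labeled distance.
#'
#' @param t an unrooted [lrf_tree].
#' @return A named list of trees; names are canonical keys.
#' @export
tree_neighbors <- function(t) {
  out <- list()
  add <- function(tn) {
    k <- canonical_key(tn)
    if (is.null(out[[k]])) out[[k]] <<- tn
  }
  iv <- internal_nodes(t)
  for (v in iv) add(apply_flip(t, v))
  e <- tree_edges(t, internal_only = TRUE)
  for (i in seq_len(nrow(e))) {
    if (!is_mixed_edge(t, e[i, 1L], e[i, 2L])) {
      add(apply_contraction(t, e[i, ]))
    }
  }
  for (v in iv) {
    deg <- node_degree(t, v)
    if (deg < 4L) next
    nb <- t$adj[[v]]
    for (size in 2:(deg - 2L)) {
      sets <- utils::combn(nb, size, simplify = FALSE)
      for (X in sets) add(apply_extension(t, v, X))
    }
  }
  out
}

universe_cache <- function(leaves) {
  ukey <- paste(sort(leaves), collapse = "\r")
  u <- get0(ukey, envir = lrf_cache)
  if (is.null(u)) {
    u <- new.env(parent = emptyenv())
    u$key2id <- new.env(parent = emptyenv())
    u$trees <- list()
    u$adjn <- list()
    assign(ukey, u, envir = lrf_cache)
  }
  u
}

cache_intern <- function(u, t, key = canonical_key(t)) {
  id <- get0(key, envir = u$key2id)
  if (is.null(id)) {
    id <- length(u$trees) + 1L
    u$trees[[id]] <- t
    u$adjn[id] <- list(NULL)
    assign(key, id, envir = u$key2id)
  }
  id
}

cache_expand <- function(u, id) {
  if (!is.null(u$adjn[[id]])) return(u$adjn[[id]])
  nb <- tree_neighbors(u$trees[[id]])
  ids <- vapply(seq_along(nb),
                function(i) cache_intern(u, nb[[i]], names(nb)[i]),
                integer(1L))
  u$adjn[[id]] <- ids
  ids
}

#' Exact labeled edit distance by breadth-first search
#'
#' Shortest path in the edit graph between the two trees' canonical keys,
#' found by BFS with lazy neighborhood expansion. The explored graph is
#' cached per leaf-name universe for the session, so repeated queries on
#' the same leaf set are fast. Intended for small trees (about 7 leaves
#' or fewer); the state space grows super-exponentially beyond that.
#'
#' @param t1,t2 unrooted [lrf_tree] objects on the same leaf set.
#' @param max_depth search bound; the default
#'   (bad edges of both trees plus both internal node counts) always
#'   suffices. An error is raised if the bound is exceeded.
#' @return Integer distance.
#' @export
#' @examples
#' exact_distance(parse_newick("((A,B)Spe,(C,D)Dup,E)Spe;"),
#'                parse_newick("((A,B)Dup,(C,D)Dup,E)Spe;"))
exact_distance <- function(t1, t2, max_depth = NULL) {
  check_comparable(t1, t2)
  if (is_rooted(t1)) stop("exact distance runs on unrooted trees")
  if (is.null(max_depth)) {
    cls <- classify_edges(t1, t2)
    max_depth <- sum(!cls$t1$good) + sum(!cls$t2$good) +
      length(internal_nodes(t1)) + length(internal_nodes(t2))
  }
  u <- universe_cache(leaf_names(t1))
  id1 <- cache_intern(u, t1)
  id2 <- cache_intern(u, t2)
  if (id1 == id2) return(0L)
  depth <- integer(0)
  depth[id1] <- 0L
  frontier <- id1
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    if (d > max_depth) {
      stop(sprintf("exact distance exceeds max_depth = %d", max_depth))
    }
    nxt <- integer(0)
    for (v in frontier) {
      nb <- cache_expand(u, v)
      for (w in nb) {
        if (is.na(depth[w]) || length(depth) < w) {
          if (w == id2) return(d)
          depth[w] <- d
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  stop("edit graph exhausted without reaching the target tree")
}

#' Enumerate the full labeled-tree space on a leaf set
#'
#' Breadth-first closure of the edit graph starting from the SPE star
#' tree; since extensions generate every topology and flips every
#' labeling, this is the complete set of event-labeled unrooted trees on
#' the given leaves. Only feasible for small leaf sets (about 6 or
#' fewer).
#'
#' @param leaves character vector of at least 3 leaf names.
#' @return A named list of trees keyed by canonical key.
#' @export
all_labeled_trees <- function(leaves) {
  stopifnot(length(leaves) >= 3L)
  star <- labeled_tree(cbind("c0", leaves), labels = c(c0 = "SPE"))
  u <- universe_cache(leaves)
  queue <- cache_intern(u, star)
  seen <- logical(0)
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- cache_expand(u, v)
    for (w in nb) {
      if (length(seen) < w || is.na(seen[w]) || !seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  keys <- ls(u$key2id)
  ids <- vapply(keys, function(k) get(k, envir = u$key2id), integer(1L))
  stats::setNames(u$trees[ids], keys)
}
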