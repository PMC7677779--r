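#' Convert a rooted tree to its unrooted counterpart with a dummy leaf
#'
#' Attaches a dummy leaf to the root and drops the root status. This is
#' the standard device linking the rooted (clade-based) and unrooted
#' (bipartition-based) Robinson-Foulds distances: the clade distance of
#' two rooted trees equals the bipartition distance of their dummy-leaf
#' unrooted versions, provided both use the same dummy name.
#'
#' @param t a rooted [lrf_tree].
#' @param dummy_name name for the added leaf; the default is chosen to
#'   avoid clashes with biological identifiers.
#' @return An unrooted `lrf_tree` with one more leaf; all labels kept.
#' @export
#' @examples
#' unroot_with_dummy(parse_newick("((A,B)Spe,(C,D)Dup)Spe;"))
unroot_with_dummy <- function(t, dummy_name = "__ROOT__") {
  if (!is_rooted(t)) stop("tree is already unrooted")
  if (dummy_name %in% leaf_names(t)) {
    stop(sprintf("dummy name '%s' collides with an existing leaf", dummy_name))
  }
  r <- t$root
  d <- length(t$adj) + 1L
  t$adj[[d]] <- r
  t$adj[[r]] <- c(t$adj[[r]], d)
  t$leaf[d] <- dummy_name
  t$label[d] <- NA_character_
  t$root <- NA_integer_
  t$anchor <- r
  assert_valid(t)
  t
}

# BFS edge-distances from v to all alive nodes (NA = unreachable)
bfs_dist <- function(t, v) {
  dist <- rep(NA_integer_, length(t$adj))
  dist[v] <- 0L
  queue <- v
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    nb <- t$adj[[x]]
    new <- nb[is.na(dist[nb])]
    dist[new] <- dist[x] + 1L
    queue <- c(queue, new)
  }
  dist
}

#' Metric geometry of an unrooted tree
#'
#' The *eccentricity* of a node is its maximum edge-distance to a leaf;
#' the *diameter* is the length (in edges) of the longest leaf-to-leaf
#' chain; the *midpoints* are the nodes of minimum eccentricity, which is
#' always `ceiling(diameter / 2)`. These quantities drive the optimal
#' contraction of a mixed tree: contracting from a midpoint uses
#' `eccentricity - 1` flips.
#'
#' @param t an unrooted [lrf_tree] with at least 2 leaves.
#' @return A list with `diameter` (integer), `eccentricity` (integer
#'   vector named by node id, over all alive nodes), and `midpoints`
#'   (integer node ids).
#' @export
#' @examples
#' tree_geometry(parse_newick("((A,B)Spe,(C,D)Dup,E)Spe;"))
tree_geometry <- function(t) {
  if (is_rooted(t)) stop("geometry is defined for unrooted trees")
  lv <- tree_leaves(t)
  if (length(lv) < 2L) stop("need at least 2 leaves")
  alive <- alive_nodes(t)
  ecc <- vapply(alive, function(v) max(bfs_dist(t, v)[lv]), integer(1L))
  names(ecc) <- alive
  diam <- max(ecc[as.character(lv)])
  mid <- alive[ecc == min(ecc)]
  stopifnot(min(ecc) == ceiling(diam / 2))
  list(diameter = as.integer(diam), eccentricity = ecc, midpoints = mid)
}
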