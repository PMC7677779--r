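#' @keywords internal
"_PACKAGE"

# The two-symbol event alphabet. Kept as plain strings so trees print and
# serialize readably; flip_label() is the only way labels are ever changed.
LRF_LABELS <- c("SPE", "DUP")

#' Flip an event label
#'
#' The label alphabet has exactly two symbols (`"SPE"` and `"DUP"`), so a
#' flip is an involution: `flip_label(flip_label(x)) == x`.
#'
#' @param label `"SPE"` or `"DUP"` (vectorized).
#' @return The other label.
#' @export
#' @examples
#' flip_label("SPE")
flip_label <- function(label) {
  bad <- !label %in% LRF_LABELS
  if (any(bad)) {
    stop("unknown label(s): ", paste(unique(label[bad]), collapse = ", "))
  }
  unname(ifelse(label == "SPE", "DUP", "SPE"))
}

new_lrf_tree <- function(adj, leaf, label, root = NA_integer_,
                         anchor = NA_integer_) {
  structure(
    list(adj = adj, leaf = leaf, label = label,
         root = as.integer(root), anchor = as.integer(anchor)),
    class = "lrf_tree"
  )
}

#' Build an event-labeled tree from an edge list
#'
#' Constructs an [lrf_tree] from node names. Every name appearing in
#' `labels` is an internal node carrying that event label; every other name
#' is a leaf. This is the programmatic companion to [parse_newick()] and is
#' what the bundled fixtures use.
#'
#' @param edges two-column character matrix (or data frame) of node names;
#'   each row is an undirected edge.
#' @param labels named character vector mapping internal node names to
#'   `"SPE"` or `"DUP"`.
#' @param root optional name of the root node; omit (default) for an
#'   unrooted tree.
#' @return A validated `lrf_tree`.
#' @export
#' @examples
#' t <- labeled_tree(rbind(c("u", "A"), c("u", "B"), c("u", "v"),
#'                         c("v", "C"), c("v", "D")),
#'                   labels = c(u = "SPE", v = "DUP"))
#' t
labeled_tree <- function(edges, labels, root = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  nms <- unique(c(edges[, 1L], edges[, 2L]))
  if (!all(names(labels) %in% nms)) {
    stop("labels refer to unknown node names: ",
         paste(setdiff(names(labels), nms), collapse = ", "))
  }
  id <- seq_along(nms)
  names(id) <- nms
  n <- length(nms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- id[[edges[i, 1L]]]
    b <- id[[edges[i, 2L]]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  leaf <- rep(NA_character_, n)
  lab <- rep(NA_character_, n)
  internal <- nms %in% names(labels)
  leaf[!internal] <- nms[!internal]
  lab[internal] <- unname(labels[nms[internal]])
  rt <- if (is.null(root)) NA_integer_ else id[[root]]
  anchor <- if (!is.null(root)) rt else which(internal)[1L]
  t <- new_lrf_tree(adj, leaf, lab, root = rt, anchor = anchor)
  assert_valid(t)
  t
}

alive_nodes <- function(t) which(!vapply(t$adj, is.null, logical(1L)))

#' Leaf and internal node accessors
#'
#' @param t an [lrf_tree].
#' @return Integer node ids (`tree_leaves`, `internal_nodes`), the named
#'   leaf character vector (`leaf_names`), or an integer degree.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
tree_leaves <- function(t) {
  alive <- alive_nodes(t)
  alive[!is.na(t$leaf[alive])]
}

#' @rdname tree-accessors
#' @export
internal_nodes <- function(t) {
  alive <- alive_nodes(t)
  alive[is.na(t$leaf[alive])]
}

#' @rdname tree-accessors
#' @export
leaf_names <- function(t) {
  lv <- tree_leaves(t)
  stats::setNames(t$leaf[lv], lv)
}

#' @rdname tree-accessors
#' @param v node id.
#' @export
node_degree <- function(t, v) length(t$adj[[v]])

#' @rdname tree-accessors
#' @export
is_rooted <- function(t) !is.na(t$root)

is_internal <- function(t, v) is.na(t$leaf[v]) && !is.null(t$adj[[v]])

#' List the edges of a tree
#'
#' @param t an [lrf_tree].
#' @param internal_only if `TRUE`, keep only edges joining two internal
#'   nodes.
#' @return Two-column integer matrix of node ids, each row an edge with
#'   `a < b`, in canonical (sorted) order.
#' @export
tree_edges <- function(t, internal_only = FALSE) {
  res <- matrix(0L, 0L, 2L)
  for (v in alive_nodes(t)) {
    nb <- t$adj[[v]]
    nb <- nb[nb > v]
    if (length(nb)) res <- rbind(res, cbind(v, nb))
  }
  colnames(res) <- c("a", "b")
  if (internal_only) {
    keep <- is.na(t$leaf[res[, 1L]]) & is.na(t$leaf[res[, 2L]])
    res <- res[keep, , drop = FALSE]
  }
  res[order(res[, 1L], res[, 2L]), , drop = FALSE]
}

#' Is an edge mixed?
#'
#' An edge is *mixed* when its two endpoints are internal nodes carrying
#' different event labels; mixed edges cannot be contracted without a prior
#' flip. A tree is a *mixed tree* when all its internal edges are mixed.
#'
#' @param t an [lrf_tree].
#' @param a,b endpoints of an edge.
#' @return Logical.
#' @export
is_mixed_edge <- function(t, a, b) {
  isTRUE(is.na(t$leaf[a]) && is.na(t$leaf[b]) && t$label[a] != t$label[b])
}

#' @rdname is_mixed_edge
#' @export
is_mixed_tree <- function(t) {
  e <- tree_edges(t, internal_only = TRUE)
  all(vapply(seq_len(nrow(e)),
             function(i) is_mixed_edge(t, e[i, 1L], e[i, 2L]),
             logical(1L)))
}

#' Validate an event-labeled tree
#'
#' Checks the structural invariants of the tree class: connected and
#' acyclic; unique leaf names; every internal node labeled with one of the
#' two event symbols and no leaf labeled; internal degrees at least 3
#' except a root, which may have degree 2.
#'
#' @param t an [lrf_tree].
#' @return Character vector of human-readable violations; empty when the
#'   tree is valid. Violations are data, not errors.
#' @export
validate_tree <- function(t) {
  out <- character(0)
  alive <- alive_nodes(t)
  n <- length(alive)
  if (n == 0L) return("tree has no nodes")
  # symmetry of the adjacency relation
  for (v in alive) {
    for (u in t$adj[[v]]) {
      if (is.null(t$adj[[u]]) || !(v %in% t$adj[[u]])) {
        out <- c(out, sprintf("edge {%d,%d} is not symmetric", v, u))
      }
    }
  }
  edges <- sum(lengths(t$adj[alive])) / 2
  if (edges != n - 1L) {
    out <- c(out, sprintf("not a tree: %d nodes but %g edges", n, edges))
  }
  # connectivity by BFS
  seen <- rep(FALSE, length(t$adj))
  queue <- alive[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- t$adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen[alive])) out <- c(out, "tree is not connected")
  lv <- alive[!is.na(t$leaf[alive])]
  iv <- alive[is.na(t$leaf[alive])]
  if (anyDuplicated(t$leaf[lv])) {
    dup <- unique(t$leaf[lv][duplicated(t$leaf[lv])])
    out <- c(out, paste0("duplicate leaf name(s): ", paste(dup, collapse = ", ")))
  }
  for (v in lv) {
    if (length(t$adj[[v]]) != 1L) {
      out <- c(out, sprintf("leaf %d ('%s') has degree %d", v, t$leaf[v],
                            length(t$adj[[v]])))
    }
    if (!is.na(t$label[v])) {
      out <- c(out, sprintf("leaf %d ('%s') carries a label", v, t$leaf[v]))
    }
  }
  for (v in iv) {
    if (is.na(t$label[v])) {
      out <- c(out, sprintf("internal node %d lacks a label", v))
    } else if (!t$label[v] %in% LRF_LABELS) {
      out <- c(out, sprintf("internal node %d has unknown label '%s'",
                            v, t$label[v]))
    }
    mindeg <- if (!is.na(t$root) && v == t$root) 2L else 3L
    if (length(t$adj[[v]]) < mindeg) {
      out <- c(out, sprintf("internal node %d has degree %d (minimum %d)",
                            v, length(t$adj[[v]]), mindeg))
    }
  }
  if (!is.na(t$root) && !(t$root %in% iv)) {
    out <- c(out, "root is not an alive internal node")
  }
  out
}

assert_valid <- function(t) {
  v <- validate_tree(t)
  if (length(v)) stop("invalid labeled tree: ", paste(v, collapse = "; "))
  invisible(t)
}

#' @export
print.lrf_tree <- function(x, ...) {
  lv <- tree_leaves(x)
  iv <- internal_nodes(x)
  cat(sprintf("Event-labeled %s tree: %d leaves, %d internal nodes (%d SPE, %d DUP)\n",
              if (is_rooted(x)) "rooted" else "unrooted",
              length(lv), length(iv),
              sum(x$label[iv] == "SPE"), sum(x$label[iv] == "DUP")))
  nwk <- write_newick(x)
  if (nchar(nwk) > 70) nwk <- paste0(substr(nwk, 1, 67), "...")
  cat(" ", nwk, "\n", sep = "")
  invisible(x)
}

#' Test labeled-topology isomorphism
#'
#' Two trees are equal when there is a bijection of their nodes preserving
#' adjacency, leaf names, internal labels and rootedness; internal node ids
#' are arbitrary bookkeeping and never enter the comparison.
#'
#' @param t1,t2 [lrf_tree] objects.
#' @return Logical.
#' @export
tree_isomorphic <- function(t1, t2) {
  if (is_rooted(t1) != is_rooted(t2)) return(FALSE)
  if (!setequal(leaf_names(t1), leaf_names(t2))) return(FALSE)
  if (is_rooted(t1)) {
    identical(rooted_serial(t1, t1$root, 0L), rooted_serial(t2, t2$root, 0L))
  } else {
    identical(canonical_key(t1), canonical_key(t2))
  }
}

# Minimal recursive serialization of the subtree at v seen from `parent`
# (0 = none); children serialized in sorted order so the string is
# invariant under node renaming.
rooted_serial <- function(t, v, parent) {
  if (!is.na(t$leaf[v])) return(t$leaf[v])
  kids <- setdiff(t$adj[[v]], parent)
  parts <- vapply(kids, function(u) rooted_serial(t, u, v), character(1L))
  paste0("(", paste(sort(parts), collapse = ","), ")",
         substr(t$label[v], 1L, 1L))
}
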