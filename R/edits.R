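# ---- the three unit-cost edit operations ------------------------------

#' Edit operations on event-labeled trees
#'
#' The labeled Robinson-Foulds distance is built from three unit-cost
#' operations: `apply_contraction()` removes an internal edge whose two
#' endpoints carry the same label, merging them (the merged node keeps id
#' `edge[1]`); `apply_extension()` is its inverse, moving a subset `moved`
#' of a node's neighbors onto a new node that copies the label;
#' `apply_flip()` changes one internal node's label to the other symbol.
#' A mixed edge (differently-labeled endpoints) cannot be contracted
#' without a prior flip, and an extension may neither move fewer than 2
#' neighbors nor leave the split node with degree below 3.
#'
#' @param t an [lrf_tree].
#' @param edge integer pair `c(a, b)`; `b` is merged into `a`.
#' @param node internal node id.
#' @param moved integer ids of the neighbors moved onto the new node.
#' @param new_label the label to assign; defaults to the flipped current
#'   label (the only legal choice).
#' @return The edited tree. The new node created by an extension gets id
#'   `length(t$adj) + 1`.
#' @name edit-operations
#' @examples
#' star <- parse_newick("(A,B,C,D)Spe;")
#' q <- apply_extension(star, internal_nodes(star), tree_leaves(star)[1:2])
#' apply_contraction(q, tree_edges(q, internal_only = TRUE)[1, ])
NULL

#' @rdname edit-operations
#' @export
apply_contraction <- function(t, edge) {
  a <- edge[[1L]]; b <- edge[[2L]]
  if (is.null(t$adj[[a]]) || is.null(t$adj[[b]]) || !(b %in% t$adj[[a]])) {
    stop(sprintf("no edge {%s,%s} in the tree", a, b))
  }
  if (!is.na(t$leaf[a]) || !is.na(t$leaf[b])) {
    stop("cannot contract a terminal edge")
  }
  if (t$label[a] != t$label[b]) {
    stop("cannot contract a mixed edge: a node flip is required first")
  }
  moved <- setdiff(t$adj[[b]], a)
  for (u in moved) t$adj[[u]][t$adj[[u]] == b] <- a
  t$adj[[a]] <- c(setdiff(t$adj[[a]], b), moved)
  t$adj[b] <- list(NULL)
  t$label[b] <- NA_character_
  if (!is.na(t$anchor) && t$anchor == b) t$anchor <- a
  if (!is.na(t$root) && t$root == b) t$root <- a
  t
}

#' @rdname edit-operations
#' @export
apply_extension <- function(t, node, moved) {
  if (is.null(t$adj[[node]]) || !is.na(t$leaf[node])) {
    stop("extension requires an internal node")
  }
  deg <- length(t$adj[[node]])
  if (!all(moved %in% t$adj[[node]])) {
    stop("moved set must be neighbors of the extended node")
  }
  if (length(moved) < 2L) stop("extension must move at least 2 neighbors")
  if (length(moved) > deg - 2L) {
    stop("extension would leave a node of degree < 3")
  }
  y <- length(t$adj) + 1L
  for (u in moved) t$adj[[u]][t$adj[[u]] == node] <- y
  t$adj[[y]] <- c(node, moved)
  t$adj[[node]] <- c(setdiff(t$adj[[node]], moved), y)
  t$leaf[y] <- NA_character_
  t$label[y] <- t$label[node]
  t
}

#' @rdname edit-operations
#' @export
apply_flip <- function(t, node, new_label = flip_label(t$label[node])) {
  if (is.null(t$adj[[node]]) || !is.na(t$leaf[node])) {
    stop("only internal nodes can be flipped")
  }
  if (new_label == t$label[node]) {
    stop("flip must assign the other label")
  }
  t$label[node] <- new_label
  t
}

# ---- edit scripts ------------------------------------------------------

op_flip <- function(node, new_label) {
  list(kind = "FLIP", node = as.integer(node), new_label = new_label)
}
op_contract <- function(a, b, moved = NULL) {
  # `moved` (b's other neighbors at application time) is annotated by the
  # heuristic executors so a contraction can later be reversed as an
  # extension; it is not needed to apply the op forward.
  list(kind = "CONTRACT", a = as.integer(a), b = as.integer(b),
       moved = if (!is.null(moved)) as.integer(moved))
}
op_extend <- function(node, moved) {
  list(kind = "EXTEND", node = as.integer(node), moved = as.integer(moved))
}

#' Edit scripts
#'
#' An ordered sequence of edit operations, replayable from a source tree.
#' `edit_script()` wraps a list of operations; `script_counts()` tallies
#' them by kind.
#'
#' @param ops list of operations as stored in [mutate()] or distance
#'   reports.
#' @return `edit_script()` returns an `lrf_edit_script`; `script_counts()`
#'   a named integer vector with `flips`, `contractions`, `extensions`,
#'   `total`.
#' @export
edit_script <- function(ops = list()) {
  structure(ops, class = "lrf_edit_script")
}

#' @rdname edit_script
#' @param script an `lrf_edit_script`.
#' @export
script_counts <- function(script) {
  kinds <- vapply(script, function(o) o$kind, character(1L))
  c(flips = sum(kinds == "FLIP"),
    contractions = sum(kinds == "CONTRACT"),
    extensions = sum(kinds == "EXTEND"),
    total = length(kinds))
}

#' @export
print.lrf_edit_script <- function(x, ...) {
  cnt <- script_counts(x)
  cat(sprintf("Edit script: %d operations (%d flips, %d contractions, %d extensions)\n",
              cnt[["total"]], cnt[["flips"]], cnt[["contractions"]],
              cnt[["extensions"]]))
  invisible(x)
}

#' Serialize or parse the line-oriented edit-script format
#'
#' One line per operation: `FLIP <node> <label>`, `CONTRACT <a> <b>`, or
#' `EXTEND <node> <id,id,...>`. Node ids refer to the replay state: ids
#' are stable under replay from the script's source tree (contractions
#' keep the first endpoint, extensions append a fresh id).
#'
#' @param script an [edit_script()].
#' @param lines character vector as produced by `format_edit_script()`.
#' @return A character vector, or an `lrf_edit_script`.
#' @export
format_edit_script <- function(script) {
  vapply(script, function(o) {
    switch(o$kind,
           FLIP = sprintf("FLIP %d %s", o$node, o$new_label),
           CONTRACT = sprintf("CONTRACT %d %d", o$a, o$b),
           EXTEND = sprintf("EXTEND %d %s", o$node,
                            paste(o$moved, collapse = ",")))
  }, character(1L))
}

#' @rdname format_edit_script
#' @export
read_edit_script <- function(lines) {
  ops <- lapply(lines[nzchar(trimws(lines))], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    switch(f[1L],
           FLIP = op_flip(as.integer(f[2L]), f[3L]),
           CONTRACT = op_contract(as.integer(f[2L]), as.integer(f[3L])),
           EXTEND = op_extend(as.integer(f[2L]),
                              as.integer(strsplit(f[3L], ",")[[1L]])),
           stop("unknown edit op: ", ln))
  })
  edit_script(ops)
}

apply_op <- function(t, op) {
  switch(op$kind,
         FLIP = apply_flip(t, op$node, op$new_label),
         CONTRACT = apply_contraction(t, c(op$a, op$b)),
         EXTEND = apply_extension(t, op$node, op$moved),
         stop("unknown operation kind: ", op$kind))
}

#' Replay an edit script from a source tree
#'
#' Applies the operations in order, stopping with an informative error at
#' the first illegal one; every intermediate tree is a valid labeled tree.
#'
#' @param script an [edit_script()].
#' @param source the [lrf_tree] the script starts from.
#' @return The final tree.
#' @export
replay <- function(script, source) {
  t <- source
  for (i in seq_along(script)) {
    t <- tryCatch(apply_op(t, script[[i]]), error = function(e) {
      stop(sprintf("illegal edit at index %d (%s): %s",
                   i, script[[i]]$kind, conditionMessage(e)), call. = FALSE)
    })
  }
  t
}

# ---- the random-edit simulator ----------------------------------------

sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Draw one random edit operation
#'
#' The mutation model used for benchmarking: with probability 0.3 the
#' label of a uniformly random internal node is flipped; the remaining
#' probability mass is spread evenly over all internal edges joining two
#' equally-labeled nodes (a contraction) and all nodes of degree greater
#' than 3 (an extension, with the moved subset drawn by choosing a size
#' uniformly in `2:(degree - 2)` and then a uniform subset of that size).
#' When neither a contractible edge nor an expandable node exists, the
#' 0.7 mass falls back to a flip. Randomness comes from R's global RNG;
#' seed via [set.seed()] or use [mutate()].
#'
#' @param t an [lrf_tree] with at least one internal node.
#' @param p_flip probability of the flip branch.
#' @return A list with `op` (the operation performed, annotated) and
#'   `tree` (the edited tree).
#' @export
random_edit <- function(t, p_flip = 0.3) {
  iv <- internal_nodes(t)
  if (!length(iv)) stop("tree has no internal node")
  do_flip <- function() {
    v <- sample_one(iv)
    op <- op_flip(v, flip_label(t$label[v]))
    list(op = op, tree = apply_op(t, op))
  }
  if (stats::runif(1L) < p_flip) return(do_flip())
  e <- tree_edges(t, internal_only = TRUE)
  contractible <- which(t$label[e[, 1L]] == t$label[e[, 2L]])
  expandable <- iv[vapply(iv, function(v) node_degree(t, v) > 3L, logical(1L))]
  n_pool <- length(contractible) + length(expandable)
  if (n_pool == 0L) return(do_flip())
  pick <- sample.int(n_pool, 1L)
  if (pick <= length(contractible)) {
    row <- e[contractible[pick], ]
    op <- op_contract(row[[1L]], row[[2L]])
  } else {
    v <- expandable[pick - length(contractible)]
    deg <- node_degree(t, v)
    size <- sample_one(2:(deg - 2L))
    op <- op_extend(v, sort(sample(t$adj[[v]], size)))
  }
  list(op = op, tree = apply_op(t, op))
}

#' Apply k random edits
#'
#' Runs [random_edit()] `k` times under a fixed seed and returns both the
#' mutated tree and the edit script, which replays from the input tree to
#' the returned tree.
#'
#' @param t an [lrf_tree].
#' @param k number of edits (`k >= 0`).
#' @param seed optional integer seed for reproducibility.
#' @param p_flip probability of the flip branch per edit.
#' @return A list with `tree` and `script`.
#' @export
#' @examples
#' m <- mutate(parse_newick("((A,B)Spe,(C,D)Dup,E)Spe;"), k = 3, seed = 1)
#' m$script
mutate <- function(t, k, seed = NULL, p_flip = 0.3) {
  stopifnot(k >= 0L)
  if (!is.null(seed)) set.seed(seed)
  ops <- vector("list", k)
  for (i in seq_len(k)) {
    step <- random_edit(t, p_flip = p_flip)
    ops[[i]] <- step$op
    t <- step$tree
  }
  list(tree = t, script = edit_script(ops))
}
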