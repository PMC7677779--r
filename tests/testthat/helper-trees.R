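# shared fixture builders for the suite; everything is generated in code

nwk <- function(text, codec = label_codec("name")) parse_newick(text, codec)

# unrooted quartet ((A,B),(C,D)) with chosen internal labels
quartet <- function(lab1 = "SPE", lab2 = "DUP",
                    leaves = c("A", "B", "C", "D")) {
  labeled_tree(rbind(c("x", leaves[1]), c("x", leaves[2]), c("x", "y"),
                     c("y", leaves[3]), c("y", leaves[4])),
               labels = c(x = lab1, y = lab2))
}

# random rooted tree: either rooted at an internal node (root degree >= 3)
# or at a fresh binary root subdividing an internal edge
random_rooted <- function(n, rate = 0.3) {
  t <- random_labeled_tree(n, rate)
  iv <- internal_nodes(t)
  e <- tree_edges(t, internal_only = TRUE)
  if (stats::runif(1) < 0.5 || nrow(e) == 0L) {
    v <- iv[sample.int(length(iv), 1L)]
    t$root <- v
    t$anchor <- v
  } else {
    j <- sample.int(nrow(e), 1L)
    a <- e[j, 1L]; b <- e[j, 2L]
    r <- length(t$adj) + 1L
    t$adj[[a]][t$adj[[a]] == b] <- r
    t$adj[[b]][t$adj[[b]] == a] <- r
    t$adj[[r]] <- c(a, b)
    t$leaf[r] <- NA_character_
    t$label[r] <- sample(c("SPE", "DUP"), 1L)
    t$root <- r
    t$anchor <- r
  }
  stopifnot(length(validate_tree(t)) == 0L)
  t
}

# relabel a tree so every internal edge is mixed (2-coloring by parity)
make_mixed <- function(t) {
  iv <- internal_nodes(t)
  d <- labeledRF:::bfs_dist(t, iv[1L])
  for (v in iv) t$label[v] <- if (d[v] %% 2L == 0L) "SPE" else "DUP"
  t
}

# Independent minimum-flip search for contracting a tree to a star:
# 0-1 BFS over (contract non-mixed edge: cost 0, flip: cost 1) moves.
# Deliberately ignorant of diameters and midpoints.
brute_min_flips <- function(t) {
  frontier <- list(list(t = t, f = 0L))
  best <- new.env(parent = emptyenv())
  assign(canonical_key(t), 0L, envir = best)
  while (length(frontier)) {
    fs <- vapply(frontier, function(s) s$f, integer(1L))
    i <- which.min(fs)
    s <- frontier[[i]]
    frontier <- frontier[-i]
    if (get(canonical_key(s$t), envir = best) < s$f) next
    if (length(internal_nodes(s$t)) == 1L) return(s$f)
    push <- function(t2, f2) {
      k2 <- canonical_key(t2)
      old <- get0(k2, envir = best)
      if (is.null(old) || old > f2) {
        assign(k2, f2, envir = best)
        frontier[[length(frontier) + 1L]] <<- list(t = t2, f = f2)
      }
    }
    e <- tree_edges(s$t, internal_only = TRUE)
    for (j in seq_len(nrow(e))) {
      if (!is_mixed_edge(s$t, e[j, 1L], e[j, 2L])) {
        push(apply_contraction(s$t, e[j, ]), s$f)
      }
    }
    for (v in internal_nodes(s$t)) push(apply_flip(s$t, v), s$f + 1L)
  }
  stop("search exhausted without reaching a star")
}
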