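#' Worked-example pair: one shared split, radically relabeled
#'
#' A deterministic 21-leaf pair illustrating why an optimal labeled edit
#' path may contract a good edge. `t` is a hub with three alternating
#' SPE/DUP chains of six internal nodes (all 18 internal edges mixed, all
#' bad except the hub-to-P-chain edge); `t_prime` is uniformly SPE with a
#' different arrangement of the same leaves that shares exactly one
#' non-trivial bipartition with `t` (all P leaves versus the rest). On
#' this pair the per-pair heuristic needs 43 operations while the full
#' star path needs only 42, because contracting the shared (good) edge
#' lets the three chains of `t` share flips.
#'
#' @return A list with unrooted trees `t` and `t_prime` on the same
#'   21-name leaf set.
#' @export
#' @examples
#' p <- fig3_pair()
#' rf_distance(p$t, p$t_prime)
fig3_pair <- function() {
  edges <- list()
  labels <- c(h = "SPE")
  for (X in c("p", "q", "r")) {
    chain <- paste0(X, 1:6)
    edges <- c(edges, list(c("h", chain[1L])))
    for (i in 1:5) edges <- c(edges, list(c(chain[i], chain[i + 1L])))
    labels[chain] <- rep(c("DUP", "SPE"), 3L)  # odd positions DUP
    up <- toupper(X)
    for (i in 1:5) edges <- c(edges, list(c(chain[i], paste0(up, i))))
    edges <- c(edges, list(c(chain[6L], paste0(up, "6a")),
                           c(chain[6L], paste0(up, "6b"))))
  }
  t <- labeled_tree(do.call(rbind, edges), labels)

  pend_m <- c("P2", "P3", "P4", "P5", "P6a")
  pend_n <- c("R1", "Q2", "R2", "Q3", "R3", "Q4", "R4", "Q5", "R5",
              "Q6a", "R6a")
  edges2 <- list(c("hp", "Q1"), c("hp", "m1"), c("hp", "n1"))
  for (i in 1:5) edges2 <- c(edges2, list(c(paste0("m", i), paste0("m", i + 1L))))
  for (i in 1:11) edges2 <- c(edges2, list(c(paste0("n", i), paste0("n", i + 1L))))
  for (i in 1:5) edges2 <- c(edges2, list(c(paste0("m", i), pend_m[i])))
  edges2 <- c(edges2, list(c("m6", "P6b"), c("m6", "P1")))
  for (i in 1:11) edges2 <- c(edges2, list(c(paste0("n", i), pend_n[i])))
  edges2 <- c(edges2, list(c("n12", "Q6b"), c("n12", "R6b")))
  labels2 <- stats::setNames(rep("SPE", 19L),
                             c("hp", paste0("m", 1:6), paste0("n", 1:12)))
  t_prime <- labeled_tree(do.call(rbind, edges2), labels2)

  stopifnot(setequal(leaf_names(t), leaf_names(t_prime)),
            length(intersect(bipartition_set(t), bipartition_set(t_prime))) == 1L)
  list(t = t, t_prime = t_prime)
}

#' Random event-labeled tree
#'
#' Grows a uniform random binary topology by sequential leaf attachment
#' (each new leaf subdivides a uniformly chosen edge), then contracts
#' each internal edge independently with probability
#' `multifurcation_rate`, then labels each internal node SPE or DUP
#' independently with equal probability. A synthetic stand-in for a
#' reconciled gene tree.
#'
#' @param n_leaves number of leaves (at least 3).
#' @param multifurcation_rate per-internal-edge contraction probability
#'   in `[0, 1]`; 0 gives a binary tree, 1 a star.
#' @param seed optional integer seed.
#' @param leaf_names leaf names, default `L1..Ln`.
#' @return An unrooted [lrf_tree].
#' @export
#' @examples
#' random_labeled_tree(8, multifurcation_rate = 0.3, seed = 42)
random_labeled_tree <- function(n_leaves, multifurcation_rate = 0,
                                seed = NULL,
                                leaf_names = paste0("L", seq_len(n_leaves))) {
  if (n_leaves < 3L) stop("need at least 3 leaves")
  stopifnot(length(leaf_names) == n_leaves, !anyDuplicated(leaf_names))
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(n_leaves)
  nxt <- N + 1L                       # first internal id
  ed <- rbind(c(1L, nxt), c(2L, nxt), c(3L, nxt))
  for (i in seq_len(N - 3L) + 3L) {
    j <- sample.int(nrow(ed), 1L)
    w <- nxt <- nxt + 1L
    old <- ed[j, ]
    ed[j, ] <- c(old[1L], w)
    ed <- rbind(ed, c(w, old[2L]), c(w, i))
  }
  # optional multifurcations: contract internal edges independently
  if (multifurcation_rate > 0) {
    merged_into <- seq_len(nxt)
    find <- function(x) {
      while (merged_into[x] != x) x <- merged_into[x]
      x
    }
    internal <- ed[, 1L] > N & ed[, 2L] > N
    drop <- internal & stats::runif(nrow(ed)) < multifurcation_rate
    for (j in which(drop)) {
      a <- find(ed[j, 1L]); b <- find(ed[j, 2L])
      if (a != b) merged_into[max(a, b)] <- min(a, b)
    }
    ed <- ed[!drop, , drop = FALSE]
    ed[] <- vapply(ed, find, integer(1L))
  }
  adj <- vector("list", nxt)
  for (j in seq_len(nrow(ed))) {
    a <- ed[j, 1L]; b <- ed[j, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  leaf <- rep(NA_character_, nxt)
  leaf[seq_len(N)] <- leaf_names
  lab <- rep(NA_character_, nxt)
  alive_int <- which(!vapply(adj, is.null, logical(1L)))
  alive_int <- alive_int[alive_int > N]
  lab[alive_int] <- sample(LRF_LABELS, length(alive_int), replace = TRUE)
  t <- new_lrf_tree(adj, leaf, lab, anchor = alive_int[1L])
  assert_valid(t)
  t
}

#' Random-edit benchmark of the labeled distance
#'
#' For each replicate, applies `k_max` random edits to the base tree one
#' at a time and, after each edit, records the classical RF distance and
#' the labeled estimate between the base tree and the mutated tree. The
#' labeled estimate accounts for label changes and therefore tracks the
#' true number of edits more closely than classical RF, which is blind
#' to flips.
#'
#' @param base an unrooted [lrf_tree].
#' @param k_max maximum number of edits per replicate (at least 1).
#' @param replicates number of independent replicates (at least 1).
#' @param seed optional integer seed.
#' @param p_flip flip probability per edit (see [random_edit()]).
#' @return A tibble with columns `replicate`, `n_edits`, `rf_classical`,
#'   `labeled_estimate`, one row per (replicate, 0..k_max).
#' @export
#' @examples
#' base <- random_labeled_tree(10, 0.3, seed = 7)
#' evaluation_run(base, k_max = 3, replicates = 2, seed = 7)
evaluation_run <- function(base, k_max, replicates, seed = NULL,
                           p_flip = 0.3) {
  stopifnot(k_max >= 1L, replicates >= 1L)
  if (is_rooted(base)) stop("base tree must be unrooted")
  if (!is.null(seed)) set.seed(seed)
  n_row <- replicates * (k_max + 1L)
  rep_col <- integer(n_row); k_col <- integer(n_row)
  rf_col <- integer(n_row); est_col <- integer(n_row)
  r <- 0L
  for (i in seq_len(replicates)) {
    t <- base
    for (k in 0:k_max) {
      if (k > 0L) t <- random_edit(t, p_flip = p_flip)$tree
      r <- r + 1L
      rep_col[r] <- i
      k_col[r] <- k
      rf_col[r] <- if (k == 0L) 0L else rf_distance(base, t)
      est_col[r] <- if (k == 0L) 0L else labeled_rf_estimate(base, t)$total
    }
  }
  tibble::tibble(replicate = rep_col, n_edits = k_col,
                 rf_classical = rf_col, labeled_estimate = est_col)
}
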