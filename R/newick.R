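#' Label codecs for Newick input and output
#'
#' Internal-node event labels can be written in two common dialects:
#' as internal node name strings (`"((A,B)Spe,(C,D)Dup)Spe;"`) or as NHX
#' comment blocks carrying the duplication key `D`
#' (`"((A,B)[&&NHX:D=N],(C,D)[&&NHX:D=Y])[&&NHX:D=N];"`), the convention
#' used by TreeBest/Ensembl gene trees. A codec bundles the decoding
#' synonyms and the strings used on output.
#'
#' @param type `"name"` or `"nhx"`.
#' @param spe,dup case-insensitive name strings accepted for each label by
#'   the name codec.
#' @param spe_out,dup_out strings emitted by [write_newick()] under the
#'   name codec.
#' @return A codec object for [parse_newick()] / [write_newick()].
#' @export
#' @examples
#' parse_newick("((A,B)Spe,(C,D)Dup)Spe;", label_codec("name"))
label_codec <- function(type = c("name", "nhx"),
                        spe = c("spe", "speciation"),
                        dup = c("dup", "duplication"),
                        spe_out = "Spe", dup_out = "Dup") {
  type <- match.arg(type)
  structure(list(type = type, spe = tolower(spe), dup = tolower(dup),
                 spe_out = spe_out, dup_out = dup_out),
            class = "lrf_codec")
}

decode_label <- function(codec, name, nhx, pos) {
  if (codec$type == "nhx") {
    m <- regmatches(nhx, regexpr("(?<=[:&])D=([A-Za-z])", nhx, perl = TRUE))
    if (is.na(nhx) || !length(m)) {
      stop(sprintf("missing internal label: no NHX D tag near position %d", pos))
    }
    d <- toupper(sub("^D=", "", m[[1L]]))
    if (d == "Y") return("DUP")
    if (d == "N") return("SPE")
    stop(sprintf("ambiguous internal label: NHX D=%s near position %d", d, pos))
  }
  nm <- tolower(trimws(name))
  if (is.na(name) || !nzchar(nm)) {
    stop(sprintf("missing internal label near position %d", pos))
  }
  if (nm %in% codec$spe) return("SPE")
  if (nm %in% codec$dup) return("DUP")
  stop(sprintf("ambiguous internal label '%s' near position %d", name, pos))
}

encode_label <- function(codec, label) {
  if (codec$type == "nhx") {
    if (label == "DUP") "[&&NHX:D=Y]" else "[&&NHX:D=N]"
  } else {
    if (label == "DUP") codec$dup_out else codec$spe_out
  }
}

#' Read an event-labeled tree from a Newick string
#'
#' Parses Newick with internal-node labels encoded per `codec`. A top-level
#' node of degree 2 yields a rooted tree (whose root must itself carry a
#' label); a top-level node of degree 3 or more yields an unrooted tree.
#' Branch lengths are parsed and discarded. Non-root internal nodes of
#' degree 2 are rejected unless `suppress_unary = TRUE`, in which case they
#' are spliced out and their label discarded.
#'
#' @param text a Newick string (one tree, terminated by `;`).
#' @param codec a [label_codec()].
#' @param suppress_unary splice out degree-2 non-root internal nodes
#'   instead of rejecting them.
#' @return An [lrf_tree].
#' @export
#' @examples
#' parse_newick("((A,B)Spe,C,D)Dup;")
parse_newick <- function(text, codec = label_codec("name"),
                         suppress_unary = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n_char <- length(chars)
  i <- 1L

  err <- function(msg) stop(sprintf("Newick syntax error at position %d: %s", i, msg))
  peek <- function() if (i <= n_char) chars[i] else ""
  skip_ws <- function() while (i <= n_char && grepl("^\\s$", chars[i])) i <<- i + 1L

  read_name <- function() {
    skip_ws()
    start <- i
    while (i <= n_char && !chars[i] %in% c("(", ")", ",", ":", ";", "[", "]")) {
      i <<- i + 1L
    }
    trimws(paste(chars[start:(i - 1L)][seq_len(i - start)], collapse = ""))
  }

  read_comment <- function() {
    # consumes "[...]"; returns contents
    start <- i
    i <<- i + 1L
    while (i <= n_char && chars[i] != "]") i <<- i + 1L
    if (i > n_char) { i <<- start; err("unterminated comment") }
    out <- paste(chars[(start + 1L):(i - 1L)][seq_len(i - start - 1L)], collapse = "")
    i <<- i + 1L
    out
  }

  nodes <- list()  # each: list(children = int vec, name, nhx, pos)
  add_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }

  parse_subtree <- function() {
    skip_ws()
    if (peek() == "(") {
      pos0 <- i
      i <<- i + 1L
      kids <- parse_subtree()
      skip_ws()
      while (peek() == ",") {
        i <<- i + 1L
        kids <- c(kids, parse_subtree())
        skip_ws()
      }
      if (peek() != ")") err("expected ',' or ')'")
      i <<- i + 1L
      name <- read_name()
      nhx <- read_trailers()
      add_node(list(children = kids, name = name, nhx = nhx, pos = pos0))
    } else {
      pos0 <- i
      name <- read_name()
      if (!nzchar(name)) err("expected a leaf name or '('")
      nhx <- read_trailers()
      add_node(list(children = integer(0), name = name, nhx = nhx, pos = pos0))
    }
  }

  read_trailers <- function() {
    nhx <- NA_character_
    repeat {
      skip_ws()
      if (peek() == ":") {
        i <<- i + 1L
        skip_ws()
        start <- i
        while (i <= n_char && grepl("^[-+0-9.eE]$", chars[i])) i <<- i + 1L
        if (i == start) err("expected a branch length after ':'")
      } else if (peek() == "[") {
        cm <- read_comment()
        if (grepl("&&NHX", cm, fixed = TRUE)) nhx <- cm
      } else break
    }
    nhx
  }

  skip_ws()
  top <- parse_subtree()
  skip_ws()
  if (peek() != ";") err("expected ';' at end of tree")
  i <- i + 1L
  skip_ws()
  if (i <= n_char) err("trailing characters after ';'")
  if (length(nodes[[top]]$children) == 0L) {
    i <- nodes[[top]]$pos
    err("tree must have at least one internal node")
  }

  # degree-2 suppression / rejection (non-top nodes with a single child)
  repeat {
    unary <- which(vapply(nodes, function(nd) length(nd$children) == 1L,
                          logical(1L)))
    unary <- setdiff(unary, top)
    if (length(nodes[[top]]$children) == 1L) {
      i <- nodes[[top]]$pos
      err("top-level node has a single child")
    }
    if (!length(unary)) break
    if (!suppress_unary) {
      stop(sprintf(
        "internal node of degree 2 below the root near position %d (see suppress_unary)",
        nodes[[unary[1L]]]$pos))
    }
    u <- unary[1L]
    child <- nodes[[u]]$children
    for (k in seq_along(nodes)) {
      hit <- nodes[[k]]$children == u
      if (any(hit)) nodes[[k]]$children[hit] <- child
    }
    nodes[[u]]$children <- integer(0)
    nodes[[u]]$dead <- TRUE
  }

  keep <- which(!vapply(nodes, function(nd) isTRUE(nd$dead), logical(1L)))
  remap <- integer(length(nodes))
  remap[keep] <- seq_along(keep)

  n <- length(keep)
  adj <- vector("list", n)
  leaf <- rep(NA_character_, n)
  lab <- rep(NA_character_, n)
  for (k in keep) {
    nd <- nodes[[k]]
    v <- remap[k]
    if (length(nd$children)) {
      lab[v] <- decode_label(codec, nd$name, nd$nhx, nd$pos)
      for (c0 in nd$children) {
        u <- remap[c0]
        adj[[v]] <- c(adj[[v]], u)
        adj[[u]] <- c(adj[[u]], v)
      }
    } else {
      leaf[v] <- nd$name
    }
  }

  topv <- remap[top]
  rooted <- length(nodes[[top]]$children) == 2L
  t <- new_lrf_tree(adj, leaf, lab,
                    root = if (rooted) topv else NA_integer_,
                    anchor = topv)
  viol <- validate_tree(t)
  if (length(viol)) stop("invalid tree: ", paste(viol, collapse = "; "))
  t
}

# smallest leaf name in the subtree at v seen from parent; anchors the
# canonical child order of write_newick()
min_leaf_under <- function(t, v, parent) {
  if (!is.na(t$leaf[v])) return(t$leaf[v])
  kids <- setdiff(t$adj[[v]], parent)
  min(vapply(kids, function(u) min_leaf_under(t, u, v), character(1L)))
}

serialization_anchor <- function(t) {
  a <- t$anchor
  if (!is.na(a) && !is.null(t$adj[[a]]) && is.na(t$leaf[a])) return(a)
  lv <- tree_leaves(t)
  t$adj[[lv[order(t$leaf[lv])][1L]]][1L]
}

#' Write an event-labeled tree as Newick
#'
#' Children are emitted in canonical order (by the lexicographically
#' smallest leaf name under each subtree), so isomorphic trees serialized
#' from the same top node produce identical strings, and
#' `parse_newick(write_newick(t))` is isomorphic to `t`.
#'
#' @param t an [lrf_tree].
#' @param codec a [label_codec()].
#' @return A Newick string.
#' @export
#' @examples
#' write_newick(parse_newick("((B,A)Spe,C,D)Dup;"))
write_newick <- function(t, codec = label_codec("name")) {
  start <- if (is_rooted(t)) t$root else serialization_anchor(t)
  ser <- function(v, parent) {
    if (!is.na(t$leaf[v])) return(t$leaf[v])
    kids <- setdiff(t$adj[[v]], parent)
    keys <- vapply(kids, function(u) min_leaf_under(t, u, v), character(1L))
    parts <- vapply(kids[order(keys)], function(u) ser(u, v), character(1L))
    paste0("(", paste(parts, collapse = ","), ")", encode_label(codec, t$label[v]))
  }
  paste0(ser(start, 0L), ";")
}
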