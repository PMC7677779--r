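#' Convert to an ape phylo object
#'
#' Bridges to the ape ecosystem through Newick serialization; event
#' labels travel as internal node labels (`"Spe"` / `"Dup"`).
#'
#' @param t an [lrf_tree].
#' @return An `ape::phylo` object.
#' @export
as_phylo <- function(t) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("as_phylo() needs the ape package")
  }
  ape::read.tree(text = write_newick(t))
}

#' @export
plot.lrf_tree <- function(x, ...) {
  ph <- as_phylo(x)
  ape::plot.phylo(ph, show.node.label = TRUE, ...)
  invisible(x)
}
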