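# Newick tree input/output, thin wrappers over ape with strict errors.

#' Read a newick tree
#' @param path file containing one newick tree.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  txt <- paste(readLines(path), collapse = "")
  parse_newick(txt)
}

#' Parse a newick string into a phylo object
#' @param text newick string ending in `;`.
#' @return an [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stop2("newick syntax error: unbalanced parentheses")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop2("newick syntax error")
  tr
}

#' Write a tree in newick format
#' @param tree an [ape::phylo] object.
#' @param path output file.
#' @param digits branch-length precision.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, digits = 10L) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
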