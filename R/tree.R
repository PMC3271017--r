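#' Parse and validate a rooted Newick tree
#'
#' Reads a Newick string (or file, via \code{read_phylo_tree}) into an
#' \pkg{ape} \code{phylo} object and validates it for simulation: every edge
#' must carry a finite non-negative branch length, leaf labels must be unique
#' and non-empty, and the root must be unambiguous. Unnamed internal nodes
#' are labeled deterministically (\code{n1}, \code{n2}, ... in ape node
#' order). Polytomies, e.g. from consensus trees, are kept as polytomies:
#' the simulator treats the children of a polytomous node as independent
#' lineages, which is exactly the branch-independence of the model.
#'
#' @param text A Newick string.
#' @return A validated \code{phylo} object.
#' @export
#' @examples
#' tr <- parse_newick("(A:0.1,(B:0.2,C:0.3):0.05);")
#' tr$tip.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  neg <- regexpr(":\\s*-", text)
  if (neg > 0)
    stop(sprintf("negative branch length at character offset %d of Newick input", as.integer(neg)),
         call. = FALSE)
  depth <- cumsum((strsplit(text, "", fixed = TRUE)[[1]] == "(") -
                  (strsplit(text, "", fixed = TRUE)[[1]] == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    off <- if (any(depth < 0)) which(depth < 0)[1L] else length(depth)
    stop(sprintf("unbalanced parentheses at character offset %d of Newick input", off),
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick input: ", conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick input", call. = FALSE)
  validate_phylo(tree)
}

#' @rdname parse_newick
#' @param file Path to a Newick file; its first tree is used.
#' @export
read_phylo_tree <- function(file) {
  parse_newick(trimws(paste(readLines(file, warn = FALSE), collapse = "")))
}

#' @rdname parse_newick
#' @param tree A \code{phylo} object to validate in place.
#' @export
validate_phylo <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; the simulator needs evolutionary times on every edge", call. = FALSE)
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree has missing or non-finite branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label", call. = FALSE)
  if (anyDuplicated(labs))
    stop("duplicate leaf label: ", labs[anyDuplicated(labs)], call. = FALSE)
  n_node <- tree$Nnode
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) || anyDuplicated(tree$node.label)) {
    tree$node.label <- paste0("n", seq_len(n_node))
  }
  # exactly one root: one node that never appears as a child
  ntip <- length(labs)
  children <- tree$edge[, 2]
  roots <- setdiff(seq_len(ntip + n_node), children)
  if (length(roots) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  tree
}
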