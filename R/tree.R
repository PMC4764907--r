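#' Read a rooted phylogenetic tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' diversity computations rely on: a single rooted tree, unique leaf
#' labels, and non-negative branch lengths. Missing branch lengths are set
#' to zero with a warning.
#'
#' @param path Path to a Newick file containing one tree.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("unparseable Newick in '", path, "': ", conditionMessage(e),
      call. = FALSE
    )
  })
  if (is.null(tr)) {
    stop("unparseable Newick in '", path, "'", call. = FALSE)
  }
  if (inherits(tr, "multiPhylo")) {
    stop("expected a single tree, found ", length(tr), call. = FALSE)
  }
  validate_tree(tr)
}

validate_tree <- function(tr) {
  stopifnot(inherits(tr, "phylo"))
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
      paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths treated as 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  if (!ape::is.rooted(tr)) {
    stop("tree must be rooted", call. = FALSE)
  }
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Total branch length of a tree.
total_branch_length <- function(tree) {
  sum(tree$edge.length)
}

# Logical tips x edges incidence: does edge e lie on the path from the root
# to tip t (equivalently, is t a descendant of e's child node)? Computed by
# postorder accumulation; used to vectorize Faith's PD over many samples.
edge_tip_matrix <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  edge <- tree$edge
  # tip membership per node, built in postorder (children before parents)
  po <- ape::reorder.phylo(tree, "postorder")
  member <- matrix(FALSE, nrow = n_tip, ncol = n_node)
  member[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (i in seq_len(nrow(po$edge))) {
    parent <- po$edge[i, 1]
    child <- po$edge[i, 2]
    member[, parent] <- member[, parent] | member[, child]
  }
  out <- member[, edge[, 2], drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}
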