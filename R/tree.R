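## Labelled phylogenies: an ape "phylo" tree plus a test/reference label per
## edge. Test (foreground) branches are the ones on which every dN/dS
## category omega is raised to the selection-intensity exponent k.

#' Construct a labelled tree
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param edge_label Character vector, one entry per row of `tree$edge`,
#'   each `"test"` or `"reference"`. Defaults to all-reference.
#' @return An object of class `labelled_tree`.
#' @export
labelled_tree <- function(tree, edge_label = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  ne <- nrow(tree$edge)
  if (is.null(edge_label)) edge_label <- rep("reference", ne)
  if (length(edge_label) != ne ||
      !all(edge_label %in% c("test", "reference"))) {
    stop("edge_label must assign 'test' or 'reference' to every edge")
  }
  structure(list(tree = tree, edge_label = edge_label),
            class = "labelled_tree")
}

#' @export
print.labelled_tree <- function(x, ...) {
  cat(sprintf("labelled tree: %d tips, %d edges (%d test, %d reference)\n",
              length(x$tree$tip.label), nrow(x$tree$edge),
              sum(x$edge_label == "test"),
              sum(x$edge_label == "reference")))
  invisible(x)
}

#' Number of test branches
#' @param ltree A `labelled_tree`.
#' @return Integer.
#' @export
n_test_branches <- function(ltree) sum(ltree$edge_label == "test")

#' Label foreground branches of a tree
#'
#' Marks the branches on which the selection-intensity test is performed.
#' Foreground taxa can be given as a single character vector (one clade) or
#' as a list of vectors (one per foreground lineage, e.g. one per genus).
#'
#' @param tree An [ape::phylo] tree or a `labelled_tree` (labels are
#'   recomputed).
#' @param foreground Character vector of tip labels, or list of such vectors.
#' @param mode `"clade"` (default): every branch inside the smallest subtree
#'   spanning each foreground group, including its stem branch; `"tips"`:
#'   terminal branches of the foreground taxa only.
#' @return A `labelled_tree`.
#' @export
label_foreground <- function(tree, foreground, mode = c("clade", "tips")) {
  mode <- match.arg(mode)
  if (inherits(tree, "labelled_tree")) tree <- tree$tree
  if (!is.list(foreground)) foreground <- list(foreground)
  tips <- tree$tip.label
  unknown <- setdiff(unlist(foreground), tips)
  if (length(unknown)) {
    stop("unknown foreground taxa: ", paste(unknown, collapse = ", "))
  }
  ne <- nrow(tree$edge)
  lab <- rep("reference", ne)
  for (grp in foreground) {
    idx <- match(grp, tips)
    if (mode == "tips" || length(idx) == 1L) {
      lab[tree$edge[, 2] %in% idx] <- "test"
    } else {
      mrca <- ape::getMRCA(tree, idx)
      desc <- subtree_nodes(tree, mrca)
      ## subtree branches: child inside the clade; stem: child == mrca
      lab[tree$edge[, 2] %in% c(desc, mrca)] <- "test"
    }
  }
  labelled_tree(tree, lab)
}

## all node numbers strictly below `node` (tips and internals)
subtree_nodes <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack)) {
    nd <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, nd)
    stack <- c(stack, tree$edge[tree$edge[, 1] == nd, 2])
  }
  out
}

#' Read a newick tree with optional foreground tags
#'
#' Branch labels may be carried in the newick string itself as a `{test}`
#' suffix on tip or internal node labels (the branch leading to that node is
#' marked as foreground), or applied afterwards with [label_foreground()].
#'
#' @param path Path to a single-tree newick file.
#' @return A `labelled_tree`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(txt)) stop("empty newick file: ", path)
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("unbalanced parentheses in %s (%d '(' vs %d ')')",
                 path, n_open, n_close))
  }
  bad <- regmatches(txt, regexpr("\\{(?!test\\})[^}]*\\}", txt, perl = TRUE))
  if (length(bad)) {
    stop("unknown branch label token '", bad[[1]], "' (only {test} is known)")
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tagged <- function(labels) {
    if (is.null(labels)) return(logical(0))
    grepl("\\{test\\}$", labels)
  }
  tip_tag <- tagged(tree$tip.label)
  node_tag <- tagged(tree$node.label)
  tree$tip.label <- sub("\\{test\\}$", "", tree$tip.label)
  if (!is.null(tree$node.label)) {
    tree$node.label <- sub("\\{test\\}$", "", tree$node.label)
  }
  ntip <- length(tree$tip.label)
  tag_nodes <- c(which(tip_tag),
                 if (length(node_tag)) ntip + which(node_tag) else integer(0))
  lab <- ifelse(tree$edge[, 2] %in% tag_nodes, "test", "reference")
  labelled_tree(tree, lab)
}

#' Write a labelled tree to newick
#'
#' Foreground branches are encoded as `{test}` suffixes on the labels of
#' their child nodes, so [read_newick()] round-trips topology, branch
#' lengths (including zero lengths) and labels.
#'
#' @param ltree A `labelled_tree` (or plain `phylo`, written unlabelled).
#' @param path Output file path.
#' @return Invisibly, the newick string.
#' @export
write_newick <- function(ltree, path) {
  if (inherits(ltree, "phylo")) ltree <- labelled_tree(ltree)
  tree <- ltree$tree
  ntip <- length(tree$tip.label)
  test_children <- tree$edge[ltree$edge_label == "test", 2]
  tip_hit <- test_children[test_children <= ntip]
  tree$tip.label[tip_hit] <- paste0(tree$tip.label[tip_hit], "{test}")
  node_hit <- test_children[test_children > ntip] - ntip
  if (length(node_hit)) {
    if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
    tree$node.label[node_hit] <- paste0(tree$node.label[node_hit], "{test}")
  }
  str <- ape::write.tree(tree)
  writeLines(str, path)
  invisible(str)
}
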