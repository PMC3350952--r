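#' Trees with branch-type labels
#'
#' A \code{labeled_tree} couples an \code{ape} \code{phylo} object with a
#' branch-type label for every edge. Branch types partition the tree into
#' "background" branches and one or more named foreground sets (e.g. the stem
#' branches of the Tekay, Reina and Galadriel clades, labeled T, R, G, or
#' unions such as TR and GTR); the codon site-class models let the selection
#' intensity differ between these types.
#'
#' @param phylo An \code{ape::phylo} tree. Edge lengths are optional; missing
#'   lengths are set to \code{default_length} (with a message).
#' @param edge_types Character vector with one branch type per row of
#'   \code{phylo$edge}, or \code{NULL} for all-background.
#' @param default_length Branch length used when the tree carries none.
#' @return Object of class \code{labeled_tree}: list with elements
#'   \code{phylo} and \code{edge_types}.
#' @export
labeled_tree <- function(phylo, edge_types = NULL, default_length = 0.1) {
  if (!inherits(phylo, "phylo")) stop("'phylo' must be an ape phylo tree")
  if (anyDuplicated(phylo$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(phylo$tip.label[duplicated(phylo$tip.label)]), collapse = ", "))
  }
  nedge <- nrow(phylo$edge)
  if (is.null(phylo$edge.length)) {
    message("tree has no branch lengths; defaulting all to ", default_length)
    phylo$edge.length <- rep(default_length, nedge)
  }
  if (any(phylo$edge.length < 0)) stop("negative branch length in tree")
  if (is.null(edge_types)) edge_types <- rep("background", nedge)
  if (length(edge_types) != nedge) {
    stop("edge_types must have one entry per edge")
  }
  structure(list(phylo = phylo, edge_types = edge_types), class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("Labeled tree:", length(x$phylo$tip.label), "tips,",
      nrow(x$phylo$edge), "edges\n")
  tab <- table(x$edge_types)
  cat("Branch types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a newick tree with branch-type labels
#'
#' Standard newick, extended with a \code{#TYPE} suffix on a tip or internal
#' node name: the branch leading to that node receives branch type
#' \code{TYPE} (any alphanumeric name); all other branches are
#' \code{"background"}. Branch lengths are optional and default to 0.1.
#'
#' @param path Path to a newick file.
#' @param default_length Branch length substituted when absent.
#' @return A \code{labeled_tree}.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((a:1,b:1)#TR:0.5,c:1.5);", tf)
#' tr <- read_newick(tf)
#' table(tr$edge_types)
#' @export
read_newick <- function(path, default_length = 0.1) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close) stop("unbalanced parentheses in newick file ", path)
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse newick in ", path)
  labeled_tree_from_phylo_labels(phy, default_length = default_length)
}

# Pull "#TYPE" suffixes out of tip/node labels into edge types.
labeled_tree_from_phylo_labels <- function(phy, default_length = 0.1) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  node_names <- c(phy$tip.label,
                  if (is.null(phy$node.label)) rep("", nnode) else phy$node.label)
  types <- rep("background", ntip + nnode)
  has <- grepl("#", node_names, fixed = TRUE)
  types[has] <- sub("^.*#", "", node_names[has])
  if (any(has & !grepl("^[A-Za-z0-9_]+$", types) & seq_along(types) > 0)) {
    bad <- which(has & !grepl("^[A-Za-z0-9_]+$", types))[1L]
    stop("invalid branch-type label '", types[bad], "'")
  }
  node_names[has] <- sub("#.*$", "", node_names[has])
  phy$tip.label <- node_names[seq_len(ntip)]
  if (!is.null(phy$node.label)) phy$node.label <- node_names[ntip + seq_len(nnode)]
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  edge_types <- types[phy$edge[, 2L]]
  labeled_tree(phy, edge_types, default_length = default_length)
}

#' Write a labeled tree to newick
#'
#' Branch types other than \code{"background"} are emitted as \code{#TYPE}
#' suffixes on the corresponding child node's name; lengths are written with
#' 10 significant digits so read/write round-trips are lossless at that
#' precision.
#'
#' @param tree A \code{labeled_tree}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "labeled_tree"))
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labels <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep("", nnode) else phy$node.label)
  fg <- which(tree$edge_types != "background")
  for (e in fg) {
    child <- phy$edge[e, 2L]
    labels[child] <- paste0(labels[child], "#", tree$edge_types[e])
  }
  phy$tip.label <- labels[seq_len(ntip)]
  phy$node.label <- labels[ntip + seq_len(nnode)]
  ape::write.tree(phy, file = path, digits = 10)
  invisible(path)
}
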