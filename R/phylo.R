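#' Pairwise distances from an alignment
#'
#' Distances over shared ungapped columns: \code{"p"} is the raw mismatch
#' fraction, \code{"poisson"} the Poisson correction \eqn{-\ln(1-p)} for
#' proteins, and \code{"jc"} the Jukes-Cantor correction
#' \eqn{-\frac{3}{4}\ln(1-4p/3)} for DNA. Saturated pairs (p at or beyond
#' the model's domain) raise an error naming the pair rather than returning
#' infinite distances.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (gaps \code{"-"}), or a character matrix (taxa x columns).
#' @param model One of \code{"p"}, \code{"poisson"}, \code{"jc"}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment, model = c("p", "poisson", "jc")) {
  model <- match.arg(model)
  m <- as_char_matrix(alignment)
  n <- nrow(m)
  taxa <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  gap <- m == "-" | m == "."
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !gap[i, ] & !gap[j, ]
      if (!any(shared)) stop("no shared ungapped columns for pair ",
                             taxa[i], "/", taxa[j])
      p <- mean(m[i, shared] != m[j, shared])
      v <- switch(model,
        p = p,
        poisson = {
          if (p >= 1) stop("saturated pair ", taxa[i], "/", taxa[j],
                           " (p = ", p, ") under poisson model")
          -log(1 - p)
        },
        jc = {
          if (p >= 0.75) stop("saturated pair ", taxa[i], "/", taxa[j],
                              " (p = ", p, ") under jc model")
          -0.75 * log(1 - 4 * p / 3)
        })
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

as_char_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment))) stop("alignment matrix must have rownames")
    return(alignment)
  }
  if (is.null(names(alignment))) stop("alignment must be named")
  if (length(unique(nchar(alignment))) != 1L) {
    stop("aligned sequences differ in length")
  }
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Neighbor-joining tree
#'
#' Classical neighbor joining (Q-criterion agglomeration with the standard
#' branch-length formulas). Ties in the Q criterion are broken
#' deterministically by the lexicographically smallest pair of node keys
#' (each node keyed by its smallest descendant leaf name). Negative branch
#' lengths are clamped to zero with the deficit moved to the sister branch,
#' which preserves the joined pair's path length and never changes topology.
#' On additive distance matrices the input tree is recovered exactly.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return A \code{labeled_tree} (unrooted; trifurcating root node).
#' @export
nj_tree <- function(dm) {
  if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric")
  if (any(!is.finite(dm))) stop("distance matrix must be finite")
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  taxa <- rownames(dm)
  ntip <- n
  # node bookkeeping: tips 1..ntip, internals appended
  nodes <- seq_len(ntip)
  keys <- taxa
  next_node <- ntip + 1L
  edges <- NULL         # rows: parent, child, length (parent = joined node)
  D <- dm
  active <- seq_len(n)  # indices into current D rows
  node_of <- nodes
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    kp <- apply(cand, 1L, function(ij) {
      k <- sort(c(keys[node_of[active[ij[1]]]], keys[node_of[active[ij[2]]]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(kp)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- next_node; next_node <- next_node + 1L
    ni <- node_of[active[i]]; nj <- node_of[active[j]]
    keys[u] <- min(keys[ni], keys[nj])
    edges <- rbind(edges, c(u, ni, li), c(u, nj, lj))
    # distances from the new node
    others <- active[-c(i, j)]
    du <- (D[active[i], others] + D[active[j], others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    newrow <- nrow(D)
    D[newrow, others] <- du; D[others, newrow] <- du
    node_of[newrow] <- u
    active <- c(others, newrow)
  }
  # final three nodes joined in a trifurcation
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  root <- next_node
  edges <- rbind(edges,
                 c(root, node_of[a], max(la, 0)),
                 c(root, node_of[b], max(lb, 0)),
                 c(root, node_of[c3], max(lc, 0)))
  build_phylo_from_edges(edges, taxa, root)
}

# Assemble an ape phylo from (parent, child, length) rows with our internal
# ids, renumbering internals so the root is ntip+1 as ape requires.
build_phylo_from_edges <- function(edges, taxa, root) {
  ntip <- length(taxa)
  ids <- unique(as.vector(edges[, 1:2]))
  internals <- sort(setdiff(ids, seq_len(ntip)))
  # breadth-first renumbering from the root
  ord <- root
  queue <- root
  children_of <- split(edges[, 2], edges[, 1])
  while (length(queue)) {
    nd <- queue[1L]; queue <- queue[-1L]
    kids <- children_of[[as.character(nd)]]
    kids <- kids[kids > ntip]
    ord <- c(ord, kids); queue <- c(queue, kids)
  }
  newid <- integer(max(ids))
  newid[seq_len(ntip)] <- seq_len(ntip)
  newid[ord] <- ntip + seq_along(ord)
  phy <- list(edge = cbind(newid[edges[, 1]], newid[edges[, 2]]),
              edge.length = edges[, 3], tip.label = taxa,
              Nnode = length(internals))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  labeled_tree(phy)
}

#' Bootstrap support for a neighbor-joining (or other) tree
#'
#' Nonparametric bootstrap: alignment columns are resampled with
#' replacement, the tree builder is rerun on each replicate, and the support
#' of each internal branch of the point-estimate tree is the percentage of
#' replicate trees containing the same bipartition. Supports are written
#' into the returned tree's \code{node.label} (and field \code{support}).
#'
#' @param alignment Named character vector or matrix of aligned sequences.
#' @param builder Function alignment -> \code{labeled_tree}; defaults to
#'   neighbor joining on \code{model} distances.
#' @param replicates Number of bootstrap replicates (1000 by default).
#' @param seed Integer seed for reproducible resampling.
#' @param model Distance model for the default builder.
#' @return The point-estimate \code{labeled_tree} with a \code{support}
#'   vector (percent, one entry per internal node; NA for the root).
#' @export
bootstrap_support <- function(alignment, builder = NULL, replicates = 1000,
                              seed = NULL, model = "p") {
  m <- as_char_matrix(alignment)
  if (is.null(builder)) {
    builder <- function(a) nj_tree(distance_matrix(a, model))
  }
  point <- builder(m)
  with_local_seed(seed, {
    reps <- lapply(seq_len(replicates), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      builder(m[, cols, drop = FALSE])$phylo
    })
    class(reps) <- "multiPhylo"
    counts <- ape::prop.clades(point$phylo, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / replicates
    point$support <- support
    point$phylo$node.label <- format(round(support, 1), trim = TRUE)
    point
  })
}

#' Label clade stem branches with branch types
#'
#' Assigns a branch type to the stem branch of each named clade (the branch
#' leading to the most recent common ancestor of the clade's leaves), for use
#' as foreground in the branch-site and clade models. Each leaf set must be
#' monophyletic in the tree; leaf sets must not overlap.
#'
#' @param tree A \code{labeled_tree}.
#' @param clade_spec Named list: type name -> character vector of leaf names.
#' @param include_stem If \code{TRUE} (default) label the stem branch; if
#'   \code{FALSE}, label all branches inside the clade instead.
#' @return The tree with updated \code{edge_types}.
#' @export
label_branches <- function(tree, clade_spec, include_stem = TRUE) {
  stopifnot(inherits(tree, "labeled_tree"))
  phy <- tree$phylo
  nm <- names(clade_spec)
  if (is.null(nm) || any(nm == "")) stop("clade_spec must be a named list")
  for (i in seq_along(clade_spec)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(clade_spec[[i]], clade_spec[[j]]))) {
        stop("overlapping clade specs '", nm[j], "' and '", nm[i], "'")
      }
    }
  }
  types <- rep("background", nrow(phy$edge))
  for (i in seq_along(clade_spec)) {
    leaves <- clade_spec[[i]]
    miss <- setdiff(leaves, phy$tip.label)
    if (length(miss)) stop("unknown leaves in clade '", nm[i], "': ",
                           paste(miss, collapse = ", "))
    tips <- match(leaves, phy$tip.label)
    if (length(tips) == 1L) {
      node <- tips
    } else {
      node <- ape::getMRCA(phy, tips)
      desc <- descendant_tips(phy, node)
      if (!setequal(desc, tips)) {
        stop("leaf set of clade '", nm[i], "' is not monophyletic")
      }
    }
    stem <- which(phy$edge[, 2L] == node)
    if (!length(stem)) stop("clade '", nm[i], "' spans the root; cannot label its stem")
    if (include_stem) {
      types[stem] <- nm[i]
    } else {
      types[edges_within(phy, node)] <- nm[i]
    }
  }
  tree$edge_types <- types
  tree
}

descendant_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- phy$edge[phy$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

edges_within <- function(phy, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    es <- which(phy$edge[, 1L] == nd)
    out <- c(out, es)
    stack <- c(stack, phy$edge[es, 2L][phy$edge[es, 2L] > length(phy$tip.label)])
  }
  out
}
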