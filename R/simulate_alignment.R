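#' Default 8-taxon study tree for selection simulations
#'
#' A balanced 8-taxon topology with a deeply diverged 4-taxon clade whose
#' stem branch carries the foreground label \code{"FG"} (stem length 0.4
#' expected substitutions per codon, tip branches 0.3, inner branches 0.15;
#' trifurcating root so the stem is a genuine unrooted branch). Divergence
#' on this scale matches anciently separated retroelement clades, where
#' lineage-specific selective episodes are tested.
#'
#' @return A \code{labeled_tree}.
#' @export
default_selection_tree <- function() {
  phy <- ape::read.tree(text = paste0(
    "(((a:0.3,b:0.3):0.15,(c:0.3,d:0.3):0.15)FG_STEM:0.4,",
    "(e:0.3,f:0.3):0.15,(g:0.3,h:0.3):0.15);"))
  tr <- labeled_tree(phy)
  stem <- which(phy$node.label == "FG_STEM")
  node <- length(phy$tip.label) + stem
  tr$phylo$node.label <- NULL
  tr$edge_types[tr$phylo$edge[, 2L] == node] <- "FG"
  tr
}

#' Simulate a codon alignment under a site-class model
#'
#' Evolves codon sites along a labeled tree under any
#' \code{\link{site_class_model}}: each site draws its class from the model's
#' proportions, the root codon is drawn from the stationary frequencies, and
#' substitution along every branch follows the class's codon process, with
#' the class's branch-type omega map deciding which omega applies on each
#' branch (so model A's classes 2a/2b switch to omega2 exactly on the
#' foreground branches). Output is bit-reproducible given \code{seed}.
#'
#' @param tree A \code{labeled_tree} with branch lengths; at least 2 leaves
#'   for a meaningful alignment. A tree whose branch lengths are all zero
#'   yields identical rows (with a warning).
#' @param model A \code{site_class_model}.
#' @param n_sites Number of codon sites (>= 1).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return List with \code{alignment} (a \code{codon_alignment}),
#'   \code{site_classes} (1-based class index per site, the simulation
#'   truth), and \code{node_states} (codon index matrix, all tree nodes x
#'   sites, for substitution counting).
#' @export
simulate_codon_alignment <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "labeled_tree"), inherits(model, "site_class_model"))
  if (n_sites < 1) stop("n_sites must be >= 1")
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  if (ntip >= 2 && all(phy$edge.length == 0)) {
    warning("all branch lengths are zero; all sequences will be identical")
  }
  code <- default_code()
  nstate <- length(code$sense)
  freqs <- if (is.null(model$freqs)) rep(1 / nstate, nstate) else model$freqs
  props <- vapply(model$classes, `[[`, numeric(1), "prop")
  with_local_seed(seed, {
    cls <- sample.int(length(props), n_sites, replace = TRUE, prob = props)
    ord <- ape::reorder.phylo(phy, "postorder")
    perm <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                  paste(phy$edge[, 1], phy$edge[, 2]))
    types <- tree$edge_types[perm]
    nnode <- ntip + phy$Nnode
    states <- matrix(NA_integer_, nnode, n_sites)
    root <- ord$edge[nrow(ord$edge), 1L]
    states[root, ] <- sample.int(nstate, n_sites, replace = TRUE, prob = freqs)
    proc_cache <- list()
    P_for <- function(om, t) {
      key <- sprintf("%.17g|%.17g", om, t)
      P <- proc_cache[[key]]
      if (is.null(P)) {
        P <- transition_probs(
          codon_process(model$kappa, om, freqs, code, scale = FALSE), t)
        proc_cache[[key]] <<- P
      }
      P
    }
    # same branch-length convention as the likelihood: lengths are expected
    # substitutions per codon under the class mixture for the branch's type
    scales <- mixture_edge_scales(model, types, code)
    for (e in rev(seq_len(nrow(ord$edge)))) {   # preorder: root towards tips
      parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
      for (ci in unique(cls)) {
        sites <- which(cls == ci)
        om <- omega_for_types(model$classes[[ci]]$omega, types[e])
        P <- P_for(om, ord$edge.length[e] / scales[e])
        ps <- states[parent, sites]
        for (s in unique(ps)) {
          sel <- sites[ps == s]
          states[child, sel] <- sample.int(nstate, length(sel),
                                           replace = TRUE, prob = P[s, ])
        }
      }
    }
    tipm <- states[seq_len(ntip), , drop = FALSE]
    rownames(tipm) <- phy$tip.label
    list(alignment = codon_alignment(tipm, code = code),
         site_classes = cls, node_states = states)
  })
}
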