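# Felsenstein pruning over codon site-class mixtures.
#
# The alignment is compressed to unique site patterns; partial likelihoods are
# 61 x npattern matrices so each internal edge costs one dgemm and each tip
# edge a column selection. Every child contribution is rescaled by its column
# sums (any positive factor works) with the logs accumulated, so the
# computation is underflow-safe at any tree size.

prepare_likelihood <- function(aln, tree, code = default_code()) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "labeled_tree"))
  phy <- tree$phylo
  if (!all(sort(phy$tip.label) == sort(aln$taxa))) {
    stop("tree tips and alignment taxa differ")
  }
  ord <- ape::reorder.phylo(phy, "postorder")
  perm <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(phy$edge[, 1], phy$edge[, 2]))
  types <- tree$edge_types[perm]
  ntip <- length(phy$tip.label)
  key <- apply(aln$codons, 2L, paste, collapse = ",")
  upos <- which(!duplicated(key))
  map <- match(key, key[upos])
  states <- aln$codons[phy$tip.label, upos, drop = FALSE]
  weights <- tabulate(map, nbins = length(upos))
  # postorder sequence of internal nodes with their child-edge groups, so the
  # pruning can reuse unchanged per-edge contributions between site classes
  parents <- unique(ord$edge[, 1L])
  children_edges <- lapply(parents, function(p) which(ord$edge[, 1L] == p))
  names(children_edges) <- parents
  list(edge = ord$edge, lengths = ord$edge.length, types = types, perm = perm,
       ntip = ntip, nnode = ntip + phy$Nnode,
       root = ord$edge[nrow(ord$edge), 1L],
       node_order = parents, children_edges = children_edges,
       states = states, weights = weights, pattern_of_site = map,
       nsites = ncol(aln$codons), code = code,
       cache = new.env(parent = emptyenv()))
}

# Per-pattern log-likelihood for one site class. Each per-edge contribution
# is rescaled to unit column sums with the logs accumulated (underflow-safe),
# and is cached: when `prev` (the result for an already-computed class) is
# supplied, contributions whose transition matrix and child subtree are
# unchanged are reused, so model A's foreground classes 2a/2b only recompute
# the foreground edges and their root path.
prune_patterns <- function(prep, Plist, freqs, prev = NULL) {
  npat <- ncol(prep$states)
  if (nrow(prep$edge) == 0L) {            # degenerate single-taxon tree
    return(list(loglik = log(freqs[prep$states[1L, ]])))
  }
  nstate <- nrow(Plist[[1L]])
  nedge <- nrow(prep$edge)
  conts <- vector("list", nedge)
  logs <- vector("list", nedge)
  partial <- vector("list", prep$nnode)
  node_changed <- rep(TRUE, prep$nnode)
  edge <- prep$edge
  for (node in prep$node_order) {
    kid_edges <- prep$children_edges[[as.character(node)]]
    any_change <- FALSE
    for (e in kid_edges) {
      child <- edge[e, 2L]
      reuse <- !is.null(prev) && identical(Plist[[e]], prev$Plist[[e]]) &&
        (child <= prep$ntip || !node_changed[child])
      if (reuse) {
        conts[[e]] <- prev$conts[[e]]
        logs[[e]] <- prev$logs[[e]]
      } else {
        if (child <= prep$ntip) {
          # tip contributions are bounded probabilities; no rescaling needed
          conts[[e]] <- Plist[[e]][, prep$states[child, ], drop = FALSE]
        } else {
          cont <- Plist[[e]] %*% partial[[child]]
          mx <- .colSums(cont, nstate, npat)
          conts[[e]] <- cont / rep(mx, each = nstate)
          logs[[e]] <- log(mx)
        }
        any_change <- TRUE
      }
    }
    if (!any_change && !is.null(prev) && !is.null(prev$partials[[node]])) {
      partial[[node]] <- prev$partials[[node]]
      node_changed[node] <- FALSE
    } else {
      p <- conts[[kid_edges[1L]]]
      for (e in kid_edges[-1L]) p <- p * conts[[e]]
      partial[[node]] <- p
      node_changed[node] <- TRUE
    }
  }
  sl <- as.vector(freqs %*% partial[[prep$root]])
  logs_used <- Filter(Negate(is.null), logs)
  logscale <- if (length(logs_used)) Reduce(`+`, logs_used) else 0
  # impossible columns (e.g. differing codons over zero-length branches)
  # yield likelihood 0; clamp so the log stays finite and very negative
  list(loglik = log(pmax(sl, 1e-300)) + logscale,
       Plist = Plist, conts = conts, logs = logs, partials = partial)
}

omega_for_types <- function(omega_map, types) {
  om <- omega_map[types]
  om[is.na(om)] <- omega_map[["background"]]
  unname(om)
}

# npat x nclass matrix of per-pattern log-likelihoods under each site class.
# The prep object carries per-fit caches for eigendecompositions (keyed by
# kappa/omega) and transition matrices (keyed by kappa/omega/time): during a
# quasi-Newton fit successive evaluations move one parameter at a time, so
# most matrices are reused across evaluations.
class_pattern_logliks <- function(prep, model, lengths = prep$lengths) {
  nstate <- length(prep$code$sense)
  freqs <- if (is.null(model$freqs)) rep(1 / nstate, nstate) else model$freqs
  cache <- prep$cache
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$proc)) { cache$proc <- list(); cache$P <- list() }
  get_proc <- function(om) {
    key <- sprintf("%.15g|%.15g", model$kappa, om)
    p <- cache$proc[[key]]
    if (is.null(p)) {
      p <- codon_process(model$kappa, om, freqs, prep$code, scale = FALSE)
      if (length(cache$proc) > 400L) cache$proc <- list()
      cache$proc[[key]] <- p
    }
    p
  }
  get_P <- function(om, t) {
    key <- sprintf("%.15g|%.15g|%.15g", model$kappa, om, t)
    P <- cache$P[[key]]
    if (is.null(P)) {
      P <- transition_probs(get_proc(om), t)
      if (length(cache$P) > 1500L) cache$P <- list()
      cache$P[[key]] <- P
    }
    P
  }
  # Branch lengths are expected substitutions per codon under the class
  # mixture; divide by the branch-type mixture-average raw rate so classes
  # keep their relative speeds (positively selected classes evolve faster).
  scales <- mixture_edge_scales(model, prep$types, prep$code)
  out <- matrix(NA_real_, ncol(prep$states), length(model$classes))
  results <- vector("list", length(model$classes))
  for (ci in seq_along(model$classes)) {
    cl <- model$classes[[ci]]
    om <- omega_for_types(cl$omega, prep$types)
    Plist <- lapply(seq_along(om), function(e) {
      get_P(om[e], lengths[e] / scales[e])
    })
    # reuse partials from the already-computed class sharing most matrices
    prev <- NULL
    if (ci > 1L) {
      shared <- vapply(seq_len(ci - 1L), function(cj) {
        sum(vapply(seq_along(Plist), function(e) {
          identical(Plist[[e]], results[[cj]]$Plist[[e]])
        }, logical(1)))
      }, numeric(1))
      if (max(shared) > 0) prev <- results[[which.max(shared)]]
    }
    results[[ci]] <- prune_patterns(prep, Plist, freqs, prev)
    out[, ci] <- results[[ci]]$loglik
  }
  out
}

mixture_loglik_from_patterns <- function(logL, props, weights) {
  keep <- props > 0
  lw <- sweep(logL[, keep, drop = FALSE], 2L, log(props[keep]), "+")
  m <- apply(lw, 1L, max)
  site <- m + log(rowSums(exp(lw - m)))
  sum(weights * site)
}

#' Log-likelihood of a codon alignment under a site-class model
#'
#' Felsenstein pruning with per-branch transition matrices, summed over the
#' model's site-class mixture: for each site,
#' \eqn{\log \sum_c p_c L_c(\mathrm{site})}, where class c determines the
#' omega used on each branch through its branch-type omega map (foreground
#' branches switch to omega2 in model A classes 2a/2b; the extended clade
#' model C uses one omega per branch type in its divergent class).
#'
#' @param aln A \code{codon_alignment}.
#' @param tree A \code{labeled_tree} with branch lengths (expected
#'   substitutions per codon).
#' @param model A \code{site_class_model}.
#' @return Scalar log-likelihood.
#' @export
model_loglik <- function(aln, tree, model) {
  prep <- prepare_likelihood(aln, tree)
  logL <- class_pattern_logliks(prep, model)
  props <- vapply(model$classes, `[[`, numeric(1), "prop")
  mixture_loglik_from_patterns(logL, props, prep$weights)
}

#' Per-site and per-class log-likelihoods
#'
#' Lower-level companion of \code{\link{model_loglik}} used by the
#' empirical-Bayes site identification: returns the matrix of per-site
#' log-likelihoods under each site class (expanded from pattern compression).
#'
#' @inheritParams model_loglik
#' @return List with \code{logL} (nsites x nclasses), \code{props}, and the
#'   total \code{loglik}.
#' @export
model_site_logliks <- function(aln, tree, model) {
  prep <- prepare_likelihood(aln, tree)
  logL <- class_pattern_logliks(prep, model)
  props <- vapply(model$classes, `[[`, numeric(1), "prop")
  list(logL = logL[prep$pattern_of_site, , drop = FALSE], props = props,
       loglik = mixture_loglik_from_patterns(logL, props, prep$weights))
}

#' Log-likelihood of a single codon column under one process
#'
#' Convenience entry point used to validate the pruning recursion against
#' brute-force enumeration of internal states on small trees.
#'
#' @param column Named vector (by taxon) of sense-codon indices, or codon
#'   strings.
#' @param tree A \code{labeled_tree}.
#' @param process A \code{codon_process} applied to every branch, or a list
#'   of processes, one per edge (in the order of \code{tree$phylo$edge}).
#' @return Scalar log-probability of the column.
#' @export
site_loglik <- function(column, tree, process) {
  if (is.character(column)) {
    column <- stats::setNames(codon_to_index(column), names(column))
  }
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  if (!all(phy$tip.label %in% names(column))) {
    stop("column must be named by the tree's taxa")
  }
  per_edge <- if (inherits(process, "codon_process")) {
    rep(list(process), max(1L, nrow(phy$edge)))
  } else process
  freqs <- per_edge[[1L]]$freqs
  if (ntip == 1L && phy$Nnode == 0L) return(log(freqs[column[[1L]]]))
  ord <- ape::reorder.phylo(phy, "postorder")
  perm <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(phy$edge[, 1], phy$edge[, 2]))
  partial <- vector("list", ntip + phy$Nnode)
  for (e in seq_len(nrow(ord$edge))) {
    child <- ord$edge[e, 2L]; parent <- ord$edge[e, 1L]
    P <- transition_probs(per_edge[[perm[e]]], ord$edge.length[e])
    cont <- if (child <= ntip) P[, column[[phy$tip.label[child]]]]
      else P %*% partial[[child]]
    partial[[parent]] <- if (is.null(partial[[parent]])) cont
      else partial[[parent]] * cont
  }
  root <- ord$edge[nrow(ord$edge), 1L]
  log(max(sum(freqs * partial[[root]]), 1e-300))
}
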