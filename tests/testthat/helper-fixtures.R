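# Shared fixtures and cached heavy computations. The power/type-I
# calibration runs (20 replicates each) are computed once per session and
# reused by both the unit-level parameter-recovery tests and the
# calibration checks.

.fixture_cache <- new.env(parent = emptyenv())

study_tree <- function() default_selection_tree()

# Standard study conditions for branch-site simulations:
# p0 = 0.5, p1 = 0.3, omega0 = 0.1, kappa = 2, foreground "FG".
study_model <- function(omega2) {
  if (omega2 > 1) model_a(2, 0.5, 0.3, 0.1, omega2, "FG")
  else model_a_null(2, 0.5, 0.3, 0.1, "FG")
}

# One full branch-site test replicate at the study conditions.
branch_site_replicate <- function(omega2, seed, n_sites = 500) {
  tr <- study_tree()
  sim <- simulate_codon_alignment(tr, study_model(omega2), n_sites, seed = seed)
  res <- branch_site_test(sim$alignment, tr, foreground = "FG")
  list(stat = res$stat, p = res$p_raw,
       omega2_hat = res$alt_fit$natural_params[["omega2"]],
       boundary = res$alt_fit$boundary, sim = NULL)
}

# Cached 20-replicate calibration runs (omega2 = 6 power; omega2 = 1 type I).
calibration_runs <- function(omega2, n_rep = 20) {
  key <- sprintf("calib_%g_%d", omega2, n_rep)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- lapply(seq_len(n_rep), function(i) {
      branch_site_replicate(omega2, seed = 1000 * omega2 + i)
    })
  }
  .fixture_cache[[key]]
}

# Small codon alignment + tree for fast likelihood tests.
toy_tree <- function(text = "((a:0.2,b:0.3):0.1,c:0.4);") {
  tf <- tempfile(fileext = ".nwk")
  writeLines(text, tf)
  read_newick(tf)
}

random_codon_column <- function(taxa) {
  stats::setNames(sample.int(61, length(taxa), replace = TRUE), taxa)
}

# Brute-force likelihood of a single codon column by enumerating all
# internal-node state assignments (independent oracle for the pruning).
brute_force_site_loglik <- function(column, tree, process) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  states <- integer(nnode)
  states[seq_len(ntip)] <- column[phy$tip.label]
  internals <- (ntip + 1L):nnode
  Ps <- lapply(seq_len(nrow(phy$edge)), function(e) {
    transition_probs(process, phy$edge.length[e])
  })
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1L]
  total <- 0
  grid <- do.call(expand.grid, rep(list(seq_len(61)), length(internals)))
  for (g in seq_len(nrow(grid))) {
    states[internals] <- as.integer(grid[g, ])
    p <- process$freqs[states[root]]
    for (e in seq_len(nrow(phy$edge))) {
      p <- p * Ps[[e]][states[phy$edge[e, 1L]], states[phy$edge[e, 2L]]]
    }
    total <- total + p
  }
  log(total)
}

# Closure-principle Hommel oracle: adjusted p for hypothesis i is the
# maximum over all intersection hypotheses containing i of the Simes
# p-value of that intersection.
closure_simes_adjust <- function(p) {
  n <- length(p)
  simes <- function(ps) min(length(ps) * sort(ps) / seq_along(ps))
  vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    worst <- 0
    for (m in 0:length(others)) {
      combos <- utils::combn(others, m, simplify = FALSE)
      for (cc in combos) {
        worst <- max(worst, simes(p[c(i, cc)]))
      }
    }
    min(1, worst)
  }, numeric(1))
}
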