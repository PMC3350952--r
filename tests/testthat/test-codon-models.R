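test_that("rate matrices satisfy the generator and reversibility invariants", {
  set.seed(17)
  for (rep in 1:20) {
    kappa <- runif(1, 0.5, 8)
    omega <- runif(1, 0.05, 5)
    f <- runif(61, 0.2, 1); f <- f / sum(f)
    p <- codon_process(kappa, omega, f)
    Q <- rate_matrix(p)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_equal(-sum(f * diag(Q)), 1, tolerance = 1e-12)       # unit rate
    flux <- f * Q                                   # pi_i * q_ij
    expect_lt(max(abs(flux - t(flux))), 1e-12)      # detailed balance
    # only single-nucleotide changes have positive rates
    cls <- codon_pair_classes()
    expect_true(all(Q[cls == 0 & row(Q) != col(Q)] == 0))
  }
  # kappa = omega = 1, uniform: all allowed changes share one rate
  p1 <- codon_process(1, 1)
  Q1 <- rate_matrix(p1)
  offdiag <- Q1[codon_pair_classes() > 0]
  expect_lt(diff(range(offdiag)), 1e-12)
  expect_error(codon_process(2, -1), "omega")
})

test_that("transition probabilities behave as a stochastic semigroup", {
  p <- codon_process(2.5, 0.3)
  expect_equal(transition_probs(p, 0), diag(61), tolerance = 1e-12)
  P <- transition_probs(p, 0.7)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_true(all(P >= 0))
  # Chapman-Kolmogorov
  expect_equal(transition_probs(p, 0.2) %*% transition_probs(p, 0.5), P,
               tolerance = 1e-9)
  # ergodic limit: rows tend to the stationary frequencies
  Pinf <- transition_probs(p, 500)
  expect_lt(max(abs(sweep(Pinf, 2, p$freqs))), 1e-6)
  # independent matrix exponential agrees
  expect_equal(P, as.matrix(Matrix::expm(rate_matrix(p) * 0.7)),
               tolerance = 1e-9)
})

test_that("pruning matches brute-force enumeration on small trees", {
  set.seed(23)
  tr3 <- toy_tree("((a:0.2,b:0.3):0.1,c:0.4);")
  for (rep in 1:10) {
    proc <- codon_process(runif(1, 0.5, 6), runif(1, 0.05, 4))
    col <- random_codon_column(c("a", "b", "c"))
    expect_equal(site_loglik(col, tr3, proc),
                 brute_force_site_loglik(col, tr3, proc), tolerance = 1e-10)
  }
  tr4 <- toy_tree("((a:0.15,b:0.25):0.1,(c:0.3,d:0.1):0.2);")
  for (rep in 1:3) {
    proc <- codon_process(runif(1, 0.5, 6), runif(1, 0.05, 4))
    col <- random_codon_column(c("a", "b", "c", "d"))
    expect_equal(site_loglik(col, tr4, proc),
                 brute_force_site_loglik(col, tr4, proc), tolerance = 1e-10)
  }
})

test_that("degenerate site likelihoods take their closed forms", {
  proc <- codon_process(2, 0.5)
  tr1 <- toy_tree("(a:0.3);")
  expect_equal(site_loglik(c(a = 7L), tr1, proc), log(1 / 61),
               tolerance = 1e-12)
  tr0 <- labeled_tree(ape::read.tree(text = "(a:0,b:0);"))
  expect_equal(site_loglik(c(a = 5L, b = 5L), tr0, proc), log(1 / 61),
               tolerance = 1e-10)
  # differing codons over zero length: guarded large negative, not -Inf
  ll <- site_loglik(c(a = 5L, b = 6L), tr0, proc)
  expect_true(is.finite(ll))
  expect_lt(ll, -500)
})

test_that("mixture likelihood respects nesting and i.i.d.-site structure", {
  tr <- study_tree()
  sim <- simulate_codon_alignment(tr, study_model(6), 80, seed = 3)
  aln <- sim$alignment
  mA <- model_a(2, 0.6, 0.2, 0.2, 1 + 1e-12, "FG")
  mN <- model_a_null(2, 0.6, 0.2, 0.2, "FG")
  expect_equal(model_loglik(aln, tr, mA), model_loglik(aln, tr, mN),
               tolerance = 1e-9)

  # one-class model reduces to the sum of site log-likelihoods
  m0 <- model_m0(2, 0.4)
  sl <- model_site_logliks(aln, tr, m0)
  expect_equal(sum(sl$logL[, 1]), model_loglik(aln, tr, m0), tolerance = 1e-8)

  # duplicating every column doubles the log-likelihood exactly
  dbl <- codon_alignment(cbind(aln$codons, aln$codons))
  mA2 <- model_a(1.7, 0.5, 0.3, 0.15, 3, "FG")
  expect_equal(model_loglik(dbl, tr, mA2), 2 * model_loglik(aln, tr, mA2),
               tolerance = 1e-8)

  # invariance under taxon reordering
  perm <- aln$codons[sample(nrow(aln$codons)), , drop = FALSE]
  expect_equal(model_loglik(codon_alignment(perm), tr, mA2),
               model_loglik(aln, tr, mA2), tolerance = 1e-8)

  # invariance under re-rooting along an unlabeled branch (reversibility)
  rerooted <- labeled_tree(ape::root(tr$phylo, outgroup = "g",
                                     resolve.root = TRUE))
  expect_equal(model_loglik(aln, rerooted, model_m0(2, 0.4)),
               model_loglik(aln, tr, m0), tolerance = 1e-7)
})

test_that("M0 fits recover the simulation omega", {
  tr <- study_tree()
  omegas <- vapply(1:10, function(sd) {
    sim <- simulate_codon_alignment(tr, model_m0(2, 0.2), 500, seed = 300 + sd)
    fit <- fit_codon_model(sim$alignment, tr, "M0", n_starts = 1)
    fit$natural_params[["omega"]]
  }, numeric(1))
  expect_gte(median(omegas), 0.15)
  expect_lte(median(omegas), 0.25)
})

test_that("fits are stable: refitting from the optimum does not improve", {
  tr <- study_tree()
  sim <- simulate_codon_alignment(tr, study_model(6), 300, seed = 8)
  fit <- fit_codon_model(sim$alignment, tr, "M1a", n_starts = 2)
  expect_true(fit$converged)
  np <- fit$natural_params
  refit <- fit_codon_model(sim$alignment, tr, "M1a", n_starts = 1,
                           extra_starts = list(c(np[["kappa"]], np[["p0"]],
                                                 np[["omega0"]])))
  expect_lte(refit$loglik - fit$loglik, 1e-5)
  expect_gte(refit$loglik - fit$loglik, -1e-6)
})

test_that("model A simulations yield omega2 estimates above 1 when selection acted", {
  runs <- calibration_runs(6)
  w2 <- vapply(runs, `[[`, numeric(1), "omega2_hat")
  expect_gte(mean(w2 > 1), 0.9)
})

test_that("uninformative alignments are flagged", {
  tr <- study_tree()
  m <- matrix(5L, 8, 30, dimnames = list(tr$phylo$tip.label, NULL))
  aln <- codon_alignment(m)
  fit <- fit_codon_model(aln, tr, "M0", n_starts = 1)
  expect_true("flat_likelihood" %in% fit$boundary)
})
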