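test_that("chi-square and mixture tails match quadrature and quantiles", {
  expect_equal(chi2_pvalue(0, 1), 1)
  expect_equal(chi2_pvalue(stats::qchisq(0.95, 1), 1), 0.05, tolerance = 1e-12)
  expect_equal(chi2_pvalue(3.841459, 1), 0.05, tolerance = 1e-6)
  expect_equal(mixture_chi2_pvalue(0), 1)
  expect_equal(mixture_chi2_pvalue(-2), 1)
  # monotone decreasing in the statistic
  s <- seq(0.1, 10, by = 0.3)
  expect_true(all(diff(vapply(s, mixture_chi2_pvalue, numeric(1))) < 0))
  expect_true(all(diff(vapply(s, chi2_pvalue, numeric(1), df = 3)) < 0))
  # agreement with numerical quadrature of the chi-square density
  for (stat in c(0.7, 2.3, 5.1)) {
    quad <- stats::integrate(function(x) stats::dchisq(x, 1), stat, Inf,
                             rel.tol = 1e-12)$value
    expect_equal(chi2_pvalue(stat, 1), quad, tolerance = 1e-10)
    expect_equal(mixture_chi2_pvalue(stat), quad / 2, tolerance = 1e-10)
  }
  expect_error(mixture_chi2_pvalue(Inf), "finite")
})

test_that("Hommel adjustment equals the closure-principle oracle", {
  expect_equal(hommel_adjust(0.03), 0.03)
  expect_error(hommel_adjust(c(0.2, 1.4)), "0, 1")

  tab3 <- c(T = 0.1005255, R = 0.145176, G = 0.014513, TR = 0.026867,
            GTR = 0.0087175)
  expect_equal(unname(hommel_adjust(tab3)), closure_simes_adjust(tab3),
               tolerance = 1e-12)
  set.seed(19)
  for (rep in 1:10) {
    p <- runif(sample(2:5, 1))
    expect_equal(unname(hommel_adjust(p)), closure_simes_adjust(p),
                 tolerance = 1e-12)
  }
})

test_that("Hommel matches Hochberg at n = 2 and dominates Holm", {
  grid <- expand.grid(p1 = seq(0.01, 0.9, by = 0.07),
                      p2 = seq(0.01, 0.9, by = 0.07))
  for (i in seq_len(nrow(grid))) {
    p <- as.numeric(grid[i, ])
    expect_equal(hommel_adjust(p), stats::p.adjust(p, "hochberg"),
                 tolerance = 1e-12)
  }
  set.seed(29)
  for (rep in 1:20) {
    p <- runif(5)
    expect_true(all(hommel_adjust(p) <= stats::p.adjust(p, "holm") + 1e-12))
    expect_true(all(hommel_adjust(p) >= p))
    expect_true(all(hommel_adjust(p) <= 1))
  }
})

test_that("Hommel and Holm control the FWER under the global null", {
  set.seed(37)
  n_rep <- 500
  rej_hommel <- rej_holm <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    p <- runif(5)
    rej_hommel[i] <- any(hommel_adjust(p) < 0.05)
    rej_holm[i] <- any(stats::p.adjust(p, "holm") < 0.05)
  }
  expect_lte(mean(rej_hommel), 0.08)
  expect_lte(mean(rej_holm), 0.08)
})

test_that("clade-site test df is 3 for one foreground type and nesting holds", {
  expect_equal(n_free_params("cladeC_ext", n_types = 2) - n_free_params("M1a"), 3)
  expect_equal(n_free_params("modelA") - n_free_params("modelA_null"), 1)

  tr <- study_tree()
  sim <- simulate_codon_alignment(tr, study_model(6), 120, seed = 21)
  res <- clade_site_test(sim$alignment, tr, n_starts = 1)
  expect_equal(res$df, 3)
  expect_gte(res$alt_fit$loglik, res$null_fit$loglik - 1e-6)
  expect_gte(res$stat, 0)
  expect_identical(res$null_family, "chi2")
})

test_that("clade-site test detects strong foreground divergence", {
  # class-2 omega 4 on the foreground type vs 0.5 background
  tr <- study_tree()
  m <- model_cladec(2, 0.5, 0.2, 0.1, c(background = 0.5, FG = 4))
  hits <- vapply(1:5, function(sd) {
    sim <- simulate_codon_alignment(tr, m, 400, seed = 500 + sd)
    clade_site_test(sim$alignment, tr, n_starts = 1)$p_raw
  }, numeric(1))
  expect_gte(mean(hits < 0.05), 0.8)
})

test_that("branch-site test calibrates: power under omega2=6, level under the null", {
  power_runs <- calibration_runs(6)
  p_power <- vapply(power_runs, `[[`, numeric(1), "p")
  expect_gte(mean(p_power < 0.05), 0.8)

  null_runs <- calibration_runs(1)
  p_null <- vapply(null_runs, `[[`, numeric(1), "p")
  expect_lte(mean(p_null < 0.05), 0.15)
  # statistics are always clamped nonnegative
  expect_true(all(vapply(power_runs, `[[`, numeric(1), "stat") >= 0))
  expect_true(all(vapply(null_runs, `[[`, numeric(1), "stat") >= 0))
  # under the null the omega2 estimate often sits at its lower bound
  at_bound <- vapply(null_runs, function(r) "omega2_lower" %in% r$boundary,
                     logical(1))
  expect_gte(mean(at_bound), 0.3)
})

test_that("branch scans adjust with Hommel and are order-invariant", {
  tr <- study_tree()
  sim <- simulate_codon_alignment(tr, study_model(6), 150, seed = 77)
  clades <- list(FG = c("a", "b", "c", "d"), GH = c("g", "h"))
  scan <- scan_branches(sim$alignment, tr, clades, alpha = 0.1)
  expect_s3_class(scan, "branch_scan")
  expect_equal(scan$table$p_hommel,
               unname(hommel_adjust(scan$table$p_raw)))
  expect_true(all(scan$table$p_hommel >= scan$table$p_raw))

  scan_rev <- scan_branches(sim$alignment, tr, rev(clades), alpha = 0.1)
  m1 <- scan$table[order(scan$table$branch), ]
  m2 <- scan_rev$table[order(scan_rev$table$branch), ]
  expect_equal(m1$p_raw, m2$p_raw, tolerance = 1e-6)
  expect_equal(m1$p_hommel, m2$p_hommel, tolerance = 1e-6)

  # single-branch scan: adjustment is the identity
  one <- scan_branches(sim$alignment, tr, clades["FG"], alpha = 0.1)
  expect_equal(one$table$p_raw, one$table$p_hommel)
})

test_that("site posteriors identify simulated positively selected sites", {
  tr <- study_tree()
  sim <- simulate_codon_alignment(tr, study_model(6), 500, seed = 99)
  bl <- estimate_branch_lengths(sim$alignment, tr, n_starts = 1)
  alt <- fit_codon_model(sim$alignment, bl$tree, "modelA", foreground = "FG")
  sp <- site_posteriors(alt, sim$alignment, bl$tree)
  expect_true(all(sp$table$posterior >= 0 & sp$table$posterior <= 1))
  expect_true(all(sp$table$site[sp$table$flag95] %in%
                    sp$table$site[sp$table$flag90]))
  truth <- sim$site_classes >= 3
  auc <- suppressMessages(as.numeric(pROC::auc(truth, sp$table$posterior,
                                               quiet = TRUE)))
  expect_gt(auc, 0.8)

  # degenerate model with no positively selected mass
  m0mass <- alt
  m0mass$model <- model_a(2, 0.625, 0.375, 0.1, 1 + 1e-9, "FG")
  sp0 <- site_posteriors(m0mass, sim$alignment, bl$tree)
  expect_true(all(sp0$table$posterior < 1e-6))

  # grid EB stays a valid posterior and flags nest
  spg <- site_posteriors(alt, sim$alignment, bl$tree, method = "grid_EB")
  expect_true(all(spg$table$posterior >= 0 & spg$table$posterior <= 1))
  expect_true(all(spg$table$site[spg$table$flag95] %in%
                    spg$table$site[spg$table$flag90]))
})
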