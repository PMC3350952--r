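#' Tail probabilities for likelihood-ratio tests
#'
#' \code{chi2_pvalue} is the upper-tail chi-square probability.
#' \code{mixture_chi2_pvalue} is the boundary null for the branch-site test:
#' because the null (omega2 = 1) places the parameter on the boundary of the
#' alternative, 2*delta-log-likelihood is asymptotically distributed as the
#' 50:50 mixture of a point mass at zero and chi-square with 1 df, so
#' p = 1 for a statistic <= 0 and half the chi-square(1) tail otherwise.
#'
#' @param stat Observed 2*delta-log-likelihood (finite).
#' @param df Degrees of freedom (for \code{chi2_pvalue}).
#' @return p-value in [0, 1].
#' @examples
#' mixture_chi2_pvalue(1.634722)   # 0.1005255
#' chi2_pvalue(3.841459, 1)        # 0.05
#' @export
mixture_chi2_pvalue <- function(stat) {
  if (!is.finite(stat)) stop("statistic must be finite")
  if (stat <= 0) return(1)
  0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' @rdname mixture_chi2_pvalue
#' @export
chi2_pvalue <- function(stat, df) {
  if (!is.finite(stat)) stop("statistic must be finite")
  if (stat <= 0) return(1)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Hommel FWER-adjusted p-values
#'
#' Hommel's (1988) stepwise procedure based on Simes tests of intersection
#' hypotheses; controls the family-wise error rate and is uniformly at least
#' as powerful as Hochberg among these stepwise procedures. Delegates to
#' \code{stats::p.adjust(method = "hommel")} after validating the input.
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values (same order/names), each >= its raw value.
#' @export
hommel_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) stop("p must be a nonempty numeric vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "hommel")
}

clamp_stat <- function(stat, tol = 1e-6) {
  if (stat < 0) {
    if (stat < -tol) {
      warning("2*delta-loglik = ", format(stat),
              " below -tol; check convergence. Clamping to 0.")
    }
    stat <- 0
  }
  stat
}

# Saturation guard: mean pairwise Jukes-Cantor distance at third codon
# positions, a cheap proxy for the synonymous distance. Values beyond ~3
# (or saturated pairs) make positive-selection inference unreliable.
mean_syn_distance <- function(aln, code = default_code()) {
  dna <- codon_alignment_to_dna(aln, code)
  third <- vapply(dna, function(s) {
    paste(strsplit(s, "")[[1L]][seq(3L, nchar(s), 3L)], collapse = "")
  }, character(1))
  d <- tryCatch(distance_matrix(third, "jc"), error = function(e) NULL)
  if (is.null(d)) return(Inf)
  mean(d[upper.tri(d)])
}

new_lrt_result <- function(null_fit, alt_fit, null_family, df, p_raw,
                           foreground = NULL, syn_distance = NA_real_) {
  stat <- clamp_stat(2 * (alt_fit$loglik - null_fit$loglik))
  structure(
    list(null_fit = null_fit, alt_fit = alt_fit, stat = stat,
         null_family = null_family, df = df, p_raw = p_raw(stat),
         p_adjusted = NULL, foreground = foreground,
         syn_distance = syn_distance),
    class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("LRT:", x$alt_fit$model_id, "vs", x$null_fit$model_id,
      if (!is.null(x$foreground)) paste0("(foreground ", x$foreground, ")"), "\n")
  cat(sprintf("  2*delta-loglik = %.6f, null = %s, p = %.6g\n", x$stat,
              if (x$null_family == "mixture") "1/2*chi2_0 + 1/2*chi2_1"
              else paste0("chi2_", x$df), x$p_raw))
  if (!is.null(x$p_adjusted)) cat(sprintf("  Hommel-adjusted p = %.6g\n", x$p_adjusted))
  invisible(x)
}

#' Branch-site test of positive selection
#'
#' Fits branch-site model A (omega2 >= 1 free on the given foreground branch
#' type) against its null with omega2 fixed at 1, after estimating branch
#' lengths once under M0 (held fixed for both fits). The p-value uses the
#' boundary mixture null \code{1/2 chi2_0 + 1/2 chi2_1}. The null fit is
#' warm-started from the alternative's estimates in addition to the default
#' starts.
#'
#' @param aln A \code{codon_alignment}.
#' @param tree A \code{labeled_tree} whose edge types include
#'   \code{foreground}.
#' @param foreground Foreground branch-type name.
#' @param estimate_bl Estimate branch lengths under M0 first (default TRUE).
#' @param n_starts Starts for each site-class fit (warm start counts toward
#'   the null's total).
#' @param chi2_fallback Use a conservative chi-square(1) null instead of the
#'   mixture (default FALSE).
#' @return An \code{lrt_result}.
#' @export
branch_site_test <- function(aln, tree, foreground, estimate_bl = TRUE,
                             n_starts = 3, chi2_fallback = FALSE) {
  if (estimate_bl) {
    tree <- estimate_branch_lengths(aln, tree, n_starts = 1)$tree
  }
  alt <- fit_codon_model(aln, tree, "modelA", foreground = foreground,
                         n_starts = n_starts)
  np <- alt$natural_params
  warm <- c(np[["kappa"]], min(np[["p0"]] + np[["p1"]], 1 - 1e-6),
            np[["p0"]] / (np[["p0"]] + np[["p1"]]), np[["omega0"]])
  nul <- fit_codon_model(aln, tree, "modelA_null", foreground = foreground,
                         n_starts = max(1, n_starts - 1),
                         extra_starts = list(warm))
  ds <- mean_syn_distance(aln)
  if (is.finite(ds) && ds > 3) {
    warning("mean pairwise synonymous distance ", format(ds, digits = 3),
            " > 3: synonymous substitutions may be saturated")
  }
  pfun <- if (chi2_fallback) function(s) chi2_pvalue(s, 1) else mixture_chi2_pvalue
  new_lrt_result(nul, alt,
                 null_family = if (chi2_fallback) "chi2" else "mixture",
                 df = 1L, p_raw = pfun, foreground = foreground,
                 syn_distance = ds)
}

#' Clade-site test
#'
#' Fits the extended clade model C (a divergent site class with one omega per
#' branch type, including background) against the nearly neutral M1a model.
#' The degrees of freedom are the difference in free parameter counts; with
#' one foreground branch type this is 3. The p-value uses the chi-square
#' null with those df.
#'
#' @inheritParams branch_site_test
#' @return An \code{lrt_result}.
#' @export
clade_site_test <- function(aln, tree, estimate_bl = TRUE, n_starts = 3) {
  if (!any(tree$edge_types != "background")) {
    stop("tree has no labeled branch types for the clade model")
  }
  if (estimate_bl) {
    tree <- estimate_branch_lengths(aln, tree, n_starts = 1)$tree
  }
  nul <- fit_codon_model(aln, tree, "M1a", n_starts = n_starts)
  alt <- fit_codon_model(aln, tree, "cladeC_ext", n_starts = n_starts)
  n_types <- length(unique(tree$edge_types))
  df <- n_free_params("cladeC_ext", n_types = n_types) - n_free_params("M1a")
  ds <- mean_syn_distance(aln)
  new_lrt_result(nul, alt, null_family = "chi2", df = df,
                 p_raw = function(s) chi2_pvalue(s, df), syn_distance = ds)
}

#' Scan several branches with the branch-site test
#'
#' Treats each named clade's stem branch as foreground in turn (the standard
#' way to test several branches), then adjusts the raw p-values with the
#' Hommel FWER procedure and reports the rejection set at \code{alpha}.
#'
#' @param aln A \code{codon_alignment}.
#' @param tree A \code{labeled_tree} (labels are reassigned per scan).
#' @param clades Named list: branch name -> leaf set defining the clade whose
#'   stem is the foreground branch.
#' @param alpha FWER level for the reported rejection set (default 0.05).
#' @param ... Passed to \code{\link{branch_site_test}}.
#' @return Object of class \code{branch_scan}: list with \code{table} (one
#'   row per branch: stat, raw and Hommel-adjusted p, parameter estimates,
#'   rejection flag) and \code{tests} (the \code{lrt_result}s).
#' @export
scan_branches <- function(aln, tree, clades, alpha = 0.05, ...) {
  if (length(clades) == 0L) stop("no branches to scan")
  base <- tree
  base$edge_types <- rep("background", length(base$edge_types))
  bl <- estimate_branch_lengths(aln, base, n_starts = 1)$tree
  tests <- lapply(names(clades), function(nm) {
    labeled <- label_branches(bl, clades[nm])
    branch_site_test(aln, labeled, foreground = nm, estimate_bl = FALSE, ...)
  })
  names(tests) <- names(clades)
  p_raw <- vapply(tests, `[[`, numeric(1), "p_raw")
  p_adj <- hommel_adjust(p_raw)
  for (i in seq_along(tests)) tests[[i]]$p_adjusted <- p_adj[[i]]
  est <- t(vapply(tests, function(tt) {
    np <- tt$alt_fit$natural_params
    c(np[["p0"]], np[["p1"]], np[["omega0"]], np[["omega2"]])
  }, numeric(4)))
  colnames(est) <- c("p0", "p1", "omega0", "omega2")
  tab <- data.frame(
    branch = names(clades),
    stat = vapply(tests, `[[`, numeric(1), "stat"),
    p_raw = p_raw, p_hommel = p_adj, est,
    omega2_unbounded = vapply(tests, function(tt) {
      "omega2_upper" %in% tt$alt_fit$boundary
    }, logical(1)),
    reject = p_adj < alpha,
    row.names = NULL)
  structure(list(table = tab, tests = tests, alpha = alpha),
            class = "branch_scan")
}

#' @export
print.branch_scan <- function(x, ...) {
  cat("Branch-site scan (Hommel FWER correction, alpha =", x$alpha, ")\n")
  tab <- x$table
  tab$omega2 <- ifelse(tab$omega2_unbounded, Inf, tab$omega2)
  print(tab[, c("branch", "stat", "p_raw", "p_hommel", "p0", "p1",
                "omega0", "omega2", "reject")], digits = 5, row.names = FALSE)
  rej <- tab$branch[tab$reject]
  cat("rejected:", if (length(rej)) paste(rej, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Posterior identification of positively selected sites
#'
#' Naive empirical Bayes (NEB): at the alternative fit's maximum-likelihood
#' estimates, the posterior probability that a site belongs to the positively
#' selected classes (2a or 2b) is computed by Bayes' rule from the per-class
#' site likelihoods. \code{"grid_EB"} additionally averages the posterior
#' over a uniform-prior grid on (p0, p1, omega2) weighted by the data
#' likelihood — a lightweight empirical-Bayes treatment of estimation
#' uncertainty in those parameters (the full BEB integration of the codeml
#' literature is not reimplemented). Sites are flagged at posterior cutoffs
#' 0.90 and 0.95.
#'
#' @param alt_fit The model A \code{codon_fit} (alternative).
#' @param aln The \code{codon_alignment} used in the fit.
#' @param tree The \code{labeled_tree} used in the fit (M0 branch lengths).
#' @param method \code{"NEB"} (default) or \code{"grid_EB"}.
#' @param grid_points Per-axis grid size for \code{"grid_EB"}.
#' @return Object of class \code{site_posteriors}: data.frame with per-site
#'   posterior and cutoff flags, plus the method used.
#' @export
site_posteriors <- function(alt_fit, aln, tree, method = c("NEB", "grid_EB"),
                            grid_points = 4) {
  method <- match.arg(method)
  stopifnot(inherits(alt_fit, "codon_fit"))
  if (!alt_fit$model_id %in% c("modelA", "modelA_null")) {
    stop("site posteriors are defined for model A fits")
  }
  tree <- alt_fit$tree
  np <- alt_fit$natural_params
  post_at <- function(model) {
    sl <- model_site_logliks(aln, tree, model)
    lw <- sweep(sl$logL, 2L, log(pmax(sl$props, 1e-300)), "+")
    m <- apply(lw, 1L, max)
    w <- exp(lw - m)
    tot <- rowSums(w)
    list(post = rowSums(w[, 3:4, drop = FALSE]) / tot, loglik = sl$loglik)
  }
  if (method == "NEB") {
    post <- post_at(alt_fit$model)$post
  } else {
    g <- seq(0.1, 0.9, length.out = grid_points)
    w2g <- c(1.5, 3, 6, 12)[seq_len(grid_points)]
    grid <- expand.grid(s = g, r = g, w2 = w2g)
    res <- lapply(seq_len(nrow(grid)), function(i) {
      m <- model_a(np[["kappa"]], grid$s[i] * grid$r[i],
                   grid$s[i] * (1 - grid$r[i]), np[["omega0"]],
                   grid$w2[i], alt_fit$foreground, alt_fit$model$freqs)
      post_at(m)
    })
    ll <- vapply(res, `[[`, numeric(1), "loglik")
    wts <- exp(ll - max(ll)); wts <- wts / sum(wts)
    post <- Reduce(`+`, Map(function(r, w) r$post * w, res, wts))
  }
  structure(
    list(table = data.frame(site = seq_along(post), posterior = post,
                            flag90 = post >= 0.90, flag95 = post >= 0.95),
         method = method),
    class = "site_posteriors")
}

#' @export
print.site_posteriors <- function(x, ...) {
  hits <- x$table[x$table$flag90, , drop = FALSE]
  cat("Positively selected site posteriors (", x$method, "): ",
      nrow(hits), " site(s) at cutoff 0.90\n", sep = "")
  if (nrow(hits)) print(hits, row.names = FALSE, digits = 3)
  invisible(x)
}
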