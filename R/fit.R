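# Bounded multi-start maximum-likelihood fitting of the codon site-class
# models. Proportions are optimised through logistic transforms
# (s = p0 + p1, r = p0 / (p0 + p1)), kappa and the clade-model omegas on the
# log scale, and model A's omega2 directly on its bounded interval [1, 999]
# so a boundary fit is visible as omega2 pinned at a bound. Branch lengths
# are estimated jointly only under M0; the site-class models keep them fixed
# at the tree's values (the package protocol is one M0 fit per dataset).

model_param_spec <- function(model_id, foreground = NULL, types = NULL) {
  lg <- function(x) log(x)
  switch(model_id,
    M0 = list(
      names = c("log_kappa", "log_omega"),
      lower = c(lg(0.05), lg(1e-4)), upper = c(lg(50), lg(999)),
      starts = list(c(2, 0.3), c(1.0, 0.05), c(4, 1.2)),
      encode = function(p) c(log(p[1]), log(p[2])),
      build = function(th, freqs) model_m0(exp(th[1]), exp(th[2]), freqs)),
    M1a = list(
      names = c("log_kappa", "logit_p0", "logit_omega0"),
      lower = c(lg(0.05), -12, -12), upper = c(lg(50), 12, 12),
      starts = list(c(2, 0.7, 0.1), c(1.2, 0.9, 0.3), c(4, 0.4, 0.02)),
      encode = function(p) c(log(p[1]), stats::qlogis(p[2]), stats::qlogis(p[3])),
      build = function(th, freqs) {
        model_m1a(exp(th[1]), stats::plogis(th[2]), stats::plogis(th[3]), freqs)
      }),
    modelA = list(
      names = c("log_kappa", "logit_s", "logit_r", "logit_omega0", "omega2"),
      lower = c(lg(0.05), -12, -12, -12, 1), upper = c(lg(50), 12, 12, 12, 999),
      starts = list(c(2, 0.9, 0.5, 0.1, 3), c(1.2, 0.7, 0.8, 0.3, 1.5),
                    c(4, 0.97, 0.3, 0.03, 15)),
      encode = function(p) c(log(p[1]), stats::qlogis(p[2]), stats::qlogis(p[3]),
                             stats::qlogis(p[4]), p[5]),
      build = function(th, freqs) {
        s <- stats::plogis(th[2]); r <- stats::plogis(th[3])
        model_a(exp(th[1]), s * r, s * (1 - r), stats::plogis(th[4]),
                th[5], foreground, freqs)
      }),
    modelA_null = list(
      names = c("log_kappa", "logit_s", "logit_r", "logit_omega0"),
      lower = c(lg(0.05), -12, -12, -12), upper = c(lg(50), 12, 12, 12),
      starts = list(c(2, 0.9, 0.5, 0.1), c(1.2, 0.7, 0.8, 0.3),
                    c(4, 0.97, 0.3, 0.03)),
      encode = function(p) c(log(p[1]), stats::qlogis(p[2]), stats::qlogis(p[3]),
                             stats::qlogis(p[4])),
      build = function(th, freqs) {
        s <- stats::plogis(th[2]); r <- stats::plogis(th[3])
        model_a_null(exp(th[1]), s * r, s * (1 - r), stats::plogis(th[4]),
                     foreground, freqs)
      }),
    cladeC_ext = {
      k <- length(types)
      list(
        names = c("log_kappa", "logit_s", "logit_r", "logit_omega0",
                  paste0("log_omega_", types)),
        lower = c(lg(0.05), -12, -12, -12, rep(lg(1e-4), k)),
        upper = c(lg(50), 12, 12, 12, rep(lg(999), k)),
        starts = list(c(2, 0.9, 0.5, 0.1, rep(1, k)),
                      c(1.2, 0.7, 0.8, 0.3, rep(0.4, k)),
                      c(4, 0.97, 0.3, 0.03, rep(4, k))),
        encode = function(p) c(log(p[1]), stats::qlogis(p[2]), stats::qlogis(p[3]),
                               stats::qlogis(p[4]), log(p[4 + seq_len(k)])),
        build = function(th, freqs) {
          s <- stats::plogis(th[2]); r <- stats::plogis(th[3])
          om <- stats::setNames(exp(th[4 + seq_len(k)]), types)
          model_cladec(exp(th[1]), s * r, s * (1 - r), stats::plogis(th[4]),
                       om, freqs)
        })
    },
    stop("unknown model id '", model_id, "'"))
}

#' Fit a codon site-class model by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) maximisation from several deterministic
#' starting points (jittered defaults; the best optimum is kept). Under M0
#' the branch lengths can be estimated jointly; all other models hold the
#' tree's branch lengths fixed, following the package protocol of estimating
#' lengths once under M0 per dataset and reusing them for every site-class
#' fit.
#'
#' @param aln A \code{codon_alignment}.
#' @param tree A \code{labeled_tree}; for \code{modelA}/\code{modelA_null} its
#'   edge types must contain the \code{foreground} type.
#' @param model_id One of \code{"M0"}, \code{"M1a"}, \code{"modelA"},
#'   \code{"modelA_null"}, \code{"cladeC_ext"}.
#' @param foreground Foreground branch-type name (model A variants).
#' @param freqs \code{"equal"} (default) or \code{"f3x4"}.
#' @param optimize_branch_lengths Estimate branch lengths jointly (M0 only).
#' @param n_starts Number of starting points used (1..3 defaults; additional
#'   warm starts may be supplied via \code{extra_starts}).
#' @param extra_starts Optional list of natural-parameter start vectors (same
#'   layout as the model's defaults) prepended to the start list.
#' @param control Passed to \code{stats::optim} (merged over package defaults).
#' @return Object of class \code{codon_fit}: the estimated
#'   \code{site_class_model}, \code{loglik}, \code{converged}, boundary flags,
#'   the tree (with estimated lengths for M0), and optimizer bookkeeping.
#' @export
fit_codon_model <- function(aln, tree, model_id, foreground = NULL,
                            freqs = c("equal", "f3x4"),
                            optimize_branch_lengths = identical(model_id, "M0"),
                            n_starts = 3, extra_starts = NULL,
                            control = list()) {
  freqs <- match.arg(freqs)
  model_id <- match.arg(model_id,
    c("M0", "M1a", "modelA", "modelA_null", "cladeC_ext"))
  if (model_id %in% c("modelA", "modelA_null")) {
    if (is.null(foreground)) stop("model A needs a foreground branch type")
    if (!foreground %in% tree$edge_types) {
      stop("no branch of type '", foreground, "' in the tree")
    }
  }
  if (optimize_branch_lengths && model_id != "M0") {
    stop("branch lengths are only optimized under M0")
  }
  types <- NULL
  if (model_id == "cladeC_ext") {
    types <- unique(c("background", setdiff(unique(tree$edge_types), "background")))
  }
  fvec <- if (freqs == "f3x4") f3x4_frequencies(aln) else NULL
  prep <- prepare_likelihood(aln, tree)
  spec <- model_param_spec(model_id, foreground, types)
  nedge <- nrow(prep$edge)
  lower <- spec$lower; upper <- spec$upper
  if (optimize_branch_lengths) {
    lower <- c(lower, rep(log(1e-6), nedge))
    upper <- c(upper, rep(log(20), nedge))
  }
  n_eval <- 0L
  npar0 <- length(spec$names)
  last <- NULL
  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    model <- spec$build(theta[seq_len(npar0)], fvec)
    lengths <- if (optimize_branch_lengths) exp(theta[-seq_len(npar0)])
      else prep$lengths
    logL <- class_pattern_logliks(prep, model, lengths)
    props <- vapply(model$classes, `[[`, numeric(1), "prop")
    ll <- mixture_loglik_from_patterns(logL, props, prep$weights)
    val <- if (!is.finite(ll)) 1e12 else -ll
    last <<- list(theta = theta, value = val)
    val
  }
  # forward-difference gradient reusing the objective value at the expansion
  # point (optim evaluates fn and gr back-to-back at the same theta)
  gradient <- function(theta) {
    f0 <- if (!is.null(last) && identical(theta, last$theta)) last$value
      else objective(theta)
    g <- numeric(length(theta))
    h <- 1e-6 * pmax(abs(theta), 1)
    for (i in seq_along(theta)) {
      step <- if (theta[i] + h[i] <= upper[i]) h[i] else -h[i]
      th <- theta; th[i] <- th[i] + step
      g[i] <- (objective(th) - f0) / step
    }
    last <<- list(theta = theta, value = f0)
    g
  }
  starts <- lapply(spec$starts[seq_len(min(n_starts, length(spec$starts)))],
                   spec$encode)
  if (!is.null(extra_starts)) {
    starts <- c(lapply(extra_starts, spec$encode), starts)
  }
  bl_start <- log(pmax(prep$lengths, 1e-4))
  ctrl <- utils::modifyList(list(maxit = 300, factr = 1e9), control)
  # staged multi-start: short exploratory runs rank the starting points,
  # the winner is run to convergence and then polished at a tighter
  # tolerance so the reported optimum is stable under refitting
  stage1 <- lapply(starts, function(st) {
    th0 <- pmin(pmax(if (optimize_branch_lengths) c(st, bl_start) else st,
                     lower), upper)
    if (length(starts) == 1L) return(list(par = th0, value = objective(th0)))
    stats::optim(th0, objective, gr = gradient, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = utils::modifyList(ctrl, list(maxit = 8, factr = 1e10)))
  })
  winner <- stage1[[which.min(vapply(stage1, `[[`, numeric(1), "value"))]]
  best <- stats::optim(winner$par, objective, gr = gradient,
                       method = "L-BFGS-B", lower = lower, upper = upper,
                       control = ctrl)
  polish <- stats::optim(best$par, objective, gr = gradient,
                         method = "L-BFGS-B", lower = lower, upper = upper,
                         control = utils::modifyList(ctrl, list(factr = 1e6)))
  if (polish$value <= best$value) {
    polish$convergence <- min(polish$convergence, best$convergence)
    best <- polish
  }
  theta <- best$par
  model <- spec$build(theta[seq_len(npar0)], fvec)
  out_tree <- tree
  if (optimize_branch_lengths) {
    est <- exp(theta[-seq_len(npar0)])
    out_tree$phylo$edge.length[prep$perm] <- est
  }
  boundary <- character(0)
  if (model_id == "modelA") {
    w2 <- theta[5L]
    if (w2 >= 0.995 * 999) boundary <- c(boundary, "omega2_upper")
    if (w2 <= 1 + 1e-5) boundary <- c(boundary, "omega2_lower")
  }
  if (nrow(unique(aln$codons)) == 1L) boundary <- c(boundary, "flat_likelihood")
  structure(
    list(model_id = model_id, model = model, loglik = -best$value,
         converged = best$convergence == 0, n_starts = length(starts),
         boundary = boundary, tree = out_tree, foreground = foreground,
         theta = theta, n_eval = n_eval,
         natural_params = fit_natural_params(model_id, theta, types)),
    class = "codon_fit")
}

fit_natural_params <- function(model_id, theta, types = NULL) {
  switch(model_id,
    M0 = c(kappa = exp(theta[1]), omega = exp(theta[2])),
    M1a = c(kappa = exp(theta[1]), p0 = stats::plogis(theta[2]),
            omega0 = stats::plogis(theta[3])),
    modelA = ,
    modelA_null = {
      s <- stats::plogis(theta[2]); r <- stats::plogis(theta[3])
      out <- c(kappa = exp(theta[1]), p0 = s * r, p1 = s * (1 - r),
               omega0 = stats::plogis(theta[4]))
      if (model_id == "modelA") out["omega2"] <- theta[5]
      out
    },
    cladeC_ext = {
      s <- stats::plogis(theta[2]); r <- stats::plogis(theta[3])
      k <- length(types)
      c(kappa = exp(theta[1]), p0 = s * r, p1 = s * (1 - r),
        omega0 = stats::plogis(theta[4]),
        stats::setNames(exp(theta[4 + seq_len(k)]), paste0("omega_", types)))
    })
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("Codon model fit:", x$model_id,
      if (!is.null(x$foreground)) paste0("(foreground ", x$foreground, ")"),
      "\n  log-likelihood:", format(x$loglik, digits = 10),
      if (!x$converged) "[NOT CONVERGED]", "\n")
  est <- x$natural_params
  if (!is.null(est["omega2"]) && !is.na(est["omega2"]) &&
      "omega2_upper" %in% x$boundary) {
    cat("  omega2 at upper bound: reported as unbounded (>= 999)\n")
  }
  cat("  estimates:", paste(names(est), signif(est, 5), sep = "=",
                            collapse = ", "), "\n")
  if (length(x$boundary)) cat("  boundary flags:",
                              paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate branch lengths under M0
#'
#' Fits the one-ratio M0 model with branch lengths free, and returns the tree
#' with the estimated lengths installed; all subsequent site-class fits on
#' the dataset hold these lengths fixed.
#'
#' @inheritParams fit_codon_model
#' @param ... Passed to \code{\link{fit_codon_model}}.
#' @return List with \code{tree} (updated \code{labeled_tree}) and \code{fit}
#'   (the M0 \code{codon_fit}).
#' @export
estimate_branch_lengths <- function(aln, tree, ...) {
  fit <- fit_codon_model(aln, tree, "M0", optimize_branch_lengths = TRUE, ...)
  list(tree = fit$tree, fit = fit)
}
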