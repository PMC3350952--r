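#' Goldman-Yang style codon substitution process
#'
#' One Markov process over the 61 sense codons, parameterised by the
#' transition/transversion rate ratio kappa, the nonsynonymous/synonymous
#' rate ratio omega (dN/dS), and the stationary codon frequencies. Off-diagonal
#' rates are zero for multi-nucleotide changes and otherwise
#' \eqn{\pi_j}, \eqn{\kappa\pi_j}, \eqn{\omega\pi_j}, \eqn{\omega\kappa\pi_j}
#' for synonymous transversions/transitions and nonsynonymous
#' transversions/transitions. The generator is scaled so the expected number
#' of substitutions per codon per unit time equals one, making branch lengths
#' comparable across site classes.
#'
#' When several site classes share branch lengths (the mixture models), the
#' classes must not be rescaled independently — a positively selected class
#' evolves faster, which is most of the branch-site signal. The mixture
#' machinery therefore builds unscaled processes (\code{scale = FALSE}) and
#' divides branch lengths by the mixture-average raw rate of the branch's
#' type, so a branch length is the expected number of substitutions per codon
#' averaged over site classes while classes keep their relative rates.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega dN/dS ratio, > 0.
#' @param freqs 61 stationary codon frequencies summing to 1 (default equal).
#' @param code A \code{genetic_code}.
#' @param scale If \code{TRUE} (default) the generator is scaled to unit mean
#'   rate; if \code{FALSE} it is left raw and the raw mean rate is reported
#'   in field \code{mu} for external (mixture-level) scaling.
#' @return Object of class \code{codon_process} with the generator \code{Q},
#'   its raw mean rate \code{mu}, and a cached symmetric eigendecomposition
#'   used by \code{\link{transition_probs}}.
#' @export
codon_process <- function(kappa, omega, freqs = NULL, code = default_code(),
                          scale = TRUE) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(omega) || omega <= 0) stop("omega must be > 0")
  n <- length(code$sense)
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  if (length(freqs) != n || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8) {
    stop("freqs must be ", n, " positive values summing to 1")
  }
  cls <- codon_pair_classes(code)
  fac <- matrix(0, n, n)
  fac[cls == 1L] <- 1
  fac[cls == 2L] <- kappa
  fac[cls == 3L] <- omega
  fac[cls == 4L] <- omega * kappa
  Q <- fac * rep(freqs, each = n)     # q_ij = fac_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  if (scale) Q <- Q / mu
  # Reversible: symmetrise with pi^(1/2) for a stable eigendecomposition.
  sp <- sqrt(freqs)
  S <- Q * (sp / rep(sp, each = n))   # S_ij = sqrt(pi_i/pi_j) q_ij... see below
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  U <- e$vectors / sp                 # rows scaled by 1/sqrt(pi_i)
  Uinv <- t(e$vectors * sp)           # columns scaled by sqrt(pi_j), transposed
  structure(
    list(kappa = kappa, omega = omega, freqs = freqs, Q = Q, mu = mu,
         scaled = scale, eigenvalues = e$values, U = U, Uinv = Uinv),
    class = "codon_process"
  )
}

#' Extract the scaled rate matrix
#'
#' @param process A \code{codon_process}.
#' @return The 61 x 61 generator matrix (rows sum to zero, unit mean rate).
#' @export
rate_matrix <- function(process) {
  stopifnot(inherits(process, "codon_process"))
  process$Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the cached eigendecomposition of the reversible generator;
#' tiny negative entries from round-off are clamped to zero.
#'
#' @param process A \code{codon_process}.
#' @param t Branch length (expected substitutions per codon), >= 0.
#' @return 61 x 61 stochastic matrix.
#' @export
transition_probs <- function(process, t) {
  stopifnot(inherits(process, "codon_process"), t >= 0)
  if (t == 0) return(diag(length(process$freqs)))
  P <- process$U %*% (exp(process$eigenvalues * t) * process$Uinv)
  P[P < 0] <- 0
  P
}

# Constants (s_tv, s_ts, n_tv, n_ts) such that the raw mean rate of the
# process is mu = s_tv + kappa*s_ts + omega*(n_tv + kappa*n_ts); used to
# compute mixture-level scale factors without building full generators.
codon_rate_constants <- function(freqs, code = default_code()) {
  cls <- codon_pair_classes(code)
  pp <- freqs %o% freqs
  c(s_tv = sum(pp[cls == 1L]), s_ts = sum(pp[cls == 2L]),
    n_tv = sum(pp[cls == 3L]), n_ts = sum(pp[cls == 4L]))
}

# Mixture-average raw substitution rate for each edge, given a site-class
# model and the edge branch types: the common codeml-style scale factor that
# turns branch lengths into expected substitutions per codon per branch.
mixture_edge_scales <- function(model, types, code = default_code()) {
  nstate <- length(code$sense)
  freqs <- if (is.null(model$freqs)) rep(1 / nstate, nstate) else model$freqs
  rc <- codon_rate_constants(freqs, code)
  mu_of <- function(om) {
    rc[["s_tv"]] + model$kappa * rc[["s_ts"]] +
      om * (rc[["n_tv"]] + model$kappa * rc[["n_ts"]])
  }
  props <- vapply(model$classes, `[[`, numeric(1), "prop")
  vapply(types, function(tp) {
    sum(props * vapply(model$classes, function(cl) {
      mu_of(omega_for_types(cl$omega, tp))
    }, numeric(1)))
  }, numeric(1))
}

#' Empirical F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies multiplied across the three codon
#' positions and renormalised over the sense codons.
#'
#' @param aln A \code{codon_alignment}.
#' @param code A \code{genetic_code}.
#' @return Vector of 61 codon frequencies.
#' @export
f3x4_frequencies <- function(aln, code = default_code()) {
  codons <- code$sense[aln$codons]
  mat <- do.call(rbind, strsplit(codons, ""))
  nt <- c("A", "C", "G", "T")
  posfreq <- sapply(1:3, function(p) {
    tab <- table(factor(mat[, p], levels = nt))
    as.numeric(tab) / sum(tab)
  })
  rownames(posfreq) <- nt
  sm <- do.call(rbind, strsplit(code$sense, ""))
  f <- posfreq[cbind(sm[, 1], 1)] * posfreq[cbind(sm[, 2], 2)] *
    posfreq[cbind(sm[, 3], 3)]
  f <- pmax(f, 1e-8)
  f / sum(f)
}
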