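#' Codon site-class models
#'
#' Parameter bundles for the site/branch-site model family used by the
#' selection tests:
#' \describe{
#'   \item{M0}{one ratio: a single omega for all sites and branches.}
#'   \item{M1a}{nearly neutral: proportion p0 of sites with 0 < omega0 < 1,
#'     the rest neutral (omega = 1).}
#'   \item{modelA}{branch-site model A: classes 0 (omega0 everywhere),
#'     1 (neutral everywhere), 2a (omega0 on background, omega2 on the
#'     foreground branch type) and 2b (neutral on background, omega2 on
#'     foreground), with p2a = (1-p0-p1) p0/(p0+p1) and
#'     p2b = (1-p0-p1) p1/(p0+p1); omega2 >= 1.}
#'   \item{modelA_null}{model A with omega2 fixed at 1.}
#'   \item{cladeC_ext}{extended clade model C: classes 0 (omega0), 1 (neutral)
#'     and a divergent class 2 whose omega differs freely between branch
#'     types, including the background.}
#' }
#'
#' Each constructor returns an object of class \code{site_class_model}: a list
#' with \code{model_id}, \code{kappa}, \code{freqs} and \code{classes}, where
#' every class carries its proportion and a named omega map (entry
#' \code{"background"} plus optional per-branch-type entries).
#'
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega,omega0,omega2 dN/dS parameters; \code{omega0} must lie in
#'   (0, 1), \code{omega2 >= 1} for model A.
#' @param p0,p1 Site-class proportions (see above).
#' @param foreground Branch-type name carrying omega2 in model A.
#' @param omega_map Named vector of class-2 omegas for \code{cladeC_ext};
#'   must include \code{"background"}.
#' @param freqs 61 codon frequencies (default equal).
#' @name site_class_model
NULL

new_site_class_model <- function(model_id, kappa, freqs, classes, fixed = character(0)) {
  if (kappa <= 0) stop("kappa must be > 0")
  props <- vapply(classes, `[[`, numeric(1), "prop")
  if (any(props < -1e-12)) stop("class proportions must be nonnegative")
  if (abs(sum(props) - 1) > 1e-8) stop("class proportions must sum to 1")
  for (cl in classes) {
    if (any(cl$omega <= 0)) stop("all omega values must be > 0")
    if (!"background" %in% names(cl$omega)) stop("omega map needs a 'background' entry")
  }
  structure(list(model_id = model_id, kappa = kappa, freqs = freqs,
                 classes = classes, fixed = fixed),
            class = "site_class_model")
}

#' @rdname site_class_model
#' @export
model_m0 <- function(kappa, omega, freqs = NULL) {
  new_site_class_model("M0", kappa, freqs,
    list(list(prop = 1, omega = c(background = omega))))
}

#' @rdname site_class_model
#' @export
model_m1a <- function(kappa, p0, omega0, freqs = NULL) {
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (omega0 <= 0 || omega0 >= 1) stop("omega0 must lie in (0, 1)")
  new_site_class_model("M1a", kappa, freqs, list(
    list(prop = p0, omega = c(background = omega0)),
    list(prop = 1 - p0, omega = c(background = 1))))
}

#' @rdname site_class_model
#' @export
model_a <- function(kappa, p0, p1, omega0, omega2, foreground, freqs = NULL,
                    null = FALSE) {
  if (p0 < 0 || p1 < 0 || p0 + p1 > 1 + 1e-12) {
    stop("need p0, p1 >= 0 with p0 + p1 <= 1")
  }
  if (p0 + p1 < 1e-12) stop("p0 + p1 must be positive in model A")
  if (omega0 <= 0 || omega0 >= 1) stop("omega0 must lie in (0, 1)")
  if (omega2 < 1) stop("model A requires omega2 >= 1")
  if (null && omega2 != 1) stop("the model A null fixes omega2 = 1")
  p2 <- max(0, 1 - p0 - p1)
  p2a <- p2 * p0 / (p0 + p1)
  p2b <- p2 * p1 / (p0 + p1)
  fg2a <- c(background = omega0); fg2a[foreground] <- omega2
  fg2b <- c(background = 1); fg2b[foreground] <- omega2
  new_site_class_model(if (null) "modelA_null" else "modelA", kappa, freqs, list(
    list(prop = p0, omega = c(background = omega0)),
    list(prop = p1, omega = c(background = 1)),
    list(prop = p2a, omega = fg2a),
    list(prop = p2b, omega = fg2b)),
    fixed = if (null) "omega2" else character(0))
}

#' @rdname site_class_model
#' @export
model_a_null <- function(kappa, p0, p1, omega0, foreground, freqs = NULL) {
  model_a(kappa, p0, p1, omega0, 1, foreground, freqs, null = TRUE)
}

#' @rdname site_class_model
#' @export
model_cladec <- function(kappa, p0, p1, omega0, omega_map, freqs = NULL) {
  if (p0 < 0 || p1 < 0 || p0 + p1 > 1 + 1e-12) {
    stop("need p0, p1 >= 0 with p0 + p1 <= 1")
  }
  if (omega0 <= 0 || omega0 >= 1) stop("omega0 must lie in (0, 1)")
  if (!"background" %in% names(omega_map)) {
    stop("omega_map must include a 'background' omega")
  }
  new_site_class_model("cladeC_ext", kappa, freqs, list(
    list(prop = p0, omega = c(background = omega0)),
    list(prop = p1, omega = c(background = 1)),
    list(prop = 1 - p0 - p1, omega = omega_map)))
}

#' Number of free parameters of a site-class model
#'
#' Counts kappa plus the free parameters of the omega distribution (class
#' proportions and omega values, minus any fixed by the model definition).
#' Branch lengths and codon frequencies are not counted. The difference
#' between two nested models is the LRT degrees of freedom; for the extended
#' clade model C with one foreground branch type versus M1a it equals 3.
#'
#' @param model A \code{site_class_model} (or a model_id string plus
#'   \code{n_types} for the clade model).
#' @param n_types For \code{model_id = "cladeC_ext"} given as a string: the
#'   number of branch types including background.
#' @return Integer count of free parameters.
#' @examples
#' n_free_params("cladeC_ext", n_types = 2) - n_free_params("M1a")  # 3
#' @export
n_free_params <- function(model, n_types = NULL) {
  id <- if (inherits(model, "site_class_model")) model$model_id else model
  if (id == "cladeC_ext" && is.null(n_types)) {
    n_types <- length(model$classes[[3]]$omega)
  }
  switch(id,
    M0 = 2L,                       # kappa, omega
    M1a = 3L,                      # kappa, p0, omega0
    modelA = 5L,                   # kappa, p0, p1, omega0, omega2
    modelA_null = 4L,
    cladeC_ext = 4L + as.integer(n_types),  # kappa, p0, p1, omega0, omega per type
    stop("unknown model id '", id, "'"))
}

#' @export
print.site_class_model <- function(x, ...) {
  cat("Codon site-class model", x$model_id, " kappa =", signif(x$kappa, 4), "\n")
  for (i in seq_along(x$classes)) {
    cl <- x$classes[[i]]
    cat(sprintf("  class %d: p = %.4f, omega = %s\n", i - 1L, cl$prop,
                paste(names(cl$omega), signif(cl$omega, 4),
                      sep = ":", collapse = ", ")))
  }
  invisible(x)
}
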