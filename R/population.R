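#' Convert a coefficient of variation (%) to a lognormal log-scale SD
#'
#' Inter-individual variability of a lognormally distributed parameter is
#' conventionally reported as a coefficient of variation in percent. For a
#' parameter theta_i = theta_pop * exp(eta) with eta ~ N(0, omega^2), the
#' exact relation is CV = 100 * sqrt(exp(omega^2) - 1). This function inverts
#' that relation; [omega_to_cv()] is its inverse.
#'
#' @param cv_percent coefficient of variation in percent, >= 0.
#' @return omega, the SD of the log-scale random effect.
#' @export
cv_to_omega <- function(cv_percent) {
  if (any(cv_percent < 0)) stop("cv_percent must be non-negative")
  sqrt(log(1 + (cv_percent / 100)^2))
}

#' @rdname cv_to_omega
#' @param omega log-scale SD, >= 0.
#' @export
omega_to_cv <- function(omega) {
  if (any(omega < 0)) stop("omega must be non-negative")
  100 * sqrt(exp(omega^2) - 1)
}

#' Hierarchical population model specification
#'
#' Bundles the fixed effects, lognormal inter-individual variability (IIV),
#' random-effect correlations, residual-error models and covariate links that
#' define one population PK/PD model. IIV is exponential:
#' theta_i = theta_pop * exp(eta_i), eta ~ N(0, Omega). Continuous covariates
#' enter as power links theta_i = theta_pop * (cov/ref)^beta, categorical
#' covariates exponentially, theta_i = theta_pop * exp(beta * I\[category\]).
#'
#' @param fixed named numeric vector of fixed-effect (population) values.
#' @param iiv named numeric vector of log-scale SDs (omega); parameters not
#'   named here carry no random effect.
#' @param correlations list of length-3 lists/vectors `(par1, par2, r)` giving
#'   off-diagonal random-effect correlations.
#' @param error list of residual-error models keyed by observation stream
#'   (`"pk"`, `"pd"`); each a named vector with `b` (proportional) and
#'   optionally `a` (additive), giving sd = a + b*f.
#' @param covariate_links list of lists with elements `param`, `covariate`,
#'   `form` (`"power_scaled"` or `"exponential_categorical"`), `beta`, `ref`.
#' @param error_form `"combined1"` (sd = a + b*f, the default) or
#'   `"combined2"` (sd = sqrt(a^2 + (b*f)^2)).
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(fixed, iiv = numeric(0), correlations = list(),
                            error = list(), covariate_links = list(),
                            error_form = c("combined1", "combined2")) {
  error_form <- match.arg(error_form)
  stopifnot(is.numeric(fixed), !is.null(names(fixed)))
  if (any(!is.finite(fixed))) stop("non-finite fixed effect")
  if (length(iiv)) {
    stopifnot(!is.null(names(iiv)))
    if (any(iiv < 0)) stop("omega must be >= 0")
    if (!all(names(iiv) %in% names(fixed)))
      stop("iiv names must be a subset of fixed-effect names")
  }
  for (co in correlations) {
    if (length(co) != 3) stop("each correlation entry is (par1, par2, r)")
    r <- as.numeric(co[[3]])
    if (abs(r) >= 1) stop("|r| must be < 1")
    if (!all(c(co[[1]], co[[2]]) %in% names(iiv)))
      stop("correlated parameters must both have IIV")
  }
  for (em in error) {
    if (any(em < 0)) stop("error coefficients must be >= 0")
  }
  spec <- structure(list(fixed = fixed, iiv = iiv, correlations = correlations,
                         error = error, covariate_links = covariate_links,
                         error_form = error_form),
                    class = "population_spec")
  # fail loudly on a non-positive-definite implied covariance
  if (length(iiv)) omega_matrix(spec)
  spec
}

#' Assemble the random-effect covariance matrix of a population spec
#'
#' @param spec a [population_spec()].
#' @return the Omega matrix (named, one row/col per parameter with IIV).
#'   Errors if the implied matrix is not positive definite.
#' @export
omega_matrix <- function(spec) {
  nm <- names(spec$iiv)
  q <- length(nm)
  R <- diag(1, q)
  dimnames(R) <- list(nm, nm)
  for (co in spec$correlations) {
    R[co[[1]], co[[2]]] <- R[co[[2]], co[[1]]] <- as.numeric(co[[3]])
  }
  Om <- diag(spec$iiv, q) %*% R %*% diag(spec$iiv, q)
  dimnames(Om) <- list(nm, nm)
  active <- spec$iiv > 0
  if (any(active)) {
    ev <- eigen(Om[active, active, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("implied random-effect covariance matrix is not positive definite")
  }
  Om
}

#' Realise individual parameters from population values, random effects and
#' covariates
#'
#' @param spec a [population_spec()].
#' @param eta named numeric vector of random effects (names must match the
#'   IIV parameters; parameters without IIV implicitly get eta = 0).
#' @param covariates named list/vector of subject covariates; required when
#'   the spec carries covariate links.
#' @return named numeric vector of realised (positive) individual parameters.
#' @export
realise_individual <- function(spec, eta = NULL, covariates = NULL) {
  theta <- spec$fixed
  if (length(spec$iiv)) {
    e <- setNames(numeric(length(spec$iiv)), names(spec$iiv))
    if (!is.null(eta)) {
      if (is.null(names(eta)) && length(eta) == length(e)) names(eta) <- names(e)
      bad <- setdiff(names(eta), names(e))
      if (length(bad)) stop("eta given for parameter(s) without IIV: ",
                            paste(bad, collapse = ", "))
      e[names(eta)] <- eta
    }
    theta[names(e)] <- theta[names(e)] * exp(e)
  }
  for (lk in spec$covariate_links) {
    cv <- covariates[[lk$covariate]]
    if (is.null(cv) || (is.numeric(cv) && is.na(cv)))
      stop("covariate '", lk$covariate, "' required by a link is missing")
    fac <- switch(lk$form,
      power_scaled = (as.numeric(cv) / lk$ref)^lk$beta,
      exponential_categorical = exp(lk$beta * as.numeric(as.numeric(cv) != lk$ref)),
      stop("unknown covariate link form: ", lk$form))
    theta[lk$param] <- theta[lk$param] * fac
  }
  theta
}

#' Draw correlated random-effect vectors
#'
#' @param spec a [population_spec()].
#' @param n number of subjects.
#' @return an n x q matrix of eta draws (columns named by parameter).
#' @export
draw_etas <- function(spec, n) {
  Om <- omega_matrix(spec)
  q <- ncol(Om)
  if (q == 0) return(matrix(0, n, 0))
  E <- MASS::mvrnorm(n, mu = rep(0, q), Sigma = Om)
  if (n == 1) E <- matrix(E, 1)
  colnames(E) <- colnames(Om)
  E
}

#' Residual-error standard deviation
#'
#' @param f model predictions.
#' @param coefs named vector with `b` and optionally `a`.
#' @param form `"combined1"` (a + b*f) or `"combined2"` (sqrt(a^2 + (b f)^2)).
#' @return vector of standard deviations.
#' @export
error_sd <- function(f, coefs, form = "combined1") {
  a <- if ("a" %in% names(coefs)) coefs[["a"]] else 0
  b <- if ("b" %in% names(coefs)) coefs[["b"]] else 0
  if (form == "combined2") sqrt(a^2 + (b * f)^2) else a + b * f
}

#' Log-likelihood contribution of one or more observations
#'
#' Uncensored observations contribute a Gaussian log-density with mean equal
#' to the model prediction and an sd from the residual-error model. Interval-
#' censored (below-quantification-limit) observations contribute the
#' unconditional interval probability log\[Phi((upper-f)/sd) - Phi((lower-f)/sd)\]
#' with lower bound 0 and upper bound the LLOQ, matching the M4-style
#' treatment of censored concentrations.
#'
#' @param y observed values (for censored rows, the recorded LLOQ; ignored in
#'   the censored branch except through `upper`).
#' @param f model predictions (finite).
#' @param coefs residual-error coefficients (named `a`, `b`).
#' @param cens 0/1 censoring indicator.
#' @param lower,upper interval bounds for censored rows (defaults 0 and `y`).
#' @param form error-model form, see [error_sd()].
#' @return vector of log-likelihood contributions.
#' @export
observation_loglik <- function(y, f, coefs, cens = 0, lower = 0, upper = y,
                               form = "combined1") {
  n <- max(length(y), length(f))
  y <- rep_len(y, n)
  f <- rep_len(f, n)
  sd <- error_sd(f, coefs, form)
  if (any(sd <= 0)) stop("residual sd must be > 0 (check error coefficients)")
  cens <- rep_len(cens, n)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  ll <- numeric(length(y))
  unc <- cens == 0
  if (any(unc)) ll[unc] <- dnorm(y[unc], f[unc], sd[unc], log = TRUE)
  if (any(!unc)) {
    if (any(upper[!unc] <= 0)) stop("censoring bound (LLOQ) must be > 0")
    p <- pnorm(upper[!unc], f[!unc], sd[!unc]) - pnorm(lower[!unc], f[!unc], sd[!unc])
    ll[!unc] <- log(pmax(p, 1e-300))
  }
  ll
}

#' Write / read a population spec as a YAML config
#'
#' @param spec a [population_spec()].
#' @param path file path.
#' @export
write_population_spec <- function(spec, path) {
  obj <- list(
    fixed = as.list(spec$fixed),
    iiv_cv_percent = as.list(setNames(omega_to_cv(spec$iiv), names(spec$iiv))),
    correlations = lapply(spec$correlations, function(co)
      list(par1 = co[[1]], par2 = co[[2]], r = as.numeric(co[[3]]))),
    error = lapply(spec$error, as.list),
    covariate_links = spec$covariate_links,
    error_form = spec$error_form)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_population_spec
#' @return `read_population_spec()` returns a [population_spec()].
#' @export
read_population_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  iiv <- unlist(obj$iiv_cv_percent)
  population_spec(
    fixed = unlist(obj$fixed),
    iiv = if (length(iiv)) cv_to_omega(iiv) else numeric(0),
    correlations = lapply(obj$correlations, function(co)
      list(co$par1, co$par2, co$r)),
    error = lapply(obj$error, unlist),
    covariate_links = obj$covariate_links %||% list(),
    error_form = obj$error_form %||% "combined1")
}
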