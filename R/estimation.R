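# Population maximum-likelihood estimation: SAEM with MCMC kernels on the
# individual parameters for the general case, adaptive/fixed Gauss-Hermite
# quadrature for one-dimensional random effects, and direct ML when no
# parameter carries inter-individual variability.

#' Estimation settings
#'
#' @param n_explore,n_smooth SAEM iteration counts for the exploratory
#'   (step size 1, simulated-annealing variance floors active) and smoothing
#'   (decreasing step size) phases.
#' @param mcmc_ind,mcmc_rw numbers of independence-kernel and random-walk
#'   transitions of the individual-parameter Markov kernel per iteration.
#' @param cw_every run the componentwise random-walk kernel every this many
#'   iterations.
#' @param art_v0,art_floor initial and final artificial log-scale variance
#'   given to parameters without IIV during the exploratory phase, so that
#'   they are explored by the same Markov kernel and collapse onto point
#'   estimates as the variance decays geometrically. `art_v0` may be a named
#'   vector to widen or narrow the exploration of individual parameters
#'   (e.g. wide for parameters starting far from plausible values, narrow
#'   for parameters pre-estimated in an earlier stage).
#' @param annealing variance-decrease floor per exploratory iteration
#'   (simulated annealing); 0.95 means estimated variances may shrink by at
#'   most 5\% per iteration while the chain still explores.
#' @param nmc_ofv importance-sampling size per subject for the objective
#'   function value (-2 log marginal likelihood).
#' @param seed integer seed; identical (data, settings, seed) give an
#'   identical fit.
#' @param compute_ofv,compute_ebe switch off the post-fit OFV / empirical
#'   Bayes steps when only population estimates are needed.
#' @return a `fit_settings` list.
#' @export
fit_settings <- function(n_explore = 200, n_smooth = 100,
                         mcmc_ind = 1, mcmc_rw = 2, cw_every = 2,
                         art_v0 = 0.15, art_floor = 1e-5,
                         annealing = 0.95, nmc_ofv = 300, seed = 1,
                         compute_ofv = TRUE, compute_ebe = TRUE) {
  stopifnot(n_explore > 0, n_smooth > 0, annealing > 0, annealing <= 1)
  structure(as.list(environment()), class = "fit_settings")
}

# ---- data preparation -------------------------------------------------------

# Streams fitted per model kind.
.fit_dvids <- function(model) switch(model$kind, pk = 1, pd_obsconc = 2, c(1, 2))

.prep_subjects <- function(ds, model) {
  ids <- unique(ds$events$ID[ds$events$EVID == 0])
  lapply(ids, function(id) {
    sr <- subject_record(ds, id)
    obs <- sr$observations
    keep <- obs$DVID %in% .fit_dvids(model)
    o <- obs[keep, c("TIME", "DVID", "DV", "CENS", "LIMIT")]
    conc_input <- NULL
    if (model$kind == "pd_obsconc") {
      o <- o[o$DVID == 2, ]
      pk <- obs[obs$DVID == 1, ]
      idx <- match(o$TIME, pk$TIME)
      if (anyNA(idx))
        stop("subject ", id, ": ratio observation without a simultaneous ",
             "enalaprilat measurement")
      conc_input <- pk$DV[idx]
    }
    # per-stream precomputation for the likelihood hot path
    pre <- lapply(c(pk = 1, pd = 2), function(dvid) {
      k <- which(o$DVID == dvid)
      list(idx = k, y = o$DV[k], cens = o$CENS[k] == 1,
           lo = ifelse(is.na(o$LIMIT[k]), 0, o$LIMIT[k]))
    })
    list(id = id, obs = o, doses = sr$doses, covariates = sr$covariates,
         conc_input = conc_input, pre = pre)
  })
}

# Observation log-likelihood from cached predictions (proposal-safe: returns
# -Inf rather than erroring on degenerate predictions). Uses the per-stream
# precomputation attached by .prep_subjects.
.obs_ll <- function(sub, f, error, error_form) {
  if (is.null(f) || any(!is.finite(f))) return(-Inf)
  ll <- 0
  for (s in names(error)) {
    e <- sub$pre[[s]]
    if (!length(e$idx)) next
    coefs <- error[[s]]
    a <- coefs["a"]; if (is.na(a)) a <- 0
    b <- coefs["b"]; if (is.na(b)) b <- 0
    fi <- f[e$idx]
    sd <- if (error_form == "combined2") sqrt(a * a + (b * fi)^2) else a + b * fi
    if (any(sd <= 0)) return(-Inf)
    unc <- !e$cens
    if (any(unc)) {
      z <- (e$y[unc] - fi[unc]) / sd[unc]
      ll <- ll + sum(-0.918938533204673 - log(sd[unc]) - 0.5 * z * z)
    }
    if (any(e$cens)) {
      pr <- pnorm(e$y[e$cens], fi[e$cens], sd[e$cens]) -
        pnorm(e$lo[e$cens], fi[e$cens], sd[e$cens])
      ll <- ll + sum(log(pmax(pr, 1e-300)))
    }
  }
  if (!is.finite(ll)) -Inf else ll
}

# Observation log-likelihood of one subject given a full parameter vector.
.subj_ll <- function(model, sub, th, error, error_form) {
  f <- tryCatch(
    .predict_obs(model, th, sub$doses, sub$obs$TIME, sub$obs$DVID, sub$conc_input),
    error = function(e) NULL)
  if (is.null(f)) return(-Inf)
  .obs_ll(sub, f, error, error_form)
}

# ---- importance-sampling machinery ------------------------------------------

# log density of multivariate normal rows given a Cholesky factor
.dmvn_log_rows <- function(X, center, cholS) {
  D <- sweep(X, 2, center, `-`)
  -0.5 * colSums(backsolve(cholS, t(D), transpose = TRUE)^2) -
    sum(log(diag(cholS))) - (ncol(X) / 2) * log(2 * pi)
}

# Laplace covariance of one subject's random-effect posterior at a mode:
# numerical Hessian of the negative log posterior, eigenvalue-clipped to
# positive definiteness. Returns its Cholesky factor (covariance scale).
.laplace_chol <- function(negpost, mode, q, fallback) {
  h <- 1e-3
  H <- matrix(0, q, q)
  f0 <- negpost(mode)
  fp <- numeric(q); fm <- numeric(q)
  for (a in seq_len(q)) {
    ea <- replace(numeric(q), a, h)
    fp[a] <- negpost(mode + ea); fm[a] <- negpost(mode - ea)
    H[a, a] <- (fp[a] - 2 * f0 + fm[a]) / h^2
  }
  if (q > 1) {
    for (a in 1:(q - 1)) for (b in (a + 1):q) {
      ea <- replace(numeric(q), a, h); eb <- replace(numeric(q), b, h)
      H[a, b] <- H[b, a] <-
        (negpost(mode + ea + eb) - fp[a] - fp[b] + 2 * f0 -
           negpost(mode - ea - eb) + fm[a] + fm[b]) / (2 * h^2)
    }
  }
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  if (any(!is.finite(ev$values)) || max(ev$values) <= 0) return(fallback)
  lam <- pmax(ev$values, max(ev$values) * 1e-4)
  Sig <- ev$vectors %*% diag(1 / lam, q) %*% t(ev$vectors)
  ch <- tryCatch(chol((Sig + t(Sig)) / 2), error = function(e) NULL)
  if (is.null(ch)) fallback else ch
}

# log density of multivariate t rows (df degrees of freedom, Cholesky scale)
.dmvt_log_rows <- function(X, center, cholS, df) {
  q <- ncol(X)
  D <- sweep(X, 2, center, `-`)
  z2 <- colSums(backsolve(cholS, t(D), transpose = TRUE)^2)
  lgamma((df + q) / 2) - lgamma(df / 2) - (q / 2) * log(df * pi) -
    sum(log(diag(cholS))) - (df + q) / 2 * log1p(z2 / df)
}

# Defensive-mixture importance draws around a posterior mode: 85% from a
# heavy-tailed (t, 4 df) version of the inflated Laplace approximation, 15%
# from the population prior. Heavy tails keep the importance weights bounded
# when the Gaussian approximation understates the posterior spread.
.is_draws <- function(nmc, mode, cholPost, mean_prior, cholOm, df = 4) {
  q <- length(mode)
  comp <- runif(nmc) < 0.85
  Z <- matrix(rnorm(nmc * q), nmc, q)
  u <- sqrt(df / rchisq(nmc, df))
  PHI <- matrix(NA_real_, nmc, q)
  if (any(comp))
    PHI[comp, ] <- sweep((Z[comp, , drop = FALSE] * u[comp]) %*% cholPost,
                         2, mode, `+`)
  if (any(!comp))
    PHI[!comp, ] <- sweep(Z[!comp, , drop = FALSE] %*% cholOm, 2, mean_prior, `+`)
  l1 <- .dmvt_log_rows(PHI, mode, cholPost, df)
  l2 <- .dmvn_log_rows(PHI, mean_prior, cholOm)
  m <- pmax(l1, l2)
  lq <- m + log(0.85 * exp(l1 - m) + 0.15 * exp(l2 - m))
  list(PHI = PHI, lq = lq)
}

# covariate design row for one subject and one parameter's links
.link_design <- function(links, covariates) {
  vapply(links, function(lk) {
    cv <- covariates[[lk$covariate]]
    if (is.null(cv) || is.na(cv))
      stop("covariate '", lk$covariate, "' required by a link is missing")
    if (lk$form == "power_scaled") log(as.numeric(cv) / lk$ref)
    else as.numeric(as.numeric(cv) != lk$ref)
  }, numeric(1))
}

# Per-subject prior mean of phi = log(theta_i) for the IIV parameters.
.phi_means <- function(spec, rnames, subjects) {
  mu <- log(spec$fixed[rnames])
  M <- vapply(subjects, function(sub) {
    m <- mu
    for (lk in spec$covariate_links) {
      if (!lk$param %in% rnames) next
      m[lk$param] <- m[lk$param] + lk$beta * .link_design(list(lk), sub$covariates)
    }
    m
  }, numeric(length(rnames)))
  matrix(if (is.matrix(M)) t(M) else M, nrow = length(subjects),
         ncol = length(rnames), dimnames = list(NULL, rnames))
}

# Full parameter vector from phi (IIV part) and xi (log non-IIV structural).
.assemble_theta <- function(phi, rnames, xi, fnames, spec, sub) {
  th <- c(exp(phi), exp(xi))
  names(th) <- c(rnames, fnames)
  # covariate links on non-IIV parameters (rare, but allowed)
  for (lk in spec$covariate_links) {
    if (lk$param %in% fnames)
      th[lk$param] <- th[lk$param] *
        exp(lk$beta * .link_design(list(lk), sub$covariates))
  }
  th
}

# ---- SAEM core --------------------------------------------------------------
# All structural parameters are carried in the individual log-parameter
# vector phi. Parameters with modelled IIV keep an estimated (co)variance;
# parameters without IIV receive an artificial variance that decays
# geometrically over the exploratory phase (simulated-annealing scheme), so
# their population values are updated through the same stochastic
# approximation as everything else and collapse onto point estimates.

.saem <- function(ds, model, init, settings) {
  subjects <- .prep_subjects(ds, model)
  n <- length(subjects)
  pnames <- param_names(model)
  rnames <- names(init$iiv)
  if (!all(rnames %in% pnames))
    stop("IIV on parameter(s) absent from the model: ",
         paste(setdiff(rnames, pnames), collapse = ", "))
  fnames <- setdiff(pnames, rnames)
  anames <- c(rnames, fnames)
  q <- length(rnames); qa <- length(anames)
  if (q >= n)
    warning("as many IIV parameters as subjects (", q, " vs ", n,
            "): the random-effect covariance is likely non-identifiable")
  streams <- c("pk", "pd")[.fit_dvids(model)]
  error <- init$error[streams]
  ef <- init$error_form
  allowed <- lapply(init$correlations, function(co) c(co[[1]], co[[2]]))
  K1 <- settings$n_explore; K2 <- settings$n_smooth

  # log-scale parameter box (positivity is built in; the Hill factor is
  # bounded below at 0.1)
  lb <- setNames(rep(log(1e-5), qa), anames)
  ub <- setNames(rep(log(1e5), qa), anames)
  if ("gamma" %in% anames) lb["gamma"] <- log(0.1)

  spec <- init
  Om_est <- if (q) omega_matrix(spec) else matrix(0, 0, 0)
  art_floor <- settings$art_floor
  art0 <- setNames(rep(0.15, length(fnames)), fnames)
  if (is.null(names(settings$art_v0))) {
    art0[] <- settings$art_v0[1]
  } else {
    hit <- intersect(names(settings$art_v0), fnames)
    art0[hit] <- settings$art_v0[hit]
  }
  art_decay <- (art_floor / art0)^(1 / K1)
  art_var <- art0
  build_Om <- function() {
    Om <- matrix(0, qa, qa, dimnames = list(anames, anames))
    if (q) Om[rnames, rnames] <- Om_est
    if (length(fnames)) diag(Om)[q + seq_along(fnames)] <- art_var
    Om
  }
  Om <- build_Om()
  cholOm <- chol(Om)
  means <- .phi_means(spec, anames, subjects)
  PHI <- means
  subj_eval <- function(i, phi) {
    th <- setNames(exp(phi), anames)
    f <- tryCatch(
      .predict_obs(model, th, subjects[[i]]$doses, subjects[[i]]$obs$TIME,
                   subjects[[i]]$obs$DVID, subjects[[i]]$conc_input),
      error = function(e) NULL)
    list(ll = .obs_ll(subjects[[i]], f, error, ef), f = f)
  }
  F_cur <- vector("list", n)
  ll_cur <- numeric(n)
  for (i in seq_len(n)) {
    ev <- subj_eval(i, PHI[i, ])
    ll_cur[i] <- ev$ll; F_cur[[i]] <- ev$f
  }
  if (any(!is.finite(ll_cur)))
    stop("initial estimates give a non-finite likelihood; check init")
  prior_ll <- function(i, phi) {
    z <- backsolve(cholOm, phi - means[i, ], transpose = TRUE)
    -0.5 * sum(z^2)
  }
  in_box <- function(phi) all(phi >= lb & phi <= ub)

  s1 <- PHI; s2 <- crossprod(PHI)
  rw_scale <- rep(0.4, n)
  cw_scale <- rep(0.4, qa)
  trace <- vector("list", K1 + K2)

  for (k in seq_len(K1 + K2)) {
    gam <- if (k <= K1) 1 else 1 / (k - K1)
    # --- MCMC on the individual parameters --------------------------------
    for (i in seq_len(n)) {
      lp_cur <- ll_cur[i] + prior_ll(i, PHI[i, ])
      for (r in seq_len(settings$mcmc_ind)) {   # independence kernel
        prop <- means[i, ] + drop(crossprod(cholOm, rnorm(qa)))
        if (!in_box(prop)) next
        ev <- subj_eval(i, prop)
        if (log(runif(1)) < ev$ll - ll_cur[i]) {
          PHI[i, ] <- prop; ll_cur[i] <- ev$ll; F_cur[[i]] <- ev$f
          lp_cur <- ev$ll + prior_ll(i, prop)
        }
      }
      for (r in seq_len(settings$mcmc_rw)) {    # full random walk
        prop <- PHI[i, ] + rw_scale[i] * drop(crossprod(cholOm, rnorm(qa)))
        acc <- FALSE
        if (in_box(prop)) {
          ev <- subj_eval(i, prop)
          lpp <- ev$ll + prior_ll(i, prop)
          acc <- log(runif(1)) < lpp - lp_cur
          if (acc) {
            PHI[i, ] <- prop; ll_cur[i] <- ev$ll; F_cur[[i]] <- ev$f
            lp_cur <- lpp
          }
        }
        rw_scale[i] <- exp(log(rw_scale[i]) + (as.numeric(acc) - 0.3) / sqrt(k))
      }
      if (k %% settings$cw_every == 0) {        # componentwise random walk
        for (j in seq_len(qa)) {
          prop <- PHI[i, ]
          prop[j] <- prop[j] + cw_scale[j] * sqrt(Om[j, j]) * rnorm(1)
          acc <- FALSE
          if (in_box(prop)) {
            ev <- subj_eval(i, prop)
            lpp <- ev$ll + prior_ll(i, prop)
            acc <- log(runif(1)) < lpp - lp_cur
            if (acc) {
              PHI[i, ] <- prop; ll_cur[i] <- ev$ll; F_cur[[i]] <- ev$f
              lp_cur <- lpp
            }
          }
          cw_scale[j] <- exp(log(cw_scale[j]) + (as.numeric(acc) - 0.4) / sqrt(k))
        }
      }
    }
    # --- sufficient statistics --------------------------------------------
    s1 <- s1 + gam * (PHI - s1)
    s2 <- s2 + gam * (crossprod(PHI) - s2)
    # --- M-step: population means and covariate coefficients --------------
    for (j in seq_len(qa)) {
      links <- which(vapply(spec$covariate_links, function(lk)
        lk$param == anames[j], logical(1)))
      if (!length(links)) {
        spec$fixed[anames[j]] <- exp(mean(s1[, j]))
      } else {
        D <- vapply(subjects, function(sub)
          .link_design(spec$covariate_links[links], sub$covariates),
          numeric(length(links)))
        X <- cbind(1, matrix(if (is.matrix(D)) t(D) else D, nrow = n))
        cf <- qr.coef(qr(X), s1[, j])
        spec$fixed[anames[j]] <- exp(cf[1])
        for (b in seq_along(links))
          spec$covariate_links[[links[b]]]$beta <- cf[1 + b]
      }
    }
    means <- .phi_means(spec, anames, subjects)
    # --- M-step: Omega (structured projection + annealing floor) ----------
    if (q) {
      Sfull <- s2 / n - crossprod(s1, means) / n - crossprod(means, s1) / n +
        crossprod(means) / n
      Sfull <- (Sfull + t(Sfull)) / 2
      Sr <- Sfull[rnames, rnames, drop = FALSE]
      dg <- pmax(diag(Sr), 1e-8)
      if (k <= K1) dg <- pmax(dg, settings$annealing * diag(Om_est))
      Om_new <- diag(dg, q)
      dimnames(Om_new) <- list(rnames, rnames)
      for (pair in allowed) {
        r <- Sr[pair[1], pair[2]] / sqrt(Sr[pair[1], pair[1]] * Sr[pair[2], pair[2]])
        r <- max(min(r, 0.98), -0.98)
        Om_new[pair[1], pair[2]] <- Om_new[pair[2], pair[1]] <-
          r * sqrt(dg[match(pair[1], rnames)] * dg[match(pair[2], rnames)])
      }
      Om_est <- Om_new
    }
    art_var <- if (k <= K1) pmax(art_var * art_decay, art_floor)
               else rep(art_floor, length(fnames))
    Om <- build_Om()
    cholOm <- chol(Om)
    # --- M-step: residual error from cached predictions --------------------
    cache <- lapply(seq_len(n), function(i)
      list(f = F_cur[[i]], obs = subjects[[i]]$obs))
    err_new <- .optim_error(cache, error, ef)
    for (s in names(error)) {
      e_star <- error[[s]] + gam * (err_new[[s]] - error[[s]])
      if (k <= K1)  # annealing floor on the error variances
        e_star <- pmax(e_star, sqrt(settings$annealing) * error[[s]])
      error[[s]] <- e_star
    }
    # data likelihoods under the new error coefficients (phi unchanged)
    ll_cur <- vapply(seq_len(n), function(i)
      .obs_ll(subjects[[i]], F_cur[[i]], error, ef), numeric(1))
    trace[[k]] <- c(iter = k, spec$fixed,
                    omega = if (q) sqrt(diag(Om_est)) else NULL,
                    unlist(error))
  }
  if (q) {
    spec$iiv <- setNames(sqrt(diag(Om_est)), rnames)
    spec$correlations <- lapply(allowed, function(pair)
      list(pair[1], pair[2],
           Om_est[pair[1], pair[2]] /
             sqrt(Om_est[pair[1], pair[1]] * Om_est[pair[2], pair[2]])))
  }
  spec$error[names(error)] <- error
  list(spec = spec, PHI = PHI[, rnames, drop = FALSE], Om = Om_est,
       rnames = rnames, fnames = fnames, subjects = subjects,
       trace = do.call(rbind, trace))
}

# Residual-error coefficient update given cached predictions.
.optim_error <- function(cache, error, ef) {
  out <- error
  for (s in names(error)) {
    dvid <- if (s == "pk") 1 else 2
    y <- unlist(lapply(cache, function(cc) cc$obs$DV[cc$obs$DVID == dvid]))
    f <- unlist(lapply(cache, function(cc) cc$f[cc$obs$DVID == dvid]))
    cens <- unlist(lapply(cache, function(cc) cc$obs$CENS[cc$obs$DVID == dvid]))
    lim <- unlist(lapply(cache, function(cc) cc$obs$LIMIT[cc$obs$DVID == dvid]))
    if (!length(y)) next
    lim <- ifelse(is.na(lim), 0, lim)
    cur <- error[[s]]
    obj <- function(lx) {
      cf <- setNames(exp(lx), names(cur))
      v <- sum(observation_loglik(y, f, cf, cens, lower = lim, upper = y, form = ef))
      if (!is.finite(v)) 1e10 else -v
    }
    op <- optim(log(cur), obj, method = if (length(cur) > 1) "Nelder-Mead" else "Brent",
                lower = if (length(cur) == 1) log(cur) - 4 else -Inf,
                upper = if (length(cur) == 1) log(cur) + 4 else Inf,
                control = list(maxit = 40))
    out[[s]] <- setNames(exp(op$par), names(cur))
  }
  out
}

# ---- Gauss-Hermite path (direct PD model, one random effect) ----------------
# Vectorised over all observations and quadrature nodes: with a non-adaptive
# rule the random effect takes the same node values for every subject, so the
# marginal likelihood is G vectorised passes over the stacked observations.

.fit_agq <- function(ds, model, init, settings, gh_nodes = 41) {
  subjects <- .prep_subjects(ds, model)
  rname <- names(init$iiv)
  stopifnot(length(rname) == 1, rname %in% c("IC50", "E0"),
            model$kind == "pd_obsconc", !length(init$covariate_links))
  fnames <- setdiff(param_names(model), rname)
  enames <- names(init$error$pd)
  gh <- gauss_hermite(gh_nodes)
  y <- unlist(lapply(subjects, function(s) s$obs$DV))
  conc <- unlist(lapply(subjects, function(s) s$conc_input))
  sid <- rep(seq_along(subjects),
             vapply(subjects, function(s) nrow(s$obs), integer(1)))
  ef <- init$error_form
  nm <- c(rname, fnames)
  lw <- log(gh$weights / sqrt(pi))
  neg2ll <- function(par) {
    fixed <- setNames(exp(par[seq_along(nm)]), nm)
    omega <- exp(par[length(nm) + 1])
    coefs <- setNames(exp(par[(length(nm) + 2):length(par)]), enames)
    gam <- if (model$hill == "estimated") fixed[["gamma"]] else 1
    imx <- if (model$inhibition == "partial") fixed[["Imax"]] else 1
    cg <- conc^gam
    LL <- vapply(seq_along(gh$nodes), function(g) {
      th <- fixed
      th[rname] <- th[rname] * exp(sqrt(2) * omega * gh$nodes[g])
      f <- th[["E0"]] * (1 - imx * cg / (cg + th[["IC50"]]^gam))
      sd <- error_sd(f, coefs, ef)
      if (any(sd <= 0)) return(rep(-Inf, length(subjects)))
      as.numeric(rowsum(dnorm(y, f, sd, log = TRUE), sid))
    }, numeric(length(subjects)))
    tot <- sum(apply(LL + rep(lw, each = length(subjects)), 1, logsumexp))
    if (!is.finite(tot)) 1e10 else -2 * tot
  }
  par0 <- c(log(init$fixed[nm]), log(init$iiv), log(init$error$pd))
  op <- optim(par0, neg2ll, method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-10))
  op <- optim(op$par, neg2ll, method = "BFGS", control = list(maxit = 100))
  spec <- init
  spec$fixed[nm] <- exp(op$par[seq_along(nm)])
  spec$iiv[rname] <- exp(op$par[length(nm) + 1])
  spec$error$pd[] <- exp(op$par[(length(nm) + 2):length(op$par)])
  list(spec = spec, subjects = subjects, ofv = op$value,
       converged = op$convergence == 0)
}

# ---- direct ML (no IIV) -----------------------------------------------------

.fit_ml <- function(ds, model, init, settings) {
  subjects <- .prep_subjects(ds, model)
  pnames <- param_names(model)
  streams <- c("pk", "pd")[.fit_dvids(model)]
  err0 <- init$error[streams]
  en <- unlist(lapply(names(err0), function(s) paste0(s, ".", names(err0[[s]]))))
  par0 <- c(log(init$fixed[pnames]), setNames(log(unlist(err0)), en))
  unpack <- function(p) {
    fixed <- setNames(exp(p[seq_along(pnames)]), pnames)
    ev <- exp(p[-seq_along(pnames)])
    error <- err0
    idx <- 1
    for (s in names(error)) {
      error[[s]][] <- ev[idx:(idx + length(error[[s]]) - 1)]
      idx <- idx + length(error[[s]])
    }
    list(fixed = fixed, error = error)
  }
  obj <- function(p) {
    u <- unpack(p)
    tot <- sum(vapply(subjects, function(sub)
      .subj_ll(model, sub, u$fixed, u$error, init$error_form), numeric(1)))
    if (!is.finite(tot)) 1e10 else -2 * tot
  }
  op <- optim(par0, obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  op <- optim(op$par, obj, method = "BFGS", control = list(maxit = 200))
  u <- unpack(op$par)
  spec <- init
  spec$fixed[pnames] <- u$fixed
  spec$error[streams] <- u$error
  list(spec = spec, subjects = subjects, ofv = op$value,
       converged = op$convergence == 0)
}

# ---- public fitting interface ----------------------------------------------

#' Fit a population model by maximum likelihood
#'
#' Estimates the population parameters of a structural + statistical model on
#' an event dataset, integrating the random effects out of the likelihood.
#' Three estimation routes are used depending on the random-effect structure:
#' SAEM (stochastic approximation EM with an MCMC kernel on the individual
#' parameters and simulated-annealing variance floors) in the general case, a
#' Gauss-Hermite marginal likelihood maximised by quasi-Newton for a single
#' random effect, and direct ML when no parameter carries IIV. BLQ
#' concentrations contribute their interval probability on \[0, LLOQ\].
#'
#' @param ds a [study_dataset()] that has passed the inclusion/exclusion
#'   rules of its population.
#' @param model a [model_spec()].
#' @param init initial [population_spec()] (defines which parameters carry
#'   IIV, the correlation structure and the error models).
#' @param settings a [fit_settings()].
#' @param method `"auto"` (default), `"saem"`, `"agq"` or `"ml"`.
#' @return a `fit_result`: estimates (a [population_spec()]), `ofv`
#'   (-2 log-likelihood) with Monte-Carlo SE where stochastic, empirical
#'   Bayes estimates `ebes`, a per-iteration `trace` for SAEM, convergence
#'   flag and the echoed settings/seed.
#' @export
fit_population <- function(ds, model, init, settings = fit_settings(),
                           method = c("auto", "saem", "agq", "ml")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (!length(init$iiv)) "ml"
    else if (length(init$iiv) == 1 && model$kind == "pd_obsconc" &&
             !length(init$covariate_links)) "agq"
    else "saem"
  }
  if (method == "agq" && length(init$covariate_links))
    method <- "saem"  # the quadrature path has no covariate machinery
  t0 <- proc.time()[["elapsed"]]
  res <- with_seed(derive_seed(settings$seed, paste0("fit_", method)), {
    switch(method,
           saem = .saem(ds, model, init, settings),
           agq = .fit_agq(ds, model, init, settings),
           ml = .fit_ml(ds, model, init, settings))
  })
  fit <- structure(list(
    estimates = res$spec, model = model, method = method, init = init,
    settings = settings, seed = settings$seed, data = ds,
    subjects = res$subjects, trace = res$trace %||% NULL,
    converged = res$converged %||% TRUE,
    ofv = res$ofv %||% NA_real_, ofv_se = 0,
    PHI = res$PHI %||% NULL,
    runtime = proc.time()[["elapsed"]] - t0), class = "fit_result")
  if (settings$compute_ebe && length(res$spec$iiv))
    fit$ebes <- .ebes(fit)
  if (settings$compute_ofv && method == "saem") {
    o <- compute_ofv(ds, model, res$spec, nmc = settings$nmc_ofv,
                     seed = derive_seed(settings$seed, "ofv"), fit = fit)
    fit$ofv <- o$ofv; fit$ofv_se <- o$mc_se
  }
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result (", x$method, "), ", length(x$subjects), " subjects, OFV = ",
      round(x$ofv, 2), "\n", sep = "")
  est <- x$estimates
  tab <- data.frame(Estimate = signif(est$fixed, 4))
  print(tab)
  if (length(est$iiv))
    cat("IIV (CV%):", paste(names(est$iiv),
                            round(omega_to_cv(est$iiv), 1), collapse = ", "), "\n")
  for (co in est$correlations)
    cat("corr(", co[[1]], ",", co[[2]], ") =", round(co[[3]], 3), "\n")
  invisible(x)
}

# Empirical Bayes estimates: posterior modes of the individual random effects.
.ebes <- function(fit) {
  spec <- fit$estimates
  rnames <- names(spec$iiv)
  fnames <- setdiff(param_names(fit$model), rnames)
  xi <- log(spec$fixed[fnames])
  Om <- omega_matrix(spec)
  cholOm <- chol(Om)
  means <- .phi_means(spec, rnames, fit$subjects)
  E <- matrix(NA_real_, length(fit$subjects), length(rnames),
              dimnames = list(vapply(fit$subjects, `[[`, numeric(1), "id"), rnames))
  for (i in seq_along(fit$subjects)) {
    sub <- fit$subjects[[i]]
    negpost <- function(eta) {
      th <- .assemble_theta(means[i, ] + eta, rnames, xi, fnames, spec, sub)
      ll <- .subj_ll(fit$model, sub, th, spec$error, spec$error_form)
      z <- backsolve(cholOm, eta, transpose = TRUE)
      if (!is.finite(ll)) 1e10 else -(ll - 0.5 * sum(z^2))
    }
    start <- if (!is.null(fit$PHI)) fit$PHI[i, ] - means[i, ] else rep(0, length(rnames))
    op <- if (length(rnames) == 1)
      optim(start, negpost, method = "BFGS", control = list(maxit = 200))
    else optim(optim(start, negpost, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-10))$par,
               negpost, method = "BFGS", control = list(maxit = 60))
    E[i, ] <- op$par
  }
  E
}

#' Objective function value (-2 log marginal likelihood)
#'
#' With no IIV the integral collapses to a direct sum of observation
#' log-likelihoods; with one random effect it is computed by Gauss-Hermite
#' quadrature (deterministic); otherwise by importance sampling around the
#' empirical Bayes modes with a multivariate-t proposal, reporting the
#' Monte-Carlo standard error alongside.
#'
#' @param ds,model,spec dataset, structural model and population parameters.
#' @param nmc importance-sampling size per subject.
#' @param seed integer seed for the stochastic route.
#' @param fit optional `fit_result` whose EBE modes seed the proposal.
#' @param force_is use importance sampling even when a deterministic
#'   quadrature route exists (cross-validation of the two routes).
#' @return list with `ofv` and `mc_se`. The Monte-Carlo SE is an in-sample
#'   estimate and understates the error when importance weights are
#'   heavy-tailed (high-dimensional random effects); compare models with a
#'   common seed and equal `nmc`, and treat small differences as noise.
#' @export
compute_ofv <- function(ds, model, spec, nmc = 300, seed = 1, fit = NULL,
                        force_is = FALSE) {
  subjects <- if (!is.null(fit)) fit$subjects else .prep_subjects(ds, model)
  rnames <- names(spec$iiv)
  q <- length(rnames)
  fnames <- setdiff(param_names(model), rnames)
  xi <- log(spec$fixed[fnames])
  if (q == 0) {
    tot <- sum(vapply(subjects, function(sub)
      .subj_ll(model, sub, spec$fixed[param_names(model)], spec$error,
               spec$error_form), numeric(1)))
    return(list(ofv = -2 * tot, mc_se = 0))
  }
  Om <- omega_matrix(spec)
  cholOm <- chol(Om)
  means <- .phi_means(spec, rnames, subjects)
  if (q == 1 && !force_is) {
    gh <- gauss_hermite(41)
    om <- sqrt(Om[1, 1])
    tot <- 0
    for (i in seq_along(subjects)) {
      lls <- vapply(gh$nodes, function(x) {
        th <- .assemble_theta(means[i, ] + sqrt(2) * om * x, rnames, xi,
                              fnames, spec, subjects[[i]])
        .subj_ll(model, subjects[[i]], th, spec$error, spec$error_form)
      }, numeric(1))
      tot <- tot + logsumexp(lls + log(gh$weights / sqrt(pi)))
    }
    return(list(ofv = -2 * tot, mc_se = 0))
  }
  with_seed(derive_seed(seed, "is_ofv"), {
    ldet <- as.numeric(determinant(Om)$modulus)
    tot <- 0; var_tot <- 0
    for (i in seq_along(subjects)) {
      sub <- subjects[[i]]
      subj_ll_eta <- function(eta) {
        th <- .assemble_theta(means[i, ] + eta, rnames, xi, fnames, spec, sub)
        .subj_ll(model, sub, th, spec$error, spec$error_form)
      }
      negpost <- function(eta) {
        ll <- subj_ll_eta(eta)
        z <- backsolve(cholOm, eta, transpose = TRUE)
        if (!is.finite(ll)) 1e10 else -(ll - 0.5 * sum(z^2))
      }
      start <- if (!is.null(fit) && !is.null(fit$ebes)) fit$ebes[i, ] else rep(0, q)
      mode <- optim(start, negpost,
                    method = if (q == 1) "BFGS" else "Nelder-Mead",
                    control = list(maxit = 500))$par
      mode <- optim(mode, negpost, method = "BFGS",
                    control = list(maxit = 60))$par
      cholPost <- 1.3 * .laplace_chol(negpost, mode, q,
                                      fallback = cholOm / sqrt(2))
      dr <- .is_draws(nmc, mode, cholPost, rep(0, q), cholOm)
      lw <- vapply(seq_len(nmc), function(m) {
        eta <- dr$PHI[m, ]
        ll <- subj_ll_eta(eta)
        z <- backsolve(cholOm, eta, transpose = TRUE)
        (ll - 0.5 * sum(z^2) - 0.5 * ldet - (q / 2) * log(2 * pi)) - dr$lq[m]
      }, numeric(1))
      lml <- logsumexp(lw) - log(nmc)
      tot <- tot + lml
      w <- exp(lw - max(lw))
      var_tot <- var_tot + stats::var(w) / (nmc * mean(w)^2)
    }
    list(ofv = -2 * tot, mc_se = 2 * sqrt(var_tot))
  })
}

#' Relative standard errors of the population estimates
#'
#' `"fim"` builds the Fisher information from the outer product of
#' per-subject score vectors of the marginal log-likelihood (numerical
#' differentiation on the log/transformed scale, common random numbers);
#' `"bootstrap"` refits case-resampled datasets, warm-started at the
#' estimates, and reports 100 * SD / estimate.
#'
#' @param fit a converged `fit_result`.
#' @param method `"fim"` or `"bootstrap"`.
#' @param B bootstrap replicates (a warning is given below 20).
#' @param seed integer seed.
#' @param nmc per-subject Monte-Carlo size for the marginal likelihood in the
#'   FIM route.
#' @param settings optional reduced [fit_settings()] for bootstrap refits.
#' @return named vector of RSE (%) covering fixed effects, omegas,
#'   correlations and error coefficients.
#' @export
estimate_rse <- function(fit, method = c("fim", "bootstrap"), B = 50,
                         seed = 1, nmc = 200, settings = NULL) {
  method <- match.arg(method)
  spec <- fit$estimates
  if (method == "bootstrap") {
    if (B < 20) warning("bootstrap with B < 20 replicates is unreliable")
    ids <- unique(fit$data$events$ID)
    boots <- with_seed(derive_seed(seed, "boot"), {
      lapply(seq_len(B), function(b) sample(ids, replace = TRUE))
    })
    st <- settings %||% fit$settings
    st$compute_ofv <- FALSE; st$compute_ebe <- FALSE
    ests <- lapply(seq_len(B), function(b) {
      take <- boots[[b]]
      ev <- do.call(rbind, lapply(seq_along(take), function(j) {
        e <- fit$data$events[fit$data$events$ID == take[j], ]
        e$ID <- j
        e
      }))
      cv <- do.call(rbind, lapply(seq_along(take), function(j) {
        cc <- fit$data$covariates[fit$data$covariates$ID == take[j], ]
        cc$ID <- j
        cc
      }))
      dsb <- study_dataset(ev, cv, fit$data$population, fit$data$assay)
      st$seed <- derive_seed(seed, paste0("boot", b))
      fb <- fit_population(dsb, fit$model, spec, st, method = fit$method)
      .flatten_spec(fb$estimates)
    })
    M <- do.call(rbind, ests)
    est <- .flatten_spec(spec)
    return(100 * apply(M, 2, sd) / abs(est))
  }
  # FIM route: exact Hessian of the marginal log-likelihood when the
  # per-subject marginals are deterministic (0- or 1-dimensional random
  # effects); BHHH cross-product of per-subject scores otherwise (common
  # random numbers keep the finite differences smooth).
  par <- .spec_to_par(spec)
  h <- 1e-4
  base_seed <- derive_seed(seed, "fim")
  subj_lml <- function(spec_k) {
    vapply(seq_along(fit$subjects), function(i)
      .subject_marginal(fit, spec_k, i, nmc, base_seed + i), numeric(1))
  }
  if (length(spec$iiv) <= 1) {
    negll <- function(v) {
      pk <- par; pk$value[] <- v
      -sum(subj_lml(.par_to_spec(pk, spec)))
    }
    FIM <- optimHess(par$value, negll)
    dimnames(FIM) <- list(names(par$value), names(par$value))
  } else {
    scores <- matrix(0, length(fit$subjects), length(par$value),
                     dimnames = list(NULL, names(par$value)))
    for (j in seq_along(par$value)) {
      up <- par; up$value[j] <- up$value[j] + h
      dn <- par; dn$value[j] <- dn$value[j] - h
      scores[, j] <- (subj_lml(.par_to_spec(up, spec)) -
                        subj_lml(.par_to_spec(dn, spec))) / (2 * h)
    }
    FIM <- crossprod(scores)
  }
  V <- tryCatch(solve(FIM), error = function(e) {
    bad <- names(par$value)[which.min(abs(diag(FIM)))]
    stop("singular Fisher information matrix (parameter '", bad, "')")
  })
  se_t <- sqrt(pmax(diag(V), 0))
  # transformed scale is log for positive parameters, atanh for correlations:
  # RSE% of a lognormal parameter is ~100 * sd(log); correlations delta-back.
  rse <- 100 * se_t
  for (j in seq_along(par$value)) {
    if (par$kind[j] == "corr") {
      r <- tanh(par$value[j])
      rse[j] <- 100 * se_t[j] * (1 - r^2) / abs(r)
    }
  }
  setNames(rse, names(par$value))
}

# flatten / rebuild population specs for RSE machinery ------------------------

.flatten_spec <- function(spec) {
  out <- spec$fixed
  if (length(spec$iiv))
    out <- c(out, setNames(spec$iiv, paste0("omega_", names(spec$iiv))))
  for (co in spec$correlations)
    out <- c(out, setNames(co[[3]], paste0("corr_", co[[1]], "_", co[[2]])))
  for (s in names(spec$error))
    out <- c(out, setNames(spec$error[[s]], paste0(s, "_", names(spec$error[[s]]))))
  out
}

.spec_to_par <- function(spec) {
  v <- log(spec$fixed)
  k <- rep("fixed", length(v))
  if (length(spec$iiv)) {
    v <- c(v, setNames(log(spec$iiv), paste0("omega_", names(spec$iiv))))
    k <- c(k, rep("omega", length(spec$iiv)))
  }
  for (co in spec$correlations) {
    v <- c(v, setNames(atanh(co[[3]]), paste0("corr_", co[[1]], "_", co[[2]])))
    k <- c(k, "corr")
  }
  for (s in names(spec$error)) {
    v <- c(v, setNames(log(spec$error[[s]]), paste0(s, "_", names(spec$error[[s]]))))
    k <- c(k, rep("error", length(spec$error[[s]])))
  }
  list(value = v, kind = k)
}

.par_to_spec <- function(par, template) {
  spec <- template
  nf <- length(spec$fixed)
  spec$fixed[] <- exp(par$value[seq_len(nf)])
  idx <- nf
  if (length(spec$iiv)) {
    spec$iiv[] <- exp(par$value[idx + seq_along(spec$iiv)])
    idx <- idx + length(spec$iiv)
  }
  for (j in seq_along(spec$correlations)) {
    idx <- idx + 1
    spec$correlations[[j]][[3]] <- tanh(par$value[idx])
  }
  for (s in names(spec$error)) {
    spec$error[[s]][] <- exp(par$value[idx + seq_along(spec$error[[s]])])
    idx <- idx + length(spec$error[[s]])
  }
  spec
}

# Marginal log-likelihood of one subject under a spec (fixed small MC seed so
# finite differences see a smooth function).
.subject_marginal <- function(fit, spec, i, nmc, seed) {
  model <- fit$model
  sub <- fit$subjects[[i]]
  rnames <- names(spec$iiv)
  q <- length(rnames)
  fnames <- setdiff(param_names(model), rnames)
  xi <- log(spec$fixed[fnames])
  means <- .phi_means(spec, rnames, list(sub))
  if (q == 0)
    return(.subj_ll(model, sub, spec$fixed[param_names(model)], spec$error,
                    spec$error_form))
  Om <- omega_matrix(spec)
  if (q == 1) {
    gh <- gauss_hermite(31)
    lls <- vapply(gh$nodes, function(x) {
      th <- .assemble_theta(means[1, ] + sqrt(2) * sqrt(Om[1, 1]) * x, rnames,
                            xi, fnames, spec, sub)
      .subj_ll(model, sub, th, spec$error, spec$error_form)
    }, numeric(1))
    return(logsumexp(lls + log(gh$weights / sqrt(pi))))
  }
  cholOm <- chol(Om)
  ldet <- as.numeric(determinant(Om)$modulus)
  eb <- if (!is.null(fit$ebes)) fit$ebes[i, ] else rep(0, q)
  subj_ll_eta <- function(eta) {
    th <- .assemble_theta(means[1, ] + eta, rnames, xi, fnames, spec, sub)
    .subj_ll(model, sub, th, spec$error, spec$error_form)
  }
  negpost <- function(eta) {
    ll <- subj_ll_eta(eta)
    z <- backsolve(cholOm, eta, transpose = TRUE)
    if (!is.finite(ll)) 1e10 else -(ll - 0.5 * sum(z^2))
  }
  with_seed(seed, {
    cholPost <- 1.3 * .laplace_chol(negpost, eb, q, fallback = cholOm / sqrt(2))
    dr <- .is_draws(nmc, eb, cholPost, rep(0, q), cholOm)
    lw <- vapply(seq_len(nmc), function(m) {
      eta <- dr$PHI[m, ]
      ll <- subj_ll_eta(eta)
      z <- backsolve(cholOm, eta, transpose = TRUE)
      (ll - 0.5 * sum(z^2) - 0.5 * ldet - (q / 2) * log(2 * pi)) - dr$lq[m]
    }, numeric(1))
    logsumexp(lw) - log(nmc)
  })
}

#' Correlation test between empirical Bayes estimates
#'
#' Pearson correlation of every EBE pair with a t-test; significant pairs are
#' proposed for inclusion as off-diagonal random-effect covariances.
#'
#' @param fit a `fit_result` with at least two IIV parameters.
#' @param p_threshold flagging threshold.
#' @return data.frame with columns par1, par2, r, p, flagged.
#' @export
correlation_test_random_effects <- function(fit, p_threshold = 0.01) {
  E <- fit$ebes
  if (is.null(E) || ncol(E) < 2) stop("need at least two parameters with IIV")
  if (nrow(E) < 3) stop("need at least three subjects for a correlation test")
  prs <- utils::combn(colnames(E), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    a <- E[, prs[1, j]]; b <- E[, prs[2, j]]
    if (sd(a) == 0 || sd(b) == 0) {
      warning("constant EBE vector for ", prs[1, j], " or ", prs[2, j],
              "; correlation undefined")
      return(data.frame(par1 = prs[1, j], par2 = prs[2, j],
                        r = NA_real_, p = NA_real_, flagged = FALSE))
    }
    ct <- stats::cor.test(a, b)
    data.frame(par1 = prs[1, j], par2 = prs[2, j],
               r = unname(ct$estimate), p = ct$p.value,
               flagged = ct$p.value < p_threshold)
  }))
  out
}

#' Stepwise covariate search with profile likelihood-ratio tests
#'
#' A documented simplification of correlation-guided stepwise covariate
#' selection. Candidate (parameter, covariate) pairs are screened by the
#' correlation between empirical Bayes estimates and covariates; for each
#' candidate covariate the strongest pair is tested by a profile
#' likelihood-ratio test: the link coefficient is profiled by 1-D
#' optimisation of the marginal likelihood, evaluated with identical
#' per-subject importance-sampling draws under the null and the alternative
#' so that Monte-Carlo noise cancels exactly in the objective-function
#' difference. A candidate is included when the drop reaches the
#' chi-square(1) quantile at the forward p-value (6.635 at p = 0.01);
#' backward elimination re-tests each retained link symmetrically. When links
#' survive, the final model is refitted in full.
#'
#' @param ds dataset (passed through to the final refit).
#' @param base_fit the covariate-free `fit_result` (with EBEs).
#' @param candidates covariate column names to try.
#' @param forward_p,backward_p LRT thresholds (defaults 0.01).
#' @param settings reduced [fit_settings()] for the final refit.
#' @param nmc importance-sampling size per subject for the profile objective.
#' @param seed integer seed.
#' @return list with `selected` (covariate links), `log` (decision
#'   data.frame), `final_fit`, and the thresholds used.
#' @export
lrt_stepwise_covariates <- function(ds, base_fit,
                                    candidates = c("SEX", "AGE", "WT", "BMI"),
                                    forward_p = 0.01, backward_p = 0.01,
                                    settings = NULL, nmc = 150, seed = 1) {
  thr_f <- qchisq(1 - forward_p, df = 1)
  thr_b <- qchisq(1 - backward_p, df = 1)
  E <- base_fit$ebes
  if (is.null(E)) stop("base fit carries no empirical Bayes estimates")
  cov <- base_fit$data$covariates
  covm <- cov[match(rownames(E), as.character(cov$ID)), ]
  logrows <- list()
  screen <- list()
  for (cn in candidates) {
    x <- covm[[cn]]
    if (is.null(x) || all(is.na(x))) {
      logrows[[length(logrows) + 1]] <- data.frame(
        step = "screen", covariate = cn, param = NA, delta_ofv = NA,
        decision = "skipped: covariate absent")
      next
    }
    if (length(unique(stats::na.omit(x))) < 2) {
      logrows[[length(logrows) + 1]] <- data.frame(
        step = "screen", covariate = cn, param = NA, delta_ofv = NA,
        decision = "skipped: covariate constant across subjects")
      next
    }
    ps <- vapply(colnames(E), function(pn)
      stats::cor.test(E[, pn], as.numeric(x))$p.value, numeric(1))
    screen[[cn]] <- list(param = names(which.min(ps)), p = min(ps))
  }
  ord <- names(screen)[order(vapply(screen, `[[`, numeric(1), "p"))]
  base_seed <- derive_seed(seed, "covlrt")

  make_link <- function(cn, pn, beta = 0) {
    if (cn == "SEX") {
      list(param = pn, covariate = cn, form = "exponential_categorical",
           beta = beta, ref = 0)
    } else {
      w <- table(factor(ds$events$ID[ds$events$EVID == 0], levels = cov$ID))
      ref <- sum(cov[[cn]] * as.numeric(w)) / sum(w)  # observation-weighted mean
      list(param = pn, covariate = cn, form = "power_scaled", beta = beta,
           ref = ref)
    }
  }
  # One-time importance-sampling pass per subject, drawn in the space of the
  # individual log-parameters phi. The data likelihood of every draw is
  # cached; profiling any mean-structure parameter (the intercept of the
  # linked parameter, the link coefficient) afterwards only re-evaluates the
  # Gaussian prior density of the cached draws, so the null and alternative
  # share the exact same Monte-Carlo randomness and differ by 1 df.
  spec0 <- base_fit$estimates
  rnames <- names(spec0$iiv)
  fnames <- setdiff(param_names(base_fit$model), rnames)
  xi <- log(spec0$fixed[fnames])
  Om <- omega_matrix(spec0)
  cholOm <- chol(Om)
  ldet <- as.numeric(determinant(Om)$modulus)
  qn <- length(rnames)
  means0 <- .phi_means(spec0, rnames, base_fit$subjects)
  draws <- with_seed(base_seed, lapply(seq_along(base_fit$subjects), function(i) {
    sub <- base_fit$subjects[[i]]
    eb <- if (!is.null(base_fit$ebes)) base_fit$ebes[i, ] else rep(0, qn)
    subj_ll_eta <- function(eta) {
      th <- .assemble_theta(means0[i, ] + eta, rnames, xi, fnames, spec0, sub)
      .subj_ll(base_fit$model, sub, th, spec0$error, spec0$error_form)
    }
    negpost <- function(eta) {
      ll <- subj_ll_eta(eta)
      z <- backsolve(cholOm, eta, transpose = TRUE)
      if (!is.finite(ll)) 1e10 else -(ll - 0.5 * sum(z^2))
    }
    cholPost <- 1.3 * .laplace_chol(negpost, eb, qn, fallback = cholOm / sqrt(2))
    dr <- .is_draws(nmc, eb, cholPost, rep(0, qn), cholOm)
    PHI <- sweep(dr$PHI, 2, means0[i, ], `+`)
    ll <- vapply(seq_len(nmc), function(m) {
      th <- .assemble_theta(PHI[m, ], rnames, xi, fnames, spec0, sub)
      .subj_ll(base_fit$model, sub, th, spec0$error, spec0$error_form)
    }, numeric(1))
    list(PHI = PHI, ll = ll, lq = dr$lq)
  }))
  # -2 log marginal likelihood as a function of the linked parameter's mean
  # shift per subject and its own omega; both the intercept and the variance
  # of the tested parameter are re-profiled under null and alternative, as a
  # full refit would do, so the comparison carries exactly 1 df for the link.
  sds0 <- sqrt(diag(Om))
  R0 <- diag(1 / sds0, qn) %*% Om %*% diag(1 / sds0, qn)
  ofv_shift <- function(pn, shift, log_om = NULL) {
    jp <- match(pn, rnames)
    if (is.null(log_om)) {
      cholK <- cholOm; ldetK <- ldet
    } else {
      sds <- sds0; sds[jp] <- exp(log_om)
      OmK <- diag(sds, qn) %*% R0 %*% diag(sds, qn)
      cholK <- tryCatch(chol(OmK), error = function(e) NULL)
      if (is.null(cholK)) return(1e10)
      ldetK <- 2 * sum(log(diag(cholK)))
    }
    tot <- 0
    for (i in seq_along(draws)) {
      mean_i <- means0[i, ]
      mean_i[jp] <- mean_i[jp] + shift[i]
      D <- sweep(draws[[i]]$PHI, 2, mean_i, `-`)
      lp <- -0.5 * colSums(backsolve(cholK, t(D), transpose = TRUE)^2) -
        0.5 * ldetK - (qn / 2) * log(2 * pi)
      tot <- tot + logsumexp(draws[[i]]$ll + lp - draws[[i]]$lq) - log(nmc)
    }
    if (!is.finite(tot)) 1e10 else -2 * tot
  }
  link_x <- function(cn, pn) {
    lk <- make_link(cn, pn)
    vapply(base_fit$subjects, function(sub)
      .link_design(list(lk), sub$covariates), numeric(1))
  }
  profile_pair <- function(cn, pn) {
    x <- link_x(cn, pn)
    jp <- match(pn, rnames)
    nsub <- length(draws)
    null <- optim(c(0, log(sds0[jp])),
                  function(p) ofv_shift(pn, rep(p[1], nsub), p[2]),
                  method = "Nelder-Mead",
                  control = list(maxit = 300, reltol = 1e-9))
    alt <- optim(c(null$par, 0),
                 function(p) ofv_shift(pn, p[1] + p[3] * x, p[2]),
                 method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-9))
    list(dofv = null$value - alt$value, beta = alt$par[3])
  }

  selected <- list()
  for (cn in ord) {
    pn <- screen[[cn]]$param
    pb <- profile_pair(cn, pn)
    keep <- is.finite(pb$dofv) && pb$dofv >= thr_f
    logrows[[length(logrows) + 1]] <- data.frame(
      step = "forward", covariate = cn, param = pn, delta_ofv = pb$dofv,
      decision = if (keep) "included" else "rejected")
    if (keep)
      selected <- c(selected, list(make_link(cn, pn, beta = pb$beta)))
  }
  if (length(selected)) {
    # backward: re-test each retained link with the same cached draws
    for (j in rev(seq_along(selected))) {
      lk <- selected[[j]]
      pb <- profile_pair(lk$covariate, lk$param)
      drop_it <- !is.finite(pb$dofv) || pb$dofv < thr_b
      logrows[[length(logrows) + 1]] <- data.frame(
        step = "backward", covariate = lk$covariate, param = lk$param,
        delta_ofv = pb$dofv,
        decision = if (drop_it) "removed" else "retained")
      if (drop_it) selected <- selected[-j]
    }
  }
  final <- base_fit
  if (length(selected)) {
    st <- settings %||% base_fit$settings
    st$compute_ofv <- FALSE
    st$seed <- derive_seed(seed, "covfinal")
    init <- base_fit$estimates
    init$covariate_links <- selected
    final <- fit_population(ds, base_fit$model, init, st,
                            method = base_fit$method)
    selected <- final$estimates$covariate_links
  }
  list(selected = selected, log = do.call(rbind, logrows), final_fit = final,
       threshold_forward = thr_f, threshold_backward = thr_b)
}
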