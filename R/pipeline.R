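# End-to-end workflows mirroring the two analyses, with seeded determinism
# and a manifest of every stage.

.obj_md5 <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

.manifest_add <- function(manifest, name, seed, obj) {
  manifest[[length(manifest) + 1]] <- list(
    stage = name, seed = seed, md5 = .obj_md5(obj),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  manifest
}

#' Default initial estimates for the adult analysis
#'
#' Round-number starting values well away from the final estimates, with
#' moderate (30\% CV) IIV on the parameters that carry random effects in the
#' final model and the V1-CL correlation started at zero.
#' @return a [population_spec()].
#' @export
default_adult_init <- function() {
  population_spec(
    fixed = c(ktr = 3, Mtt = 1, ka = 1, CL = 20, V1 = 100, Q = 5, V2 = 50,
              ke0 = 1, gamma = 1.5, E0 = 0.1, IC50 = 10),
    iiv = cv_to_omega(c(ktr = 30, Mtt = 30, CL = 30, V1 = 30, E0 = 30, IC50 = 30)),
    correlations = list(list("V1", "CL", 0)),
    error = list(pk = c(a = 0.5, b = 0.15), pd = c(b = 0.3)))
}

#' Default initial estimates for the paediatric analysis
#' @return a [population_spec()].
#' @export
default_paediatric_init <- function() {
  population_spec(fixed = c(E0 = 0.1, IC50 = 0.5),
                  iiv = cv_to_omega(c(IC50 = 50)),
                  error = list(pd = c(b = 0.3)))
}

# PK-part projection of a PKPD spec (for the staged adult workflow).
.pk_part <- function(spec) {
  pk_par <- c("ktr", "Mtt", "ka", "CL", "V1", "Q", "V2")
  population_spec(
    fixed = spec$fixed[intersect(names(spec$fixed), pk_par)],
    iiv = spec$iiv[intersect(names(spec$iiv), pk_par)],
    correlations = Filter(function(co)
      all(c(co[[1]], co[[2]]) %in% pk_par), spec$correlations),
    error = spec$error["pk"], error_form = spec$error_form)
}

#' Run the adult analysis workflow
#'
#' Stage 1 fits the PK model alone; stage 2 fits the simultaneous PK/PD model
#' initialised from the stage-1 estimates; then (optionally) the stepwise
#' covariate search, the random-effect correlation test, relative standard
#' errors, and goodness-of-fit plus visual predictive check. All stages are
#' seeded from `config$seed` and recorded in the returned manifest.
#'
#' @param config list with optional elements: `dataset` (a raw adult
#'   [study_dataset()]; generated from `design`/`truth` when absent),
#'   `design`, `truth`, `seed`, `init` (PKPD initial [population_spec()]),
#'   `settings` (a [fit_settings()]), `covariate_search` (logical),
#'   `rse_method` (`"fim"`, `"bootstrap"` or `"none"`), `vpc_nsim`.
#' @return an `adult_workflow` bundle: dataset + audit, `fit_pk`, `fit_pkpd`,
#'   covariate search log, correlation test, RSE, `gof`, `vpc`, `manifest`.
#' @export
run_adult_workflow <- function(config = list()) {
  seed <- config$seed %||% 1
  manifest <- list()
  ds_raw <- config$dataset %||% generate_adult_study(
    design = config$design %||% adult_design(),
    truth = config$truth %||% adult_final_spec(),
    seed = seed)
  manifest <- .manifest_add(manifest, "data", seed, ds_raw$events)
  inc <- apply_adult_inclusion_rules(ds_raw)
  manifest <- .manifest_add(manifest, "inclusion_rules", NA, inc$audit)

  init <- config$init %||% default_adult_init()
  st <- config$settings %||% fit_settings(n_explore = 150, n_smooth = 60,
                                          seed = seed)
  st$seed <- derive_seed(seed, "wf_pk")
  fit_pk <- fit_population(inc$dataset, model_spec(kind = "pk"),
                           .pk_part(init), st)
  manifest <- .manifest_add(manifest, "fit_pk", st$seed,
                            .flatten_spec(fit_pk$estimates))

  # stage-2 initialisation from the stage-1 PK estimates
  init2 <- init
  pkest <- fit_pk$estimates
  init2$fixed[names(pkest$fixed)] <- pkest$fixed
  init2$iiv[names(pkest$iiv)] <- pkest$iiv
  init2$error$pk <- pkest$error$pk
  st$seed <- derive_seed(seed, "wf_pkpd")
  fit_pkpd <- fit_population(inc$dataset, adult_final_model(), init2, st)
  manifest <- .manifest_add(manifest, "fit_pkpd", st$seed,
                            .flatten_spec(fit_pkpd$estimates))

  covsearch <- NULL
  if (isTRUE(config$covariate_search)) {
    covsearch <- lrt_stepwise_covariates(
      inc$dataset, fit_pkpd,
      settings = config$cov_settings %||%
        fit_settings(n_explore = 60, n_smooth = 30, seed = seed,
                     compute_ofv = FALSE),
      nmc = config$cov_nmc %||% 300, seed = derive_seed(seed, "wf_cov"))
    manifest <- .manifest_add(manifest, "covariate_search", seed, covsearch$log)
    fit_final <- covsearch$final_fit
  } else fit_final <- fit_pkpd

  cortest <- correlation_test_random_effects(fit_final)
  manifest <- .manifest_add(manifest, "correlation_test", NA, cortest)

  rse <- NULL
  if ((config$rse_method %||% "none") != "none") {
    rse <- estimate_rse(fit_final, method = config$rse_method,
                        B = config$rse_B %||% 50,
                        seed = derive_seed(seed, "wf_rse"))
    manifest <- .manifest_add(manifest, "rse", seed, rse)
  }
  g <- gof(inc$dataset, fit_final$model, fit_final)
  v <- vpc(inc$dataset, fit_final$model, fit_final,
           nsim = config$vpc_nsim %||% 500, seed = derive_seed(seed, "wf_vpc"))
  manifest <- .manifest_add(manifest, "diagnostics", NA,
                            list(g$summary, v$bands))
  structure(list(dataset = inc$dataset, audit = inc$audit, fit_pk = fit_pk,
                 fit_pkpd = fit_pkpd, covariate_search = covsearch,
                 correlation_test = cortest, rse = rse, gof = g, vpc = v,
                 fit_final = fit_final, seed = seed, manifest = manifest),
            class = "adult_workflow")
}

#' Run the paediatric analysis workflow
#'
#' Exclusion rules, the direct full-inhibition Imax fit (proportional error,
#' IIV on IC50 only) with measured concentrations as input, RSE, diagnostics,
#' the 4-hour percent-change report (only subjects with both a
#' predose-first-dose and a 4 h post-first-dose ratio contribute), and, when
#' an adult fit is supplied, the comparison overlay.
#'
#' @param config list with optional elements `dataset`, `design`, `truth`,
#'   `seed`, `init`, `settings`, `rse_method`, `rse_B`, `vpc_nsim`,
#'   `adult_fit`.
#' @return a `paediatric_workflow` bundle.
#' @export
run_paediatric_workflow <- function(config = list()) {
  seed <- config$seed %||% 1
  manifest <- list()
  ds_raw <- config$dataset %||% generate_paediatric_study(
    design = config$design %||% paediatric_design(),
    truth = config$truth %||% paediatric_final_spec(),
    seed = seed)
  manifest <- .manifest_add(manifest, "data", seed, ds_raw$events)
  exc <- apply_paediatric_exclusion_rules(ds_raw)
  manifest <- .manifest_add(manifest, "exclusion_rules", NA, exc$audit)

  st <- config$settings %||% fit_settings(seed = seed)
  st$seed <- derive_seed(seed, "wf_paed")
  fit <- fit_population(exc$dataset, paediatric_final_model(),
                        config$init %||% default_paediatric_init(), st)
  manifest <- .manifest_add(manifest, "fit_pd", st$seed,
                            .flatten_spec(fit$estimates))
  rse <- NULL
  if ((config$rse_method %||% "none") != "none") {
    rse <- estimate_rse(fit, method = config$rse_method,
                        B = config$rse_B %||% 50,
                        seed = derive_seed(seed, "wf_rse"))
    manifest <- .manifest_add(manifest, "rse", seed, rse)
  }
  g <- gof(exc$dataset, fit$model, fit)
  v <- vpc(exc$dataset, fit$model, fit, nsim = config$vpc_nsim %||% 500,
           bin_on = "tsld", seed = derive_seed(seed, "wf_vpc"))
  # 4 h percent-change pairs
  ev <- exc$dataset$events
  rat <- ev[ev$EVID == 0 & ev$DVID == 2, ]
  pre <- rat[rat$CLASS == "predose_first", c("ID", "DV")]
  post4 <- rat[rat$CLASS == "post_first" & rat$TIME == 4, c("ID", "DV")]
  both <- merge(pre, post4, by = "ID", suffixes = c("_pre", "_post"))
  pct <- if (nrow(both))
    percent_change_4h(data.frame(ratio_predose = both$DV_pre,
                                 ratio_4h = both$DV_post)) else NULL
  manifest <- .manifest_add(manifest, "percent_change_4h", NA, pct)
  overlay <- NULL
  if (!is.null(config$adult_fit)) {
    overlay <- comparison_overlay(config$adult_fit, exc$dataset,
                                  nsim = config$vpc_nsim %||% 500,
                                  seed = derive_seed(seed, "wf_overlay"))
    manifest <- .manifest_add(manifest, "overlay", NA, overlay$points)
  }
  structure(list(dataset = exc$dataset, audit = exc$audit, fit = fit,
                 rse = rse, gof = g, vpc = v, percent_change = pct,
                 overlay = overlay, seed = seed, manifest = manifest),
            class = "paediatric_workflow")
}

#' Compare fitted models on the same dataset
#'
#' Tabulates the decision criteria used during model development: objective
#' function value, residual-error coefficients, IIV CV\%s and (when
#' available) the largest relative standard error, one row per fit.
#'
#' @param fits named list of `fit_result` objects fitted to the same dataset.
#' @param rse optional named list of RSE vectors aligned with `fits`.
#' @return data.frame, one row per model.
#' @export
compare_models <- function(fits, rse = NULL) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  sums <- vapply(fits, function(f) .obj_md5(f$data$events), character(1))
  if (length(unique(sums)) > 1)
    stop("fits were made on different datasets; comparison is not meaningful")
  rows <- lapply(seq_along(fits), function(j) {
    f <- fits[[j]]
    est <- f$estimates
    nm <- names(fits)[j]
    data.frame(
      model = if (is.null(nm) || is.na(nm) || nm == "") paste0("fit", j) else nm,
      method = f$method,
      n_fixed = length(est$fixed),
      ofv = f$ofv, ofv_se = f$ofv_se,
      error_pk_a = if (!is.null(est$error$pk) && "a" %in% names(est$error$pk))
        est$error$pk[["a"]] else NA,
      error_pk_b = if (!is.null(est$error$pk)) est$error$pk[["b"]] else NA,
      error_pd_b = if (!is.null(est$error$pd)) est$error$pd[["b"]] else NA,
      iiv_cv = paste(names(est$iiv),
                     round(omega_to_cv(est$iiv), 1), sep = "=", collapse = ";"),
      max_rse = if (!is.null(rse[[j]])) max(rse[[j]]) else NA)
  })
  do.call(rbind, rows)
}
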