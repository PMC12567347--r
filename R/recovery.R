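# Parameter-recovery experiments: simulate a study at the published truth,
# fit it blind from generic initial values, and return the recovered
# population estimates. These are the package's calibration experiments; the
# acceptance script and the test suite both run them (median over seeds).

#' Adult parameter-recovery experiment
#'
#' Simulates an adult-design study (default 40 subjects) at the packaged
#' final adult parameters, then reproduces the staged analysis: a PK-only
#' SAEM fit from generic round-number initial values, followed by the
#' simultaneous PK/PD SAEM fit initialised from the PK estimates. Stage-2
#' annealing is wide for the PD link parameters (ke0, gamma), which start far
#' from their final values, and narrow for the PK fixed effects already
#' pinned down by stage 1.
#'
#' @param seed integer seed driving both simulation and estimation.
#' @param n_subjects simulated study size.
#' @param truth generating [population_spec()].
#' @param covariate_search also run the stepwise covariate search on the
#'   final fit (the generating truth carries no covariate effects, so this
#'   measures the false-selection behaviour of the search).
#' @return named vector of recovered quantities: all fixed effects, IIV CV\%
#'   (`cv_*`), the V1-CL random-effect correlation (`corr_V1_CL`), the
#'   residual-error coefficients, and (with `covariate_search`)
#'   `n_covariates_selected`.
#' @export
adult_recovery <- function(seed, n_subjects = 40, truth = adult_final_spec(),
                           covariate_search = FALSE) {
  ds <- generate_adult_study(
    adult_design(n_subjects = n_subjects, missing_plan = list()),
    truth = truth, seed = seed)
  inc <- apply_adult_inclusion_rules(ds)
  st1 <- fit_settings(n_explore = 150, n_smooth = 60, seed = seed,
                      compute_ofv = FALSE, compute_ebe = FALSE)
  fit_pk <- fit_population(inc$dataset, model_spec(kind = "pk"),
                           .pk_part(default_adult_init()), st1)
  init2 <- default_adult_init()
  init2$fixed[names(fit_pk$estimates$fixed)] <- fit_pk$estimates$fixed
  init2$iiv[names(fit_pk$estimates$iiv)] <- fit_pk$estimates$iiv
  init2$error$pk <- fit_pk$estimates$error$pk
  st2 <- fit_settings(n_explore = 200, n_smooth = 80,
                      seed = derive_seed(seed, "stage2"),
                      art_v0 = c(ka = 0.04, Q = 0.04, V2 = 0.04,
                                 ke0 = 0.5, gamma = 0.5),
                      compute_ofv = FALSE, compute_ebe = covariate_search)
  fit <- fit_population(inc$dataset, adult_final_model(), init2, st2)
  est <- fit$estimates
  out <- c(est$fixed,
           setNames(omega_to_cv(est$iiv), paste0("cv_", names(est$iiv))),
           corr_V1_CL = est$correlations[[1]][[3]],
           err_pk_a = est$error$pk[["a"]], err_pk_b = est$error$pk[["b"]],
           err_pd_b = est$error$pd[["b"]])
  if (covariate_search) {
    cs <- lrt_stepwise_covariates(inc$dataset, fit, nmc = 300,
                                  seed = derive_seed(seed, "covsearch"))
    out <- c(out, n_covariates_selected = length(cs$selected))
  }
  out
}

#' Paediatric parameter-recovery experiment
#'
#' Simulates a paediatric sparse study (default 200 subjects) at the packaged
#' final paediatric parameters and fits the direct full-inhibition Imax model
#' (IIV on IC50 only, proportional error) by Gauss-Hermite maximum
#' likelihood from generic initial values.
#'
#' @inheritParams adult_recovery
#' @return named vector: `E0`, `IC50`, `cv_IC50`, `err_pd_b`.
#' @export
paediatric_recovery <- function(seed, n_subjects = 200,
                                truth = paediatric_final_spec()) {
  ds <- generate_paediatric_study(paediatric_design(n_subjects = n_subjects),
                                  truth = truth, seed = seed)
  exc <- apply_paediatric_exclusion_rules(ds)
  fit <- fit_population(exc$dataset, paediatric_final_model(),
                        default_paediatric_init(),
                        fit_settings(seed = seed, compute_ofv = FALSE,
                                     compute_ebe = FALSE))
  est <- fit$estimates
  c(E0 = est$fixed[["E0"]], IC50 = est$fixed[["IC50"]],
    cv_IC50 = omega_to_cv(est$iiv[["IC50"]]), err_pd_b = est$error$pd[["b"]])
}

#' Median recovery over replicate seeds
#'
#' @param fun one of [adult_recovery()] / [paediatric_recovery()].
#' @param seed master seed; replicate seeds are derived from it.
#' @param n_seeds number of replicates (>= 10 for the calibration runs).
#' @param ... forwarded to `fun`.
#' @return list with `median` (named vector) and `replicates` (matrix).
#' @export
recovery_median <- function(fun, seed, n_seeds = 10, ...) {
  first <- fun(seed = derive_seed(seed, "rep1"), ...)
  reps <- matrix(NA_real_, length(first), n_seeds,
                 dimnames = list(names(first), NULL))
  reps[, 1] <- first
  for (k in seq_len(n_seeds)[-1])
    reps[, k] <- fun(seed = derive_seed(seed, paste0("rep", k)), ...)
  list(median = apply(reps, 1, median), replicates = reps)
}
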