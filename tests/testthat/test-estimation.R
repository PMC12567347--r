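# A toy one-compartment oral dataset with known parameters and additive
# noise; used for the direct-ML / NLS cross-check.
toy_1cmt <- function(seed = 1, n_sub = 4, noise = 0.1) {
  truth <- c(ka = 1.2, CL = 5, V1 = 50)
  times <- seq(0.25, 24, length.out = 50)
  k <- truth[["CL"]] / truth[["V1"]]
  f <- 1000 * truth[["ka"]] / (truth[["V1"]] * (truth[["ka"]] - k)) *
    (exp(-k * times) - exp(-truth[["ka"]] * times))
  ev <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
    set.seed(seed + i)
    y <- f + rnorm(length(f), 0, noise)
    rbind(data.frame(ID = i, TIME = 0, EVID = 1, AMT = 1000, DVID = NA,
                     DV = NA, CENS = NA, LIMIT = NA, TAG = ""),
          data.frame(ID = i, TIME = times, EVID = 0, AMT = NA, DVID = 1,
                     DV = y, CENS = 0, LIMIT = NA, TAG = ""))
  }))
  cov <- data.frame(ID = seq_len(n_sub), AGE = 25, WT = 70, BMI = 22, SEX = 0,
                    ROSS = NA, AETIOL = NA)
  study_dataset(ev, cov, "adult")
}

test_that("direct ML on a no-IIV model matches a nonlinear least-squares
           oracle to four significant digits", {
  ds <- toy_1cmt()
  m <- model_spec("pk", absorption = "first_order", disposition = "1cmt")
  init <- population_spec(fixed = c(ka = 2, CL = 8, V1 = 30),
                          error = list(pk = c(a = 0.5)))
  fit <- fit_population(ds, m, init, fit_settings(seed = 1), method = "ml")
  # independent oracle: nls on the Bateman solution written out explicitly
  obs <- ds$events[ds$events$EVID == 0, ]
  or <- nls(DV ~ 1000 * ka / (V1 * (ka - CL / V1)) *
              (exp(-(CL / V1) * TIME) - exp(-ka * TIME)),
            data = obs, start = list(ka = 1.4, CL = 6, V1 = 40),
            algorithm = "port", lower = c(0.1, 0.5, 5),
            control = nls.control(tol = 1e-10, maxiter = 500))
  est <- coef(or)
  for (nm in names(est))
    expect_equal(fit$estimates$fixed[[nm]], est[[nm]], tolerance = 1e-4)
  # additive-error SD agrees with the residual SD (ML denominator n)
  res <- obs$DV - fitted(or)
  expect_equal(fit$estimates$error$pk[["a"]],
               sqrt(mean(res^2)), tolerance = 1e-3)
})

test_that("the no-IIV objective function equals the direct observation sum", {
  ds <- toy_1cmt()
  m <- model_spec("pk", absorption = "first_order", disposition = "1cmt")
  spec <- population_spec(fixed = c(ka = 1.2, CL = 5, V1 = 50),
                          error = list(pk = c(a = 0.1)))
  o <- compute_ofv(ds, m, spec)
  expect_equal(o$mc_se, 0)
  subs <- ratiopkpd:::.prep_subjects(ds, m)
  direct <- sum(vapply(subs, function(sub) {
    f <- concentration_profile(spec$fixed, sub$doses, sub$obs$TIME, m)
    sum(observation_loglik(sub$obs$DV, f, spec$error$pk))
  }, numeric(1)))
  expect_equal(o$ofv, -2 * direct, tolerance = 1e-10)
})

test_that("importance sampling agrees with deterministic quadrature on a
           one-dimensional random effect", {
  ds <- small_paed(seed = 6)
  m <- paediatric_final_model()
  spec <- paediatric_final_spec()
  gh <- compute_ofv(ds, m, spec)            # Gauss-Hermite route
  is1 <- compute_ofv(ds, m, spec, nmc = 500, seed = 4, force_is = TRUE)
  expect_equal(gh$mc_se, 0)
  expect_lt(abs(is1$ofv - gh$ofv), 3 * max(is1$mc_se, 0.5))
  # doubling the Monte-Carlo size moves the estimate by less than the noise
  is2 <- compute_ofv(ds, m, spec, nmc = 1000, seed = 9, force_is = TRUE)
  expect_lt(abs(is2$ofv - is1$ofv), 3 * (is1$mc_se + is2$mc_se + 0.3))
})

test_that("SAEM fits are bit-identical for identical seeds", {
  ds <- apply_adult_inclusion_rules(
    generate_adult_study(adult_design(n_subjects = 4), seed = 2))$dataset
  m <- model_spec("pk")
  init <- ratiopkpd:::.pk_part(default_adult_init())
  st <- fit_settings(n_explore = 25, n_smooth = 10, seed = 7,
                     compute_ofv = FALSE, compute_ebe = FALSE)
  f1 <- fit_population(ds, m, init, st)
  f2 <- fit_population(ds, m, init, st)
  expect_identical(ratiopkpd:::.flatten_spec(f1$estimates),
                   ratiopkpd:::.flatten_spec(f2$estimates))
  st2 <- st; st2$seed <- 8
  f3 <- fit_population(ds, m, init, st2)
  expect_false(identical(f1$estimates$fixed, f3$estimates$fixed))
})

test_that("interval-censoring the BLQ concentrations matters: dropping them
           biases apparent clearance upward", {
  ds <- apply_adult_inclusion_rules(
    generate_adult_study(adult_design(n_subjects = 12,
                                      missing_plan = list()), seed = 31))$dataset
  m <- model_spec("pk")
  init <- ratiopkpd:::.pk_part(default_adult_init())
  st <- lean_settings(seed = 31)
  fit_cens <- fit_population(ds, m, init, st)
  dropped <- ds
  dropped$events <- dropped$events[!(dropped$events$EVID == 0 &
                                       dropped$events$CENS == 1), ]
  fit_drop <- fit_population(dropped, m, init, st)
  expect_gt(fit_drop$estimates$fixed[["CL"]], fit_cens$estimates$fixed[["CL"]])
})

test_that("EBE correlation test flags a strong pair and handles degenerate
           input", {
  set.seed(5)
  E0 <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit0 <- structure(list(ebes = E0), class = "fit_result")
  out0 <- correlation_test_random_effects(fit0)
  expect_false(any(out0$flagged))
  r <- 0.84
  z <- rnorm(40)
  E1 <- cbind(V1 = r * z + sqrt(1 - r^2) * rnorm(40), CL = z)
  out1 <- correlation_test_random_effects(
    structure(list(ebes = E1), class = "fit_result"))
  expect_true(out1$flagged)
  expect_lt(abs(out1$r - 0.84), 0.15)
  E2 <- cbind(a = rep(1, 10), b = rnorm(10))
  expect_warning(correlation_test_random_effects(
    structure(list(ebes = E2), class = "fit_result")), "constant")
  expect_error(correlation_test_random_effects(
    structure(list(ebes = E1[1:2, ]), class = "fit_result")), "three subjects")
})

test_that("the stepwise covariate search uses the chi-square(1) threshold and
           retains nothing on covariate-free data", {
  ds <- small_paed(seed = 16, n = 40)
  fit <- fit_population(ds, paediatric_final_model(),
                        default_paediatric_init(),
                        fit_settings(seed = 16, compute_ofv = FALSE))
  res <- lrt_stepwise_covariates(ds, fit, candidates = c("AGE", "WT", "SEX"),
                                 seed = 3)
  # threshold verified against an independently computed chi-square quantile
  expect_equal(res$threshold_forward, qchisq(0.99, df = 1))
  expect_equal(res$threshold_forward, 6.635, tolerance = 1e-3)
  expect_length(res$selected, 0)
  expect_true(all(res$log$decision[res$log$step == "forward"] == "rejected"))
  # constant candidates are skipped with a log entry
  ds2 <- ds
  ds2$covariates$AGE <- 1
  fit2 <- fit
  fit2$data <- ds2
  res2 <- lrt_stepwise_covariates(ds2, fit2, candidates = c("AGE"), seed = 3)
  expect_match(res2$log$decision[1], "constant")
  expect_length(res2$selected, 0)
})

test_that("the adult PK fit reports finite relative standard errors for
           every parameter", {
  ds <- apply_adult_inclusion_rules(
    generate_adult_study(adult_design(n_subjects = 20, missing_plan = list()),
                         seed = 61))$dataset
  fit <- fit_population(ds, model_spec("pk"),
                        ratiopkpd:::.pk_part(default_adult_init()),
                        fit_settings(n_explore = 80, n_smooth = 30, seed = 61,
                                     compute_ofv = FALSE))
  rse <- estimate_rse(fit, method = "fim", seed = 6, nmc = 60)
  expect_true(all(is.finite(rse)))
  expect_true(all(rse > 0))
  expect_length(rse[names(fit$estimates$fixed)], 7)
})

test_that("relative standard errors: near-zero at high information, finite
           and cross-method consistent on the paediatric fit", {
  ds <- toy_1cmt(noise = 0.02)
  m <- model_spec("pk", absorption = "first_order", disposition = "1cmt")
  init <- population_spec(fixed = c(ka = 2, CL = 8, V1 = 30),
                          error = list(pk = c(a = 0.5)))
  fit <- fit_population(ds, m, init, fit_settings(seed = 1), method = "ml")
  rse <- estimate_rse(fit, method = "fim", seed = 2)
  expect_true(all(is.finite(rse)))
  expect_lt(max(rse[c("ka", "CL", "V1")]), 1)  # <1% at this information level

  ds2 <- small_paed(seed = 18, n = 60)
  fit2 <- fit_population(ds2, paediatric_final_model(),
                         default_paediatric_init(),
                         fit_settings(seed = 18, compute_ofv = FALSE))
  fim <- estimate_rse(fit2, method = "fim", seed = 5)
  expect_warning(estimate_rse(fit2, method = "bootstrap", B = 5, seed = 5),
                 "B < 20")
  boot <- suppressWarnings(
    estimate_rse(fit2, method = "bootstrap", B = 30, seed = 5))
  shared <- intersect(names(fim), names(boot))
  shared <- shared[is.finite(fim[shared]) & is.finite(boot[shared])]
  expect_true(all(fim[shared] / boot[shared] < 2 &
                    boot[shared] / fim[shared] < 2))
})
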