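test_that("CV% <-> omega transform is exact and invertible", {
  expect_equal(cv_to_omega(0), 0)
  for (cv in c(10, 50, 200))
    expect_equal(omega_to_cv(cv_to_omega(cv)), cv, tolerance = 1e-12)
  # root-finding oracle on the forward map for the largest reported IIV
  om <- uniroot(function(w) omega_to_cv(w) - 141.9, c(0.1, 3), tol = 1e-12)$root
  expect_equal(cv_to_omega(141.9), om, tolerance = 1e-9)
  expect_equal(cv_to_omega(141.9), 1.0503, tolerance = 1e-4)
  expect_error(cv_to_omega(-5), "non-negative")
})

test_that("individual parameters realise fixed effects, IIV and links", {
  spec <- population_spec(
    fixed = c(CL = 10, V1 = 50),
    iiv = c(CL = 0.3),
    error = list(pk = c(a = 0.1, b = 0.1)),
    covariate_links = list(list(param = "CL", covariate = "WT",
                                form = "power_scaled", beta = 0.75, ref = 70)))
  th0 <- realise_individual(spec, eta = c(CL = 0), covariates = list(WT = 70))
  expect_equal(unname(th0), c(10, 50))
  th1 <- realise_individual(spec, eta = c(CL = 0), covariates = list(WT = 140))
  expect_equal(th1[["CL"]], 10 * 2^0.75)
  expect_equal(th1[["CL"]] / 10, 1.6818, tolerance = 1e-4)
  th2 <- realise_individual(spec, eta = c(CL = log(2)), covariates = list(WT = 70))
  expect_equal(th2[["CL"]], 20)
  expect_error(realise_individual(spec, covariates = list()), "WT")
  # categorical exponential link
  spec2 <- population_spec(fixed = c(CL = 10), iiv = c(CL = 0.1),
                           error = list(pk = c(b = 0.1)),
                           covariate_links = list(list(
                             param = "CL", covariate = "SEX",
                             form = "exponential_categorical",
                             beta = 0.2, ref = 0)))
  expect_equal(realise_individual(spec2, c(CL = 0), list(SEX = 1))[["CL"]],
               10 * exp(0.2))
})

test_that("correlated random effects reproduce the specified correlation", {
  spec <- adult_final_spec()
  E <- with(list(), {set.seed(11); draw_etas(spec, 1e5)})
  expect_equal(cor(E[, "V1"], E[, "CL"]), 0.84, tolerance = 0.01)
  # simulated-then-summarised IIV: CV% recovered within 1% relative
  cv_cl <- 100 * sd(exp(E[, "CL"])) / mean(exp(E[, "CL"]))
  expect_equal(cv_cl, 30.17, tolerance = 0.01)
  # the CV estimator of a 141.9% lognormal is heavy-tailed (4th-moment
  # driven), so its own sampling error at this n is a few percent
  cv_e0 <- 100 * sd(exp(E[, "E0"])) / mean(exp(E[, "E0"]))
  expect_equal(cv_e0, 141.9, tolerance = 0.05)
})

test_that("a non-positive-definite Omega is rejected on construction", {
  expect_error(population_spec(
    fixed = c(a = 1, b = 1, c = 1),
    iiv = c(a = 0.3, b = 0.3, c = 0.3),
    correlations = list(list("a", "b", 0.95), list("a", "c", 0.95),
                        list("b", "c", -0.9)),
    error = list(pk = c(b = 0.1))), "positive definite")
  expect_error(population_spec(fixed = c(a = 1), iiv = c(a = 0.1),
                               correlations = list(list("a", "a", 1.2)),
                               error = list()), "< 1")
})

test_that("censored observations contribute the interval probability", {
  coefs <- c(a = 0.42, b = 0.072)
  expect_equal(error_sd(10, coefs), 1.14)
  # total mass: an infinitely wide interval has log-probability ~ 0
  ll_all <- observation_loglik(y = 1e9, f = 5, coefs, cens = 1,
                               lower = 0, upper = 1e9)
  expect_lt(abs(ll_all), 1e-9)
  # quadrature oracle: trapezoid integration of the Gaussian density
  f <- 1.1; lloq <- 0.7; sd <- error_sd(f, coefs)
  x <- seq(0, lloq, length.out = 1e6 + 1)
  trap <- sum((dnorm(x[-1], f, sd) + dnorm(x[-length(x)], f, sd)) / 2) * diff(x)[1]
  ll <- observation_loglik(lloq, f, coefs, cens = 1, lower = 0, upper = lloq)
  expect_equal(ll, log(trap), tolerance = 1e-10)
  # continuity: censored and uncensored contributions stay finite near LLOQ
  eps <- c(1e-3, 1e-6, 1e-9)
  unc <- observation_loglik(lloq + eps, f, coefs)
  expect_true(all(is.finite(unc)))
  expect_error(observation_loglik(0.5, 5, coefs, cens = 1, lower = 0, upper = -1),
               "LLOQ")
  expect_error(observation_loglik(0.5, 5, c(a = 0, b = 0)), "> 0")
})

test_that("combined2 error form is available as a sensitivity option", {
  expect_equal(error_sd(10, c(a = 3, b = 0.4), form = "combined2"), 5)
})

test_that("population specs round-trip through YAML configs", {
  spec <- adult_final_spec()
  f <- tempfile(fileext = ".yaml")
  write_population_spec(spec, f)
  spec2 <- read_population_spec(f)
  expect_equal(spec2$fixed, spec$fixed)
  expect_equal(spec2$iiv, spec$iiv, tolerance = 1e-9)
  expect_equal(spec2$correlations[[1]][[3]], 0.84)
  expect_equal(spec2$error$pk, spec$error$pk)
})

test_that("packaged final specs carry the published parameter sets", {
  ad <- adult_final_spec()
  expect_equal(ad$fixed[["CL"]], 36.39)
  expect_equal(ad$fixed[["E0"]], 0.043)
  expect_equal(omega_to_cv(ad$iiv[["CL"]]), 30.17, tolerance = 1e-9)
  pd <- paediatric_final_spec()
  expect_equal(pd$fixed[["IC50"]], 1.19)
  expect_equal(omega_to_cv(pd$iiv[["IC50"]]), 59.92, tolerance = 1e-9)
})
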