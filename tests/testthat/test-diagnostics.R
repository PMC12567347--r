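test_that("hysteresis is clockwise with a slow effect compartment and
           vanishes in the direct-effect limit", {
  p <- adult_true_params()
  m <- model_spec("pkpd")
  tt <- c(0.5, 1, 2, 3, 4, 5, 6, 7, 8, 24)
  conc <- concentration_profile(p, single_dose_regimen(), tt, m)
  ratio <- ratiopkpd:::.predict_obs(m, p, single_dose_regimen(), tt,
                                    rep(2, length(tt)))
  h <- hysteresis_metric(conc, ratio, times = tt)
  expect_equal(h$direction, "clockwise")
  expect_lt(h$area, 0)
  # direct effect (instant equilibration): the loop collapses - an exactly
  # retraced path has zero signed area, and on the sampled schedule the
  # direct-effect "loop" is orders of magnitude smaller than the true one
  ratio_direct <- imax_ratio(conc, p[["E0"]], p[["IC50"]], 1, p[["gamma"]])
  h2 <- hysteresis_metric(conc, ratio_direct, times = tt)
  expect_lt(abs(h2$area), 0.05 * abs(h$area))
  up <- seq(0, 60, length.out = 25)
  retrace <- hysteresis_metric(c(up, rev(up)),
                               imax_ratio(c(up, rev(up)), 0.043, 30.01, 1, 2))
  expect_equal(retrace$direction, "none")
  expect_equal(retrace$area, 0)
  # shoelace antisymmetry under traversal reversal
  h3 <- hysteresis_metric(rev(conc), rev(ratio))
  expect_equal(h3$area, -h$area)
  expect_error(hysteresis_metric(conc[1:3], ratio[1:3]), "4")
  expect_error(hysteresis_metric(conc, ratio, times = rev(tt)), "increasing")
})

test_that("percent change at 4 h: arithmetic, median, scale invariance", {
  expect_equal(percent_change_4h(data.frame(ratio_predose = 0.2,
                                            ratio_4h = 0.2))$median, 0)
  expect_equal(percent_change_4h(data.frame(ratio_predose = 0.20,
                                            ratio_4h = 0.04))$median, 80)
  paired <- data.frame(ratio_predose = c(0.2, 0.3, 0.1),
                       ratio_4h = c(0.04, 0.09, 0.05))
  res <- percent_change_4h(paired)
  expect_equal(res$median, median(c(80, 70, 50)))
  expect_equal(res$median, 70)
  expect_equal(res$range, c(50, 80))
  scaled <- percent_change_4h(paired * 3.7)
  expect_equal(scaled$percent_change, res$percent_change)
  expect_warning(percent_change_4h(data.frame(ratio_predose = c(0.2, 0),
                                              ratio_4h = c(0.1, 0.1))),
                 "non-positive")
})

test_that("VPC bands collapse onto the population curve when all
           variability is zero", {
  truth <- paediatric_final_spec()
  truth$iiv[] <- 0
  truth$error$pd[] <- 0
  ds <- generate_paediatric_study(paediatric_design(n_subjects = 20),
                                  truth = truth, seed = 5)
  exc <- apply_paediatric_exclusion_rules(ds)
  v <- vpc(exc$dataset, paediatric_final_model(), truth, nsim = 120,
           bin_on = "tsld", seed = 2)
  pdb <- v$bands[v$bands$stream == "pd", ]
  expect_equal(pdb$pi_lower, pdb$observed, tolerance = 1e-9)
  expect_equal(pdb$pi_upper, pdb$observed, tolerance = 1e-9)
  expect_false(any(pdb$outside))
  expect_equal(v$nsim, 120)
  expect_equal(v$quantile_type, 7)
  expect_error(vpc(exc$dataset, paediatric_final_model(), truth, nsim = 50),
               "100")
})

test_that("observed VPC percentiles are invariant to observation order", {
  ds <- small_paed(seed = 7)
  m <- paediatric_final_model()
  truth <- paediatric_final_spec()
  v1 <- vpc(ds, m, truth, nsim = 100, bin_on = "tsld", seed = 3)
  shuf <- ds
  set.seed(1)
  shuf$events <- shuf$events[sample(nrow(shuf$events)), ]
  shuf$events <- shuf$events[order(shuf$events$ID, shuf$events$TIME,
                                   shuf$events$EVID, shuf$events$DVID), ]
  v2 <- vpc(shuf, m, truth, nsim = 100, bin_on = "tsld", seed = 3)
  expect_equal(v2$bands$observed, v1$bands$observed)
})

test_that("GOF residuals are exact zeros on noiseless data and standard
           normal under the generating model", {
  truth <- adult_final_spec()
  quiet <- truth
  quiet$error$pk[] <- c(0, 0)   # noise-free generation
  quiet$error$pd[] <- 0
  ds <- generate_adult_study(adult_design(n_subjects = 6), truth = quiet,
                             seed = 9)
  inc <- apply_adult_inclusion_rules(ds)
  m <- adult_final_model()
  quiet$error <- truth$error    # residual model with positive sd for IWRES
  fit <- structure(list(estimates = quiet, model = m,
                        subjects = ratiopkpd:::.prep_subjects(inc$dataset, m),
                        ebes = attr(ds, "truth_etas"), data = inc$dataset),
                   class = "fit_result")
  g <- gof(inc$dataset, m, fit)
  expect_lt(max(abs(g$table$IWRES)), 1e-6)
  expect_true(all(g$censored$CENS == 1))
  expect_false("IWRES" %in% names(g$censored))

  # with the true error model, IWRES is standard normal: ~4.6% beyond |2|
  ds2 <- generate_adult_study(adult_design(n_subjects = 40,
                                           missing_plan = list()),
                              truth = truth, seed = 21)
  inc2 <- apply_adult_inclusion_rules(ds2)
  fit2 <- structure(list(estimates = truth, model = m,
                         subjects = ratiopkpd:::.prep_subjects(inc2$dataset, m),
                         ebes = attr(ds2, "truth_etas"), data = inc2$dataset),
                    class = "fit_result")
  g2 <- gof(inc2$dataset, m, fit2)
  frac <- mean(abs(g2$table$IWRES) > 2)
  expect_gt(frac, 0.046 - 0.02)
  expect_lt(frac, 0.046 + 0.02)
  expect_error(gof(inc2$dataset, m, structure(list(ebes = NULL),
                                              class = "fit_result")),
               "empirical Bayes")
})

test_that("the comparison overlay re-indexes, tags and never alters values", {
  adult <- apply_adult_inclusion_rules(generate_adult_study(seed = 14))$dataset
  afit <- structure(list(estimates = adult_final_spec(),
                         model = adult_final_model(), data = adult),
                    class = "fit_result")
  paed <- apply_paediatric_exclusion_rules(
    generate_paediatric_study(seed = 14))$dataset
  ov <- comparison_overlay(afit, paed, nsim = 150, seed = 14)
  pts <- ov$points
  # partition into the six symbol classes
  expect_true(all(pts$dose_class %in% c("predose_first", "post_first",
                                        "post_repeated")))
  expect_true(all(pts$blq_class %in% c("quantified", "substituted")))
  expect_equal(pts$symbol, paste(pts$dose_class, pts$blq_class, sep = "/"))
  # values are re-indexed, never altered
  dv <- paed$events$DV[paed$events$EVID == 0 & paed$events$DVID == 2]
  expect_equal(sort(pts$ratio), sort(dv))
  expect_true(all(pts$tsld[pts$dose_class == "predose_first"] == 0))
  # paediatric baseline ratios (E0 = 0.19) sit above the adult median band
  # (E0 = 0.043) near t = 0
  first_bin <- min(ov$bands$bin_mid)
  med_band <- ov$bands$pi_upper[ov$bands$bin_mid == first_bin &
                                  ov$bands$percentile == 50]
  expect_gt(median(pts$ratio[pts$dose_class == "predose_first"]), med_band)
})
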