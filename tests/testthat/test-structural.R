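p2 <- adult_true_params()

test_that("transit input vanishes at dose time and conserves mass", {
  expect_equal(transit_input_rate(0, 20000, 5.31, 1.46), 0)
  expect_true(all(transit_input_rate(seq(0, 48, 0.5), 20000, 5.31, 1.46) >= 0))
  mass <- integrate(function(s) transit_input_rate(s, 20000, 5.31, 1.46),
                    0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, 20000, tolerance = 1e-6)
  expect_error(transit_input_rate(1, 100, ktr = 0.5, mtt = 1), "ktr\\*Mtt > 1")
})

test_that("transit input peaks at n/ktr (grid-search oracle)", {
  n <- 5.31 * 1.46 - 1
  grid <- seq(0.01, 5, by = 1e-4)
  peak_grid <- grid[which.max(transit_input_rate(grid, 1000, 5.31, 1.46))]
  expect_equal(peak_grid, n / 5.31, tolerance = 1e-3)
})

test_that("semi-analytic disposition matches an independent RK4 oracle", {
  tt <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 24, 48, 72)
  oracle <- rk4_profile(p2, 20000, tt)
  conc <- concentration_profile(p2, single_dose_regimen(), tt,
                                model_spec("pkpd"))
  expect_equal(conc, oracle$conc, tolerance = 1e-3)
  ce <- ratiopkpd:::.profile(p2, single_dose_regimen(), tt,
                             model_spec("pkpd"), effect = TRUE)
  expect_equal(ce, oracle$ce, tolerance = 1e-3)
})

test_that("profiles are zero predose, linear in dose, and superpose", {
  m <- model_spec("pkpd")
  expect_equal(concentration_profile(p2, single_dose_regimen(), 0, m), 0)
  tt <- c(1, 4, 24)
  c1 <- concentration_profile(p2, single_dose_regimen(20000), tt, m)
  c2 <- concentration_profile(p2, single_dose_regimen(40000), tt, m)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  reg2 <- data.frame(time = c(0, 12), amount = c(20000, 20000))
  tt2 <- c(13, 16, 24, 36)
  multi <- concentration_profile(p2, reg2, tt2, m)
  shifted <- concentration_profile(p2, single_dose_regimen(), tt2, m) +
    concentration_profile(p2, single_dose_regimen(), tt2 - 12, m)
  expect_equal(multi, shifted, tolerance = 1e-10)
})

test_that("lag-time absorption shifts the profile", {
  pl <- c(tlag = 0.5, ka = 1.19, CL = 36.39, V1 = 223.71, Q = 6.38, V2 = 108.26)
  m <- model_spec("pk", absorption = "lag")
  expect_equal(concentration_profile(pl, single_dose_regimen(), c(0.2, 0.5), m),
               c(0, 0))
  expect_gt(concentration_profile(pl, single_dose_regimen(), 1, m), 0)
  # with the lag removed, the profile equals the plain first-order model
  pf <- pl[-1]
  mf <- model_spec("pk", absorption = "first_order")
  tt <- c(1, 4, 8)
  pl0 <- pl; pl0[["tlag"]] <- 1e-12
  expect_equal(concentration_profile(pl0, single_dose_regimen(), tt, m),
               concentration_profile(pf, single_dose_regimen(), tt, mf),
               tolerance = 1e-6)
})

test_that("effect-site equilibration has the right closed-form limits", {
  ke0 <- 0.48
  tt <- sort(unique(c(seq(0, 20, by = 0.01), log(2) / ke0)))
  cc <- rep(10, length(tt))
  ce <- effect_site_profile(tt, cc, ke0)
  # constant input: Ce(t) = c (1 - exp(-ke0 t)); half the input at t = ln2/ke0
  i <- which(tt == log(2) / ke0)
  expect_equal(ce[i], 5, tolerance = 1e-9)
  expect_equal(ce[length(tt)], 10 * (1 - exp(-ke0 * 20)), tolerance = 1e-6)
  # very fast equilibration: Ce tracks C pointwise
  conc <- concentration_profile(p2, single_dose_regimen(), tt[-1],
                                model_spec("pkpd"))
  ce_fast <- effect_site_profile(tt[-1], conc, 1e4)
  expect_equal(ce_fast[-(1:5)], conc[-(1:5)], tolerance = 1e-3)
  expect_error(effect_site_profile(tt, cc, -1), "k_e0")
})

test_that("the Imax ratio model honours its anchor points", {
  expect_equal(imax_ratio(0, e0 = 0.043, ic50 = 30.01, gamma = 2.02), 0.043)
  for (g in c(0.5, 1, 2.02, 4))
    expect_equal(imax_ratio(30.01, 0.043, 30.01, imax = 1, gamma = g),
                 0.043 / 2)
  # direct arithmetic at Ce = 2 IC50
  expect_equal(imax_ratio(2 * 30.01, 0.043, 30.01, 1, 2.02),
               0.043 * (1 - 2^2.02 / (2^2.02 + 1)))
  # monotone non-increasing and full-inhibition asymptote
  ce <- seq(0, 500, length.out = 100)
  r <- imax_ratio(ce, 0.043, 30.01, 1, 2.02)
  expect_true(all(diff(r) <= 0))
  expect_lt(imax_ratio(1e6, 0.043, 30.01, 1, 2.02), 1e-6)
  # partial inhibition floor
  expect_equal(imax_ratio(1e9, 0.043, 30.01, imax = 0.8, gamma = 1),
               0.043 * 0.2, tolerance = 1e-6)
  expect_error(imax_ratio(-1, 0.043, 30.01), ">= 0")
})

test_that("both transit-stage conventions are available and differ", {
  m1 <- model_spec("pk", transit_convention = "mtt_minus_one")
  m2 <- model_spec("pk", transit_convention = "mtt")
  pk <- p2[c("ktr", "Mtt", "ka", "CL", "V1", "Q", "V2")]
  c1 <- concentration_profile(pk, single_dose_regimen(), 1, m1)
  c2 <- concentration_profile(pk, single_dose_regimen(), 1, m2)
  expect_false(isTRUE(all.equal(c1, c2)))
})

test_that("integer transit-chain cross-check: the gamma-flow input matches
           an explicit compartment chain when n is an integer", {
  # four explicit transit stages give a gamma input of shape n = 3,
  # i.e. ktr * Mtt - 1 = 3
  ktr <- 4; mtt <- 1
  pk <- c(ktr = ktr, Mtt = mtt, ka = 1.19, CL = 36.39, V1 = 223.71,
          Q = 6.38, V2 = 108.26)
  tt <- c(0.5, 1, 2, 4, 8)
  semi <- concentration_profile(pk, single_dose_regimen(1000), tt,
                                model_spec("pk"))
  # explicit chain of 4 transit compartments + absorption + 2-cmt by RK4
  k10 <- pk[["CL"]] / pk[["V1"]]; k12 <- pk[["Q"]] / pk[["V1"]]
  k21 <- pk[["Q"]] / pk[["V2"]]
  deriv <- function(t, y) {
    c(-ktr * y[1],
      ktr * (y[1] - y[2]), ktr * (y[2] - y[3]), ktr * (y[3] - y[4]),
      ktr * y[4] - pk[["ka"]] * y[5],
      pk[["ka"]] * y[5] - (k10 + k12) * y[6] + k21 * y[7],
      k12 * y[6] - k21 * y[7])
  }
  h <- 5e-4; y <- c(1000, 0, 0, 0, 0, 0, 0); t <- 0; out <- numeric(0)
  for (s in seq_len(8 / h)) {
    k1 <- deriv(t, y); k2 <- deriv(t + h / 2, y + h / 2 * k1)
    k3 <- deriv(t + h / 2, y + h / 2 * k2); k4 <- deriv(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4); t <- t + h
    if (any(abs(t - tt) < h / 2)) out <- c(out, y[6] / pk[["V1"]])
  }
  expect_equal(semi, out, tolerance = 2e-3)
})
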