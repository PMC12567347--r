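# Shared fixtures: parameter sets and small seeded datasets built in code.

adult_true_params <- function() {
  c(ktr = 5.31, Mtt = 1.46, ka = 1.19, CL = 36.39, V1 = 223.71, Q = 6.38,
    V2 = 108.26, ke0 = 0.48, gamma = 2.02, E0 = 0.043, IC50 = 30.01)
}

single_dose_regimen <- function(amount = 20000) data.frame(time = 0, amount = amount)

# Hand-rolled fixed-step RK4 integrator of the full transit/2-cmt/effect
# system; independent of the package's semi-analytic solver.
rk4_profile <- function(p, dose, times, h = 0.002) {
  k10 <- p[["CL"]] / p[["V1"]]; k12 <- p[["Q"]] / p[["V1"]]; k21 <- p[["Q"]] / p[["V2"]]
  n <- p[["ktr"]] * p[["Mtt"]] - 1
  rate_in <- function(t) if (t <= 0) 0 else
    dose * exp(log(p[["ktr"]]) + n * (log(p[["ktr"]]) + log(t)) -
                 p[["ktr"]] * t - lgamma(n + 1))
  deriv <- function(t, y) c(
    rate_in(t) - p[["ka"]] * y[1],
    p[["ka"]] * y[1] - (k10 + k12) * y[2] + k21 * y[3],
    k12 * y[2] - k21 * y[3],
    p[["ke0"]] * (y[2] / p[["V1"]] - y[4]))
  y <- c(0, 0, 0, 0); t <- 0
  out <- matrix(NA_real_, length(times), 2)
  ti <- 1
  nmax <- ceiling(max(times) / h)
  for (s in seq_len(nmax)) {
    k1 <- deriv(t, y); k2 <- deriv(t + h / 2, y + h / 2 * k1)
    k3 <- deriv(t + h / 2, y + h / 2 * k2); k4 <- deriv(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4); t <- t + h
    while (ti <= length(times) && t >= times[ti] - h / 2) {
      out[ti, ] <- c(y[2] / p[["V1"]], y[4]); ti <- ti + 1
    }
  }
  list(conc = out[, 1], ce = out[, 2])
}

# Reduced-size estimation settings for fast deterministic tests.
lean_settings <- function(seed = 1, ...) {
  fit_settings(n_explore = 60, n_smooth = 30, seed = seed,
               compute_ofv = FALSE, compute_ebe = FALSE, ...)
}

small_paed <- function(seed = 1, n = 27, ...) {
  apply_paediatric_exclusion_rules(
    generate_paediatric_study(paediatric_design(n_subjects = n, ...),
                              seed = seed))$dataset
}
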