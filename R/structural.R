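#' Structural model selection
#'
#' Defines one deterministic forward model out of the family explored during
#' model development: oral absorption (transit-compartment input, lag time, or
#' plain first-order), one- or two-compartment linear disposition, a direct or
#' effect-compartment concentration-effect link, and a full- or
#' partial-inhibition Imax model with fixed or estimated sigmoidicity.
#'
#' @param kind `"pkpd"` (joint concentration + ratio model), `"pk"`
#'   (concentration only) or `"pd_obsconc"` (ratio only, with measured
#'   concentrations supplied as input data).
#' @param absorption `"transit"`, `"lag"` or `"first_order"`.
#' @param disposition `"2cmt"` or `"1cmt"`.
#' @param pd_link `"effect_compartment"` or `"direct"`.
#' @param inhibition `"full"` (Imax fixed at 1) or `"partial"` (Imax estimated).
#' @param hill `"estimated"` (sigmoidicity gamma a parameter) or `"fixed1"`.
#' @param transit_convention shape of the continuous transit chain:
#'   `"mtt_minus_one"` uses n = k_tr*Mtt - 1 (default), `"mtt"` uses
#'   n = k_tr*Mtt; both are offered because published transit
#'   parameterisations differ by one stage.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(kind = c("pkpd", "pk", "pd_obsconc"),
                       absorption = c("transit", "lag", "first_order"),
                       disposition = c("2cmt", "1cmt"),
                       pd_link = c("effect_compartment", "direct"),
                       inhibition = c("full", "partial"),
                       hill = c("estimated", "fixed1"),
                       transit_convention = c("mtt_minus_one", "mtt")) {
  m <- list(kind = match.arg(kind), absorption = match.arg(absorption),
            disposition = match.arg(disposition), pd_link = match.arg(pd_link),
            inhibition = match.arg(inhibition), hill = match.arg(hill),
            transit_convention = match.arg(transit_convention))
  class(m) <- "model_spec"
  m
}

#' Parameter names required by a structural model
#' @param model a [model_spec()].
#' @return character vector of structural parameter names.
#' @export
param_names <- function(model) {
  nm <- character(0)
  if (model$kind != "pd_obsconc") {
    nm <- c(nm, switch(model$absorption,
                       transit = c("ktr", "Mtt", "ka"),
                       lag = c("tlag", "ka"),
                       first_order = "ka"))
    nm <- c(nm, switch(model$disposition,
                       `2cmt` = c("CL", "V1", "Q", "V2"),
                       `1cmt` = c("CL", "V1")))
  }
  if (model$kind != "pk") {
    if (model$kind == "pkpd" && model$pd_link == "effect_compartment")
      nm <- c(nm, "ke0")
    nm <- c(nm, "E0", "IC50")
    if (model$hill == "estimated") nm <- c(nm, "gamma")
    if (model$inhibition == "partial") nm <- c(nm, "Imax")
  }
  nm
}

#' Transit-compartment absorption input rate
#'
#' Continuous ("analytic") transit chain: the drug amount flows into the
#' absorption compartment at rate
#' `dose * ktr * (ktr*dt)^n * exp(-ktr*dt) / gamma(n+1)` with shape
#' `n = ktr*Mtt - 1`, i.e. a gamma-density-shaped input whose total mass over
#' \[0, Inf) equals the dose and whose mode sits at `n/ktr`.
#'
#' @param t time(s), hours since the dose.
#' @param dose dose amount (ug).
#' @param ktr transit rate constant (1/h).
#' @param mtt mean transit time (h).
#' @param convention `"mtt_minus_one"` (n = ktr*mtt - 1) or `"mtt"`.
#' @return input rate (ug/h), vectorised over `t`.
#' @export
transit_input_rate <- function(t, dose, ktr, mtt,
                               convention = c("mtt_minus_one", "mtt")) {
  convention <- match.arg(convention)
  if (ktr <= 0 || mtt <= 0 || dose <= 0) stop("dose, ktr and mtt must be > 0")
  n <- if (convention == "mtt") ktr * mtt else ktr * mtt - 1
  if (n <= 0)
    stop("transit parameterisation requires ktr*Mtt > 1 (shape n must be > 0)")
  out <- numeric(length(t))
  pos <- t > 0
  lt <- log(t[pos])
  out[pos] <- dose * exp(log(ktr) + n * (log(ktr) + lt) - ktr * t[pos] - lgamma(n + 1))
  out
}

# ---- internal semi-analytic solver -----------------------------------------

# Exponential-mixture kernel for amount in the central compartment (and,
# optionally, V1 * effect-site concentration) after a unit amount is placed
# in the absorption compartment. Returns list(rates, coefs) so that
# kernel(u) = sum(coefs * exp(-rates * u)).
.pk_kernel <- function(p, model, effect = FALSE) {
  ka <- p[["ka"]]
  two <- model$disposition == "2cmt"
  if (two) {
    v1 <- p[["V1"]]
    k10 <- p[["CL"]] / v1; k12 <- p[["Q"]] / v1; k21 <- p[["Q"]] / p[["V2"]]
    s <- k10 + k12 + k21
    disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
    rates <- c((s + disc) / 2, (s - disc) / 2, ka)
  } else {
    rates <- c(p[["CL"]] / p[["V1"]], ka)
  }
  if (effect) rates <- c(rates, p[["ke0"]])
  n <- length(rates)
  repeat {  # residue formulas assume simple poles; nudge near-degenerate rates
    ok <- TRUE
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (abs(rates[a] - rates[b]) < 1e-7 * max(rates[a], rates[b], 1e-12)) {
        rates[b] <- rates[b] * (1 + 1e-5); ok <- FALSE
      }
    }
    if (ok) break
  }
  coefs <- numeric(n)
  for (j in 1:n) {
    num <- if (two) ka * (k21 - rates[j]) else ka
    if (effect) num <- num * p[["ke0"]]
    coefs[j] <- num / prod(rates[-j] - rates[j])
  }
  list(rates = rates, coefs = coefs)
}

# Convolution of the kernel with a gamma-shaped transit input of unit mass,
# evaluated at elapsed times dt >= 0. Each exponential term is handled in
# closed form through the regularised lower incomplete gamma when its decay
# rate stays below the transit rate; otherwise (fast kernel rates, e.g. a
# large effect-compartment constant) that term's convolution integral is
# evaluated on a Gauss-Legendre grid over the exponential boundary layer.
.transit_response <- function(dt, ktr, n, kern) {
  out <- numeric(length(dt))
  pos <- which(dt > 0)
  if (!length(pos)) return(out)
  d <- dt[pos]
  mu <- ktr - kern$rates
  acc <- 0
  ln_r <- function(s) log(ktr) + n * (log(ktr) + log(pmax(s, 1e-300))) -
    ktr * s - lgamma(n + 1)
  for (j in seq_along(kern$rates)) {
    p <- kern$rates[j]
    if (mu[j] > 1e-4 * ktr) {
      lg <- -p * d + (n + 1) * (log(ktr) - log(mu[j])) +
        pgamma(d, shape = n + 1, rate = mu[j], log.p = TRUE)
      acc <- acc + sign(kern$coefs[j]) * exp(log(abs(kern$coefs[j])) + lg)
    } else {
      # term integral int_0^d r(d-u) e^{-p u} du concentrated near u = 0
      gl <- gauss_legendre(40, 0, 1)
      term <- vapply(d, function(di) {
        w <- min(di, 30 / max(p, 1e-12))
        u <- gl$nodes * w
        w * sum(gl$weights * exp(ln_r(di - u) - p * u))
      }, numeric(1))
      acc <- acc + kern$coefs[j] * term
    }
  }
  out[pos] <- acc
  out
}

# Core forward solve: concentrations (and effect-site concentrations) at
# `times` under `regimen` (data.frame time, amount). Linear kinetics, so
# repeated doses superpose.
.profile <- function(p, regimen, times, model, effect = FALSE) {
  kern <- .pk_kernel(p, model, effect = effect)
  total <- numeric(length(times))
  if (model$absorption == "transit") {
    n <- if (model$transit_convention == "mtt") p[["ktr"]] * p[["Mtt"]] else
      p[["ktr"]] * p[["Mtt"]] - 1
    n <- max(n, 1e-6)  # n -> 0 limit is a plain exponential input
    for (i in seq_len(nrow(regimen))) {
      dt <- times - regimen$time[i]
      total <- total + regimen$amount[i] *
        .transit_response(dt, p[["ktr"]], n, kern)
    }
  } else {
    lag <- if (model$absorption == "lag") p[["tlag"]] else 0
    for (i in seq_len(nrow(regimen))) {
      dt <- times - regimen$time[i] - lag
      v <- numeric(length(dt))
      pos <- dt > 0
      if (any(pos))
        v[pos] <- colSums(kern$coefs * exp(-outer(kern$rates, dt[pos])))
      total <- total + regimen$amount[i] * v
    }
  }
  conc <- total / p[["V1"]]
  if (any(!is.finite(conc)))
    stop("numerical failure in concentration profile (non-finite solution); ",
         "parameters: ", paste(names(p), signif(unlist(p), 4), sep = "=", collapse = ", "))
  pmax(conc, 0)
}

#' Central-compartment concentration profile
#'
#' Solves the linear absorption/disposition system semi-analytically: the
#' disposition impulse response is an exponential mixture obtained by partial
#' fractions, and the transit-compartment input is folded in through the
#' closed-form incomplete-gamma convolution. Repeated doses superpose.
#'
#' @param params named parameter vector (see [param_names()]).
#' @param regimen data.frame with columns `time` (h) and `amount` (ug).
#' @param times observation times (h since first dose).
#' @param model a [model_spec()].
#' @return concentrations (ug/L) at `times`.
#' @export
concentration_profile <- function(params, regimen, times,
                                  model = model_spec(kind = "pk")) {
  params <- unlist(params)
  if (any(params[intersect(names(params), c("ktr","Mtt","ka","CL","V1","Q","V2","ke0"))] <= 0))
    stop("rate, clearance and volume parameters must be > 0")
  stopifnot(all(diff(regimen$time) > 0) || nrow(regimen) <= 1)
  .profile(params, regimen, times, model, effect = FALSE)
}

#' Effect-site concentration from a central concentration time course
#'
#' First-order equilibration dCe/dt = ke0 (C - Ce), Ce(0) = 0, integrated
#' exactly over a piecewise-linear concentration series. Used for linking an
#' arbitrary (e.g. observed) concentration series to the effect site; model
#' predictions use the closed-form kernel instead.
#'
#' @param times sample times (h), strictly increasing, first entry the time
#'   origin where Ce = 0.
#' @param conc central concentrations at `times`.
#' @param k_e0 effect-compartment transfer rate constant (1/h).
#' @return effect-site concentrations at `times`.
#' @export
effect_site_profile <- function(times, conc, k_e0) {
  if (k_e0 < 0) stop("k_e0 must be >= 0")
  stopifnot(length(times) == length(conc), all(diff(times) > 0))
  ce <- numeric(length(times))
  for (i in seq_along(times)[-1]) {
    h <- times[i] - times[i - 1]
    m <- (conc[i] - conc[i - 1]) / h
    E <- exp(-k_e0 * h)
    ce[i] <- ce[i - 1] * E + conc[i - 1] * (1 - E) +
      if (k_e0 > 0) m * (h - (1 - E) / k_e0) else 0
  }
  ce
}

#' Imax pharmacodynamic model for the angiotensin II/I ratio
#'
#' ratio = E0 * (1 - Imax * Ce^gamma / (Ce^gamma + IC50^gamma)). With full
#' inhibition (Imax = 1) the ratio falls from the baseline E0 towards zero;
#' at Ce = IC50 the ratio is exactly E0 * (1 - Imax/2).
#'
#' @param ce effect-site (or plasma, for a direct link) concentration, >= 0.
#' @param e0 baseline ratio.
#' @param ic50 half-maximal inhibitory concentration (ug/L).
#' @param imax maximal fractional inhibition in (0, 1].
#' @param gamma sigmoidicity (Hill) factor, > 0.
#' @return predicted dimensionless ratio.
#' @export
imax_ratio <- function(ce, e0, ic50, imax = 1, gamma = 1) {
  if (any(ce < 0)) stop("effect-site concentration must be >= 0")
  if (ic50 <= 0 || gamma <= 0 || imax <= 0 || imax > 1 || e0 <= 0)
    stop("invalid Imax-model parameters")
  cg <- exp(gamma * log(pmax(ce, 0) + (ce == 0) * 0)) # ce^gamma with 0^g = 0
  cg[ce == 0] <- 0
  e0 * (1 - imax * cg / (cg + ic50^gamma))
}

# Predictions for a set of observation rows (internal work-horse used by the
# estimation and simulation layers). `dvid` 1 = enalaprilat concentration,
# 2 = ANG II/ANG I ratio. For kind "pd_obsconc" the measured concentrations
# must be supplied through `conc_input` (same length as `times`).
.predict_obs <- function(model, p, doses, times, dvid, conc_input = NULL) {
  p <- unlist(p)
  f <- numeric(length(times))
  imax <- if (model$kind != "pk" && model$inhibition == "partial") p[["Imax"]] else 1
  gam <- if (model$kind != "pk" && model$hill == "estimated") p[["gamma"]] else 1
  if (model$kind == "pd_obsconc") {
    if (is.null(conc_input)) stop("pd_obsconc model needs measured concentrations")
    i2 <- dvid == 2
    f[i2] <- imax_ratio(conc_input[i2], p[["E0"]], p[["IC50"]], imax, gam)
    return(f)
  }
  i1 <- dvid == 1
  if (any(i1)) f[i1] <- .profile(p, doses, times[i1], model, effect = FALSE)
  i2 <- dvid == 2
  if (any(i2)) {
    drive <- if (model$pd_link == "effect_compartment")
      .profile(p, doses, times[i2], model, effect = TRUE)
    else
      .profile(p, doses, times[i2], model, effect = FALSE)
    f[i2] <- imax_ratio(drive, p[["E0"]], p[["IC50"]], imax, gam)
  }
  f
}
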