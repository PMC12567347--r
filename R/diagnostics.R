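# Model evaluation: visual predictive checks, goodness-of-fit tables,
# hysteresis characterisation, the 4-hour percent-change statistic, and the
# adult-vs-paediatric comparison overlay.

.stream_name <- c(`1` = "pk", `2` = "pd")

# Simulate one replicate of a study on its own design under a population spec.
.simulate_design <- function(subjects, model, spec, lloq_pk) {
  etas <- draw_etas(spec, length(subjects))
  rnames <- names(spec$iiv)
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    th <- realise_individual(spec, if (length(rnames)) etas[i, ] else NULL,
                             sub$covariates)
    f <- .predict_obs(model, th[param_names(model)], sub$doses, sub$obs$TIME,
                      sub$obs$DVID, sub$conc_input)
    dv <- f
    for (s in c(1, 2)) {
      k <- sub$obs$DVID == s
      if (!any(k)) next
      coefs <- if (s == 1) spec$error$pk else spec$error$pd
      sdv <- error_sd(f[k], coefs, spec$error_form)
      dv[k] <- f[k] + sdv * rnorm(sum(k))
    }
    out[[i]] <- data.frame(ID = sub$id, TIME = sub$obs$TIME,
                           DVID = sub$obs$DVID, DV = dv)
  }
  do.call(rbind, out)
}

# Half-LLOQ convention for summarising concentrations below the limit.
.blq_half <- function(dv, dvid, cens, lloq_pk) {
  dv[dvid == 1 & !is.na(cens) & cens == 1] <- lloq_pk / 2
  dv[dvid == 1 & dv < lloq_pk] <- lloq_pk / 2
  dv
}

.make_bins <- function(x, n_bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1), type = 7))
  if (length(br) < 3) br <- range(x) + c(-1e-9, 1e-9)
  br[1] <- br[1] - 1e-9
  findInterval(x, br, rightmost.closed = TRUE)
}

#' Visual predictive check
#'
#' Simulates `nsim` replicate studies on the design of the original dataset
#' (same subjects, dose histories, covariates and sampling times), then
#' compares the observed 10/50/90th percentiles per time bin with the 90\%
#' prediction interval (5th-95th percentile across simulations) of each
#' simulated percentile. Concentrations below the LLOQ enter the percentile
#' computation at LLOQ/2, observed and simulated alike. Rich designs are
#' binned on the shared nominal times; sparse designs use quantile-based
#' bins. Bins holding fewer than 3 observations are merged with their left
#' neighbour (logged in the result).
#'
#' @param ds a [study_dataset()] (post inclusion/exclusion rules).
#' @param model a [model_spec()].
#' @param fit a `fit_result`, or a [population_spec()] to simulate from.
#' @param nsim number of Monte Carlo study replicates (default 500).
#' @param percentiles observed/simulated percentiles to track.
#' @param pi prediction-interval coverage in percent.
#' @param n_bins bins for sparse designs.
#' @param bin_on `"time"` or `"tsld"` (time since last dose).
#' @param seed integer seed.
#' @return a `vpc_result`: per-stream band tables with exit flags plus
#'   metadata (nsim, percentile type 7, binning, seed).
#' @export
vpc <- function(ds, model, fit, nsim = 500, percentiles = c(10, 50, 90),
                pi = 90, n_bins = 8, bin_on = c("time", "tsld"), seed = 1) {
  if (nsim < 100) stop("nsim must be at least 100")
  bin_on <- match.arg(bin_on)
  spec <- if (inherits(fit, "fit_result")) fit$estimates else fit
  subjects <- .prep_subjects(ds, model)
  lloq_pk <- assay_limit(ds$assay, "ENALAPRILAT")
  obs <- do.call(rbind, lapply(subjects, function(sub)
    data.frame(ID = sub$id, TIME = sub$obs$TIME, DVID = sub$obs$DVID,
               DV = sub$obs$DV, CENS = sub$obs$CENS)))
  if (bin_on == "tsld") {
    obs$AXIS <- unlist(lapply(subjects, function(sub)
      time_since_last_dose(sub, sub$obs$TIME)))
  } else obs$AXIS <- obs$TIME
  obs$DVhalf <- .blq_half(obs$DV, obs$DVID, obs$CENS, lloq_pk)

  sims <- with_seed(derive_seed(seed, "vpc"), {
    lapply(seq_len(nsim), function(s) {
      sm <- .simulate_design(subjects, model, spec, lloq_pk)
      .blq_half(sm$DV, sm$DVID, 0, lloq_pk)
    })
  })
  S <- do.call(cbind, sims)  # rows align with obs rows

  merged_bins <- character(0)
  bands <- list()
  for (dvid in intersect(unique(obs$DVID), c(1, 2))) {
    k <- which(obs$DVID == dvid)
    ax <- obs$AXIS[k]
    bin <- if (length(unique(ax)) <= 40) match(ax, sort(unique(ax)))
           else .make_bins(ax, n_bins)
    # merge small bins leftward
    repeat {
      cnt <- table(bin)
      small <- names(cnt)[cnt < 3]
      if (!length(small)) break
      b <- as.integer(small[1])
      tgt <- if (any(bin < b)) max(bin[bin < b]) else min(bin[bin > b])
      merged_bins <- c(merged_bins,
                       paste0(.stream_name[as.character(dvid)], " bin ", b,
                              " -> ", tgt))
      bin[bin == b] <- tgt
    }
    rows <- lapply(sort(unique(bin)), function(b) {
      j <- k[bin == b]
      op <- quantile(obs$DVhalf[j], percentiles / 100, type = 7)
      sp <- apply(S[j, , drop = FALSE], 2, quantile, probs = percentiles / 100,
                  type = 7)
      lo <- apply(sp, 1, quantile, probs = (1 - pi / 100) / 2, type = 7)
      hi <- apply(sp, 1, quantile, probs = 1 - (1 - pi / 100) / 2, type = 7)
      data.frame(stream = unname(.stream_name[as.character(dvid)]),
                 bin_mid = median(obs$AXIS[j]), n_obs = length(j),
                 percentile = percentiles, observed = unname(as.numeric(op)),
                 pi_lower = unname(lo), pi_upper = unname(hi),
                 outside = unname(as.numeric(op) < lo | as.numeric(op) > hi),
                 row.names = NULL)
    })
    bands[[.stream_name[as.character(dvid)]]] <- do.call(rbind, rows)
  }
  structure(list(bands = do.call(rbind, bands),
                 nsim = nsim, percentiles = percentiles, pi = pi,
                 quantile_type = 7, bin_on = bin_on, seed = seed,
                 merged_bins = merged_bins),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat("vpc_result:", x$nsim, "simulations,", nrow(x$bands), "band rows,",
      sum(x$bands$outside), "observed percentiles outside their",
      paste0(x$pi, "%"), "prediction interval\n")
  invisible(x)
}

#' Goodness-of-fit tables
#'
#' Returns the four standard diagnostic surfaces as data: observations
#' against population and individual predictions, and individual weighted
#' residuals IWRES = (y - f_ind) / sd_ind against individual predictions and
#' time. Censored records carry no residual; they are reported in a separate
#' table with their predicted values.
#'
#' @param ds,model as elsewhere.
#' @param fit a `fit_result` carrying empirical Bayes estimates.
#' @return a `gof_table`: list with `table` (uncensored rows), `censored`,
#'   and `summary` (fraction of |IWRES| > 2 per stream).
#' @export
gof <- function(ds, model, fit) {
  if (is.null(fit$ebes))
    stop("fit carries no empirical Bayes estimates; rerun fit_population ",
         "with compute_ebe = TRUE")
  spec <- fit$estimates
  rnames <- names(spec$iiv)
  rows <- list()
  for (i in seq_along(fit$subjects)) {
    sub <- fit$subjects[[i]]
    th_i <- realise_individual(spec, fit$ebes[i, ], sub$covariates)
    th_p <- realise_individual(spec, NULL, sub$covariates)
    fi <- .predict_obs(model, th_i[param_names(model)], sub$doses,
                       sub$obs$TIME, sub$obs$DVID, sub$conc_input)
    fp <- .predict_obs(model, th_p[param_names(model)], sub$doses,
                       sub$obs$TIME, sub$obs$DVID, sub$conc_input)
    coefs <- ifelse(sub$obs$DVID == 1, list(spec$error$pk), list(spec$error$pd))
    sdv <- vapply(seq_len(nrow(sub$obs)), function(j)
      error_sd(fi[j], coefs[[j]], spec$error_form), numeric(1))
    rows[[i]] <- data.frame(ID = sub$id, TIME = sub$obs$TIME,
                            stream = .stream_name[as.character(sub$obs$DVID)],
                            DV = sub$obs$DV, CENS = sub$obs$CENS,
                            PRED = fp, IPRED = fi,
                            IWRES = (sub$obs$DV - fi) / sdv)
  }
  tab <- do.call(rbind, rows)
  cen <- tab[tab$CENS == 1, setdiff(names(tab), "IWRES")]
  unc <- tab[tab$CENS == 0, ]
  if (any(!is.finite(unc$IWRES))) stop("non-finite IWRES in uncensored rows")
  summ <- aggregate(abs(unc$IWRES) > 2, by = list(stream = unc$stream), mean)
  names(summ)[2] <- "frac_iwres_gt2"
  structure(list(table = unc, censored = cen, summary = summ),
            class = "gof_table")
}

#' Hysteresis of the concentration-effect relationship
#'
#' Signed shoelace area of the polygon traced by (concentration, effect)
#' pairs in measurement order, closing the loop from the last point back to
#' the first. A negative signed area means the loop is traversed clockwise -
#' the signature of an effect that lags concentration (a given concentration
#' on the descending limb shows a lower ratio than on the ascending limb).
#'
#' @param conc time-ordered concentrations.
#' @param effect time-ordered effect (ratio) values, same length.
#' @param times optional measurement times; must be strictly increasing.
#' @param tol_factor areas below `tol_factor * (conc range * effect range)`
#'   are labelled `"none"`.
#' @return list with `area` (signed) and `direction`
#'   (`"clockwise"`, `"counterclockwise"`, `"none"`).
#' @export
hysteresis_metric <- function(conc, effect, times = NULL, tol_factor = 1e-9) {
  stopifnot(length(conc) == length(effect))
  if (length(conc) < 4) stop("need at least 4 time-ordered pairs")
  if (!is.null(times) && any(diff(times) <= 0))
    stop("times must be strictly increasing (pairs in measurement order)")
  x <- conc; y <- effect
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- 0.5 * sum(x * yn - xn * y)
  tol <- tol_factor * max(diff(range(x)) * diff(range(y)), .Machine$double.eps)
  direction <- if (abs(area) <= tol) "none"
  else if (area < 0) "clockwise" else "counterclockwise"
  list(area = area, direction = direction)
}

#' Percent change in the ratio four hours after the first dose
#'
#' Per-pair percent decrease 100 * (pre - post) / pre of the angiotensin
#' II/angiotensin I ratio between the predose-first-dose sample and the 4 h
#' sample, with the median and range across subjects.
#'
#' @param paired data.frame (or list) with columns/elements `ratio_predose`
#'   and `ratio_4h`; one row per subject with both samples available.
#' @return list with `n`, `median`, `range`, and the per-pair percent
#'   changes. Pairs with a non-positive predose ratio are rejected with a
#'   warning.
#' @export
percent_change_4h <- function(paired) {
  pre <- paired$ratio_predose
  post <- paired$ratio_4h
  stopifnot(length(pre) == length(post))
  bad <- !(pre > 0)
  if (any(bad)) {
    warning(sum(bad), " pair(s) with non-positive predose ratio rejected")
    pre <- pre[!bad]; post <- post[!bad]
  }
  pct <- 100 * (pre - post) / pre
  list(n = length(pct), median = median(pct), range = range(pct),
       percent_change = pct)
}

#' Adult-model bands with paediatric observations overlaid
#'
#' Re-expresses the adult visual predictive check on the time-since-last-dose
#' axis (the adult study is single-dose, so time equals time since dose) and
#' overlays the paediatric ratio observations re-indexed to time since their
#' last dose. Every point carries one of six symbol classes: the dose class
#' \{predose-first, post-first, post-repeated\} crossed with the BLQ class
#' \{quantified, substituted\} (ANG II below the LLOQ, ratio computed with
#' LLOQ/2). Observation values are never altered - only re-indexed and
#' tagged.
#'
#' @param adult_fit a `fit_result` of the adult PK/PD model.
#' @param paediatric_ds a paediatric [study_dataset()] that has passed
#'   [apply_paediatric_exclusion_rules()] (its events carry CLASS).
#' @param nsim,seed forwarded to [vpc()].
#' @return list with `bands` (adult ratio VPC rows) and `points`
#'   (plot-ready paediatric table).
#' @export
comparison_overlay <- function(adult_fit, paediatric_ds, nsim = 500, seed = 1) {
  v <- vpc(adult_fit$data, adult_fit$model, adult_fit, nsim = nsim, seed = seed)
  bands <- v$bands[v$bands$stream == "pd", ]
  ev <- paediatric_ds$events
  if (!"CLASS" %in% names(ev))
    stop("paediatric dataset must first pass apply_paediatric_exclusion_rules()")
  rat <- ev[ev$EVID == 0 & ev$DVID == 2, ]
  ang2 <- ev[ev$EVID == 0 & ev$DVID == 4, ]
  pts <- lapply(seq_len(nrow(rat)), function(j) {
    id <- rat$ID[j]; t <- rat$TIME[j]
    sub <- subject_record(paediatric_ds, id)
    if (!nrow(sub$doses)) return(NULL)  # no dose history: excluded, logged
    tsld <- if (rat$CLASS[j] == "predose_first") 0
            else time_since_last_dose(sub, t)
    sub2 <- ang2$CENS[ang2$ID == id & ang2$TIME == t]
    blq <- if (length(sub2) && sub2[1] == 1) "substituted" else "quantified"
    data.frame(ID = id, tsld = tsld, ratio = rat$DV[j],
               dose_class = rat$CLASS[j], blq_class = blq,
               symbol = paste(rat$CLASS[j], blq, sep = "/"))
  })
  dropped <- sum(vapply(pts, is.null, logical(1)))
  points <- do.call(rbind, pts)
  structure(list(bands = bands, points = points, nsim = v$nsim,
                 dropped_no_dose_history = dropped),
            class = "overlay_result")
}
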