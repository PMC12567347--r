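#' Assay limits per analyte and study population
#'
#' Lower limits of quantification and calibration ranges for enalaprilat and
#' the two angiotensin peptides, per study population. Units: enalaprilat in
#' ug/L, angiotensins in pg/mL (ANG I in the adult assay was reported in ug/L
#' and is converted: 1 ug/L = 1000 pg/mL).
#'
#' @param population `"adult"` or `"paediatric"`.
#' @return an `assay_config` object: data.frame with columns `analyte`,
#'   `lloq`, `uloq`, `units`, plus a `population` attribute.
#' @export
assay_config <- function(population = c("adult", "paediatric")) {
  population <- match.arg(population)
  limits <- if (population == "adult") {
    data.frame(
      analyte = c("ENALAPRILAT", "ANGI", "ANGII"),
      lloq = c(0.70, 200, 1),       # ANG I 0.2 ug/L -> 200 pg/mL
      uloq = c(NA, 30000, 125),     # ANG I 30 ug/L -> 30000 pg/mL
      units = c("ug/L", "pg/mL", "pg/mL"))
  } else {
    data.frame(
      analyte = c("ENALAPRILAT", "ANGI", "ANGII"),
      lloq = c(0.18, 25.4, 22.3),
      uloq = c(180, 1594.2, 1395.8),
      units = c("ug/L", "pg/mL", "pg/mL"))
  }
  stopifnot(all(is.na(limits$uloq) | limits$lloq < limits$uloq))
  structure(limits, population = population, class = c("assay_config", "data.frame"))
}

#' @keywords internal
assay_limit <- function(assay, analyte, what = c("lloq", "uloq")) {
  what <- match.arg(what)
  assay[[what]][assay$analyte == analyte]
}

# Known paediatric exclusion-category tags.
.known_tags <- c("", "ANGI_ULOQ", "THERAPY_STOPPED", "STOP_UNCLEAR",
                 "BOTH_BLQ", "GT24H", "OTHER")

.dvid_map <- c(ENALAPRILAT = 1, RATIO = 2, ANGI = 3, ANGII = 4)

#' Event-record study dataset
#'
#' The unit of fitting and simulation: a NONMEM/Monolix-style long table of
#' dose events (`EVID = 1`) and observations (`EVID = 0`) plus per-subject
#' covariates and the applicable assay limits. Observation streams are coded
#' by `DVID`: 1 enalaprilat (ug/L), 2 ANG II/ANG I ratio (dimensionless),
#' 3 ANG I (pg/mL), 4 ANG II (pg/mL). Censored rows (`CENS = 1`) carry the
#' interval \[`LIMIT`, `DV`\] with `DV` set to the LLOQ.
#'
#' @param events data.frame with columns ID, TIME, EVID, AMT, DVID, DV, CENS,
#'   LIMIT, TAG (TAG optional, defaults to "").
#' @param covariates data.frame with column ID plus covariate columns
#'   (AGE, WT, BMI, SEX, ROSS, AETIOL as applicable).
#' @param population `"adult"` or `"paediatric"`.
#' @param assay an [assay_config()]; defaults to the population's assay.
#' @return a validated object of class `study_dataset`.
#' @export
study_dataset <- function(events, covariates, population,
                          assay = assay_config(population)) {
  if (!"TAG" %in% names(events)) events$TAG <- ""
  events$TAG[is.na(events$TAG)] <- ""
  ds <- structure(list(population = population, events = events,
                       covariates = covariates, assay = assay),
                  class = "study_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a study dataset
#'
#' Checks the structural invariants of the event table: required columns,
#' non-negative times, positive dose amounts, doses sorted within subject,
#' known DVID codes, censored rows carrying a positive LLOQ, known exclusion
#' tags, and covariate rows for every subject with events.
#'
#' @param ds a [study_dataset()].
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_dataset <- function(ds) {
  ev <- ds$events
  need <- c("ID", "TIME", "EVID", "AMT", "DVID", "DV", "CENS", "LIMIT")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(ev$TIME < 0, na.rm = TRUE)) stop("negative TIME in event table")
  d <- ev[ev$EVID == 1, ]
  if (any(is.na(d$AMT)) || any(d$AMT <= 0)) stop("dose rows must have AMT > 0")
  if (any(unlist(tapply(d$TIME, d$ID, function(x) diff(x) < 0))))
    stop("dose events must be sorted by time within subject")
  o <- ev[ev$EVID == 0, ]
  if (any(!o$DVID %in% .dvid_map)) stop("unknown DVID code in event table")
  cen <- o$CENS == 1
  if (any(cen)) {
    if (any(is.na(o$LIMIT[cen]))) stop("censored row without LIMIT (lower bound)")
    if (any(is.na(o$DV[cen]) | o$DV[cen] <= 0))
      stop("censored row must carry the applicable LLOQ in DV")
  }
  if (any(o$DV[!cen & !is.na(o$DV)] < 0)) stop("negative uncensored DV")
  if (any(!ev$TAG %in% .known_tags))
    stop("unknown exclusion tag(s): ",
         paste(setdiff(unique(ev$TAG), .known_tags), collapse = ", "))
  if (anyDuplicated(ds$covariates$ID)) stop("duplicate subject id in covariates")
  orphan <- setdiff(unique(ev$ID), ds$covariates$ID)
  if (length(orphan)) stop("events reference subject(s) without covariates: ",
                           paste(orphan, collapse = ", "))
  invisible(ds)
}

#' @export
print.study_dataset <- function(x, ...) {
  o <- x$events[x$events$EVID == 0, ]
  cat("study_dataset (", x$population, "): ",
      length(unique(x$events$ID)), " subjects, ",
      sum(x$events$EVID == 1), " dose events, ",
      nrow(o), " observations (",
      sum(o$DVID == 1), " PK, ", sum(o$DVID == 2), " ratio)\n", sep = "")
  invisible(x)
}

#' Read / write the event CSV dialect
#'
#' Columns: ID, TIME (h), EVID (0 obs / 1 dose), AMT (ug), DVID
#' (1 enalaprilat, 2 ratio, 3 ANG I, 4 ANG II), DV, CENS (0/1), LIMIT,
#' covariates AGE, WT, BMI, SEX (0 = male, 1 = female), ROSS, AETIOL, and TAG
#' (exclusion category, empty when none). Missing numeric fields are encoded
#' as `"."`.
#'
#' @param path CSV file path.
#' @param population `"adult"` or `"paediatric"`.
#' @param assay assay limits; defaults to the population's [assay_config()].
#' @param schema optional named character vector mapping required column
#'   names to the names used in the file, e.g. `c(DV = "CONC")`.
#' @return a [study_dataset()].
#' @export
read_dataset <- function(path, population = c("adult", "paediatric"),
                         assay = NULL, schema = NULL) {
  population <- match.arg(population)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c(".", "NA", ""))
  if (!is.null(schema)) {
    for (std in names(schema)) names(raw)[names(raw) == schema[[std]]] <- std
  }
  need <- c("ID", "TIME", "EVID", "AMT", "DVID", "DV", "CENS", "LIMIT")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("input file is missing column(s): ",
                         paste(miss, collapse = ", "))
  num <- intersect(c("TIME", "AMT", "DVID", "DV", "CENS", "LIMIT",
                     "AGE", "WT", "BMI", "SEX", "ROSS"), names(raw))
  for (cc in num) raw[[cc]] <- as.numeric(raw[[cc]])
  raw$CENS[is.na(raw$CENS) & raw$EVID == 0] <- 0
  if (!"TAG" %in% names(raw)) raw$TAG <- ""
  raw$TAG[is.na(raw$TAG)] <- ""
  covnames <- intersect(c("AGE", "WT", "BMI", "SEX", "ROSS", "AETIOL"), names(raw))
  cov <- raw[!duplicated(raw$ID), c("ID", covnames), drop = FALSE]
  ev <- raw[, c(need, "TAG")]
  study_dataset(ev, cov, population,
                assay = assay %||% assay_config(population))
}

#' @rdname read_dataset
#' @param ds a [study_dataset()].
#' @export
write_dataset <- function(ds, path) {
  ev <- ds$events
  out <- merge(ev, ds$covariates, by = "ID", all.x = TRUE, sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = ".", quote = FALSE)
  invisible(path)
}

#' Subject accessor
#'
#' @param ds a [study_dataset()].
#' @param id subject id.
#' @return list with `id`, `covariates` (one-row data.frame), `doses`
#'   (data.frame time/amount) and `observations` (event rows with EVID = 0).
#' @export
subject_record <- function(ds, id) {
  ev <- ds$events[ds$events$ID == id, ]
  if (!nrow(ev)) stop("unknown subject id: ", id)
  d <- ev[ev$EVID == 1, ]
  list(id = id,
       covariates = ds$covariates[ds$covariates$ID == id, ],
       doses = data.frame(time = d$TIME, amount = d$AMT),
       observations = ev[ev$EVID == 0, ])
}

#' Time since the most recent dose
#'
#' @param subject a [subject_record()] (or any list with a `doses` data.frame).
#' @param t time(s) in hours since first dose.
#' @return `t` minus the time of the latest dose at or before `t`.
#' @export
time_since_last_dose <- function(subject, t) {
  dt <- sort(subject$doses$time)
  if (!length(dt)) stop("subject has no dose events")
  vapply(t, function(ti) {
    prior <- dt[dt <= ti]
    if (!length(prior)) stop("no dose at or before t = ", ti)
    ti - max(prior)
  }, numeric(1))
}

#' Compute the angiotensin II/angiotensin I ratio with BLQ handling
#'
#' Converts ANG I to pg/mL if reported in ug/L, then: if ANG II is below its
#' LLOQ the value is replaced by LLOQ/2 and the result flagged `"substituted"`
#' (when `blq_mode = "substitute"`; with `"use_reported"` the reported value
#' is used as-is, the convention applied to the adult data where BLQ values
#' were rare); if both analytes are below their LLOQs the record is marked
#' `"excluded"` and no ratio is emitted.
#'
#' @param ang2 ANG II value(s), pg/mL.
#' @param ang1 ANG I value(s).
#' @param assay an [assay_config()].
#' @param ang1_units `"pg/mL"` or `"ug/L"`.
#' @param blq_mode `"substitute"` or `"use_reported"`.
#' @return data.frame with columns `ratio` and `status` in
#'   \{"quantified", "substituted", "excluded"\}.
#' @export
compute_ratio <- function(ang2, ang1, assay, ang1_units = c("pg/mL", "ug/L"),
                          blq_mode = c("substitute", "use_reported")) {
  ang1_units <- match.arg(ang1_units)
  blq_mode <- match.arg(blq_mode)
  if (ang1_units == "ug/L") ang1 <- ang1 * 1000
  l1 <- assay_limit(assay, "ANGI"); l2 <- assay_limit(assay, "ANGII")
  n <- max(length(ang1), length(ang2))
  ang1 <- rep_len(ang1, n); ang2 <- rep_len(ang2, n)
  blq1 <- ang1 < l1; blq2 <- ang2 < l2
  status <- rep("quantified", n)
  val2 <- ang2
  both <- blq1 & blq2
  status[both] <- "excluded"
  if (any(ang1 == 0 & !both))
    stop("ANG I = 0 gives an undefined ratio")
  sub <- blq2 & !both & blq_mode == "substitute"
  val2[sub] <- l2 / 2
  status[sub] <- "substituted"
  ratio <- ifelse(both, NA_real_, val2 / ang1)
  data.frame(ratio = ratio, status = status)
}

#' Adult-study inclusion rules
#'
#' Applies the data-accounting rules of the rich single-dose adult study:
#' predose enalaprilat samples are excluded (no drug is expected before the
#' first-ever dose), ratio observations more than 24 h after dosing are
#' excluded (the ratio rose back above baseline there and 24 h is the maximum
#' therapeutic dosing interval), and quantifiable-range violations of
#' enalaprilat below 0.70 ug/L are converted to interval-censored rows on
#' \[0, LLOQ\].
#'
#' @param ds an adult [study_dataset()].
#' @return list with elements `dataset` (filtered, censoring applied) and
#'   `audit` (named counts; included + excluded sums to the input rows).
#' @export
apply_adult_inclusion_rules <- function(ds) {
  if (ds$population != "adult")
    stop("adult inclusion rules applied to a ", ds$population, " dataset")
  ev <- ds$events
  obs <- ev$EVID == 0
  lloq <- assay_limit(ds$assay, "ENALAPRILAT")
  first_dose <- tapply(ev$TIME[ev$EVID == 1], ev$ID[ev$EVID == 1], min)
  fd <- first_dose[as.character(ev$ID)]
  tsld <- ev$TIME - fd  # single-dose study: time since (only) dose
  predose_pk <- obs & ev$DVID == 1 & ev$TIME <= fd
  late_ratio <- obs & ev$DVID == 2 & tsld > 24
  drop <- predose_pk | late_ratio
  out <- ev[!drop, ]
  to_cens <- out$EVID == 0 & out$DVID == 1 & out$CENS == 0 & out$DV < lloq
  out$DV[to_cens] <- lloq
  out$CENS[to_cens] <- 1
  out$LIMIT[to_cens] <- 0
  audit <- c(input_obs = sum(obs),
             excluded_predose_pk = sum(predose_pk),
             excluded_ratio_gt24h = sum(late_ratio),
             censored_blq_pk = sum(out$EVID == 0 & out$DVID == 1 & out$CENS == 1),
             included_pk = sum(out$EVID == 0 & out$DVID == 1),
             included_ratio = sum(out$EVID == 0 & out$DVID == 2))
  list(dataset = study_dataset(out, ds$covariates, "adult", ds$assay),
       audit = audit)
}

#' Paediatric exclusion rules and observation classification
#'
#' Removes observation instants tagged with an exclusion category
#' (ANGI above calibration range, therapy stopped, unclear stop time, both
#' angiotensins BLQ, other uncertainties), removes instants whose time since
#' the last dose exceeds 24 h, sets predose-first-dose enalaprilat values
#' below the LLOQ to zero, and classifies the survivors into
#' predose-first-dose / post-first-dose / post-repeated-dose instants.
#' Counting is per observation instant (a simultaneous PK + PD pair counts
#' once).
#'
#' @param ds a paediatric [study_dataset()].
#' @return list with `dataset` (filtered; classification stored in the
#'   `CLASS` column of `dataset$events`) and `audit` (counts per exclusion
#'   category and per class).
#' @export
apply_paediatric_exclusion_rules <- function(ds) {
  if (ds$population != "paediatric")
    stop("paediatric exclusion rules applied to a ", ds$population, " dataset")
  ev <- ds$events
  ev$CLASS <- NULL  # re-derived below; makes the rules idempotent
  bad <- setdiff(unique(ev$TAG), .known_tags)
  if (length(bad)) stop("unknown exclusion tag(s): ", paste(bad, collapse = ", "))
  obs <- ev[ev$EVID == 0, ]
  dose <- ev[ev$EVID == 1, ]
  key <- paste(obs$ID, obs$TIME)
  inst <- !duplicated(key)  # one row per observation instant
  # time since last dose and dose-count before each instant
  tsld <- rep(NA_real_, nrow(obs)); ndose <- integer(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    dt <- dose$TIME[dose$ID == obs$ID[i]]
    prior <- dt[dt <= obs$TIME[i]]
    ndose[i] <- length(prior)
    if (length(prior)) tsld[i] <- obs$TIME[i] - max(prior)
  }
  # predose-first: at or before the first dose
  cls <- ifelse(ndose == 0 | (ndose == 1 & tsld == 0), "predose_first",
         ifelse(ndose == 1, "post_first", "post_repeated"))
  tag <- obs$TAG
  tag[tag == "" & !is.na(tsld) & tsld > 24] <- "GT24H"
  keep <- tag == ""
  # paediatric predose-first enalaprilat BLQ values are set to zero
  lloq <- assay_limit(ds$assay, "ENALAPRILAT")
  zero_fix <- keep & obs$DVID == 1 & cls == "predose_first" & obs$DV < lloq
  obs$DV[zero_fix] <- 0
  obs$CENS[zero_fix] <- 0
  cat_counts <- table(factor(tag[inst], levels = .known_tags))
  names(cat_counts)[1] <- "included"
  cls_counts <- table(factor(cls[inst & keep],
                             levels = c("predose_first", "post_first", "post_repeated")))
  obs$CLASS <- cls
  out_ev <- rbind(cbind(dose, CLASS = NA_character_), obs[keep, ])
  out_ev <- out_ev[order(out_ev$ID, out_ev$TIME, out_ev$EVID, out_ev$DVID), ]
  ids <- unique(out_ev$ID)
  list(dataset = study_dataset(out_ev,
                               ds$covariates[ds$covariates$ID %in% ids, ],
                               "paediatric", ds$assay),
       audit = list(instants_input = sum(inst),
                    instants_included = sum(inst & keep),
                    excluded = cat_counts[-1],
                    classes = cls_counts))
}
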