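test_that("a toy event CSV is parsed into doses and observations", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "ID,TIME,EVID,AMT,DVID,DV,CENS,LIMIT,AGE,WT,BMI,SEX",
    "1,0,1,20000,.,.,0,.,25,70,22,0",
    "1,2,0,.,1,15.2,0,.,25,70,22,0",
    "1,48,0,.,1,0.70,1,0,25,70,22,0"), f)
  ds <- read_dataset(f, "adult")
  expect_s3_class(ds, "study_dataset")
  expect_equal(length(unique(ds$events$ID)), 1)
  expect_equal(sum(ds$events$EVID == 1), 1)
  o <- ds$events[ds$events$EVID == 0, ]
  expect_equal(nrow(o), 2)
  expect_equal(sum(o$CENS), 1)
  expect_equal(o$LIMIT[o$CENS == 1], 0)
})

test_that("schema violations are reported by column name", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,EVID,AMT,DVID,DV,CENS",
               "1,2,0,.,1,0.70,1"), f)
  expect_error(read_dataset(f, "adult"), "LIMIT")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,EVID,AMT,DVID,DV,CENS,LIMIT",
               "1,2,0,.,9,1.0,0,."), f2)
  expect_error(read_dataset(f2, "adult"), "DVID")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,EVID,AMT,DVID,DV,CENS,LIMIT",
               "1,-2,0,.,1,1.0,0,."), f3)
  expect_error(read_dataset(f3, "adult"), "TIME")
})

test_that("write/read round-trip preserves a generated adult study", {
  ds <- generate_adult_study(adult_design(n_subjects = 3), seed = 5)
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  ds2 <- read_dataset(f, "adult")
  expect_equal(ds2$events$DV, ds$events$DV, tolerance = 1e-9)
  expect_equal(ds2$events$TIME, ds$events$TIME, tolerance = 1e-12)
  expect_identical(ds2$events$CENS, ds$events$CENS)
  expect_identical(ds2$events$DVID, ds$events$DVID)
  expect_equal(ds2$covariates$WT, ds$covariates$WT)
})

test_that("compute_ratio applies units, substitution and exclusion rules", {
  assay <- assay_config("paediatric")
  # ANG II below the paediatric LLOQ of 22.3 pg/mL -> LLOQ/2 substitution
  r <- compute_ratio(ang2 = 10, ang1 = 111.5, assay)
  expect_equal(r$ratio, 11.15 / 111.5)
  expect_equal(r$ratio, 0.1)
  expect_equal(r$status, "substituted")
  # identical quantifiable analytes -> ratio 1
  r2 <- compute_ratio(500, 500, assay)
  expect_equal(r2$ratio, 1)
  expect_equal(r2$status, "quantified")
  # both BLQ -> excluded, no ratio
  r3 <- compute_ratio(5, 20, assay)
  expect_true(is.na(r3$ratio))
  expect_equal(r3$status, "excluded")
  # unit conversion: ANG I in ug/L
  r4 <- compute_ratio(50, 0.5, assay, ang1_units = "ug/L")
  expect_equal(r4$ratio, 50 / 500)
  # adult convention: reported value used even when BLQ
  r5 <- compute_ratio(10, 111.5, assay, blq_mode = "use_reported")
  expect_equal(r5$ratio, 10 / 111.5)
  expect_equal(r5$status, "quantified")
  # ANG I zero outside the BLQ range is undefined
  expect_error(compute_ratio(50, 0, assay_config("adult")), "undefined")
})

test_that("compute_ratio is invariant to consistent unit rescaling", {
  assay <- assay_config("paediatric")
  a <- compute_ratio(80, 400, assay)
  b <- compute_ratio(80, 0.4, assay, ang1_units = "ug/L")
  expect_equal(a$ratio, b$ratio)
})

test_that("adult inclusion rules pass an empty dataset through with zero
           counts", {
  ev <- data.frame(ID = 1, TIME = 0, EVID = 1, AMT = 20000, DVID = NA,
                   DV = NA, CENS = NA, LIMIT = NA, TAG = "")
  cov <- data.frame(ID = 1, AGE = 25, WT = 70, BMI = 22, SEX = 0,
                    ROSS = NA, AETIOL = NA)
  ds <- study_dataset(ev, cov, "adult")
  r <- apply_adult_inclusion_rules(ds)
  expect_equal(unname(r$audit["input_obs"]), 0)
  expect_equal(unname(r$audit["included_pk"]), 0)
  expect_equal(unname(r$audit["included_ratio"]), 0)
})

test_that("adult inclusion rules are idempotent and audit counts sum", {
  ds <- generate_adult_study(seed = 2)
  r1 <- apply_adult_inclusion_rules(ds)
  r2 <- apply_adult_inclusion_rules(r1$dataset)
  expect_equal(r2$dataset$events, r1$dataset$events)
  a <- r1$audit
  expect_equal(a[["included_pk"]] + a[["included_ratio"]] +
                 a[["excluded_predose_pk"]] + a[["excluded_ratio_gt24h"]],
               a[["input_obs"]])
  expect_error(apply_adult_inclusion_rules(
    generate_paediatric_study(seed = 1)), "paediatric")
})

test_that("paediatric exclusion rules validate tags and are idempotent", {
  ds <- generate_paediatric_study(seed = 4)
  r1 <- apply_paediatric_exclusion_rules(ds)
  r2 <- apply_paediatric_exclusion_rules(r1$dataset)
  expect_equal(r2$audit$instants_included, r1$audit$instants_included)
  expect_equal(sum(r1$audit$excluded) + r1$audit$instants_included,
               r1$audit$instants_input)
  bad <- ds
  bad$events$TAG[which(bad$events$EVID == 0)[1]] <- "NOT_A_TAG"
  expect_error(apply_paediatric_exclusion_rules(bad), "unknown exclusion tag")
})

test_that("time since last dose follows the dosing diary", {
  sub <- list(doses = data.frame(time = c(0, 12), amount = c(1, 1)))
  expect_equal(time_since_last_dose(sub, 16), 4)
  expect_equal(time_since_last_dose(sub, c(4, 12, 23.9)), c(4, 0, 11.9))
  expect_error(time_since_last_dose(list(doses = data.frame(time = numeric(0),
                                                            amount = numeric(0))), 1),
               "no dose")
  # seven-day BID diary: scan oracle
  diary <- data.frame(time = rep(0:6 * 24, each = 2) + c(0, 12), amount = 500)
  sub2 <- list(doses = diary)
  t <- max(diary$time) + 2
  oracle <- t - max(diary$time[diary$time <= t])
  expect_equal(time_since_last_dose(sub2, t), oracle)
  expect_equal(oracle, 2)
})
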