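# The synthetic cohort generator: determinism, planted-effect faithfulness,
# site contracts, measurements and statements.

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- generator_config(n_patients_per_site = 200, seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$diagnoses, c2$diagnoses)
  expect_identical(c1$measurements, c2$measurements)
  expect_identical(c1$true_params, c2$true_params)
})

test_that("a zero prevalence multiplier silences a phenotype completely", {
  reg <- default_registry()
  reg$prev_multiplier[reg$phenotype == "038"] <- 0
  attr(reg, "direct_effects") <- attr(default_registry(), "direct_effects")
  cfg <- generator_config(n_patients_per_site = 300, seed = 2, registry = reg)
  co <- generate_cohort(cfg)
  codes <- default_phecode_map(reg)$code[default_phecode_map(reg)$phecode == "038"]
  expect_equal(sum(co$diagnoses$code %in% codes), 0)
  expect_equal(sum(co$disease$A[, "038"]), 0)
})

test_that("invalid race proportions are a configuration error", {
  sites <- default_sites()
  sites$A$race_probs["Asian"] <- 0.5
  expect_error(generator_config(sites = sites), "sum to 1")
})

test_that("null phenotypes are independent of every measurement", {
  co <- mid_cohort()   # 2500 patients/site
  reg <- co$registry
  nulls <- reg$phenotype[reg$class == "null"]
  # patient-level label vs measurement odds ratios across the site-A cohort
  first_ecg <- !duplicated(co$ecgs$patient_id)
  ecg_a <- co$ecgs$ecg_id[first_ecg & co$ecgs$site_id == "A"]
  pat_a <- co$ecgs$patient_id[match(ecg_a, co$ecgs$ecg_id)]
  meas <- co$measurements[ecg_a, c("Heart Rate", "R Amplitude in II",
                                   "Mean QTc")]
  ors <- sapply(nulls[1:10], function(p) {
    y <- co$disease$A[pat_a, p] == 1
    sapply(colnames(meas), function(m) {
      x <- meas[, m] > stats::median(meas[, m])
      odds_ratio_2x2(x, y)
    })
  })
  # mean log-OR across phenotype x measurement cells concentrates near 0
  expect_lt(mean(abs(log(ors))), 0.15)
})

test_that("factor-driven labels correlate with the registered strongest measurement in the registered direction", {
  co <- mid_cohort()
  reg <- co$registry
  fac <- reg[reg$class == "factor" & !is.na(reg$factor) & reg$beta >= 2, ]
  first_ecg <- !duplicated(co$ecgs$patient_id)
  ecg_a <- co$ecgs$ecg_id[first_ecg & co$ecgs$site_id == "A"]
  pat_a <- co$ecgs$patient_id[match(ecg_a, co$ecgs$ecg_id)]
  for (i in seq_len(nrow(fac))) {
    y <- co$disease$A[pat_a, fac$phenotype[i]]
    x <- co$measurements[ecg_a, fac$strongest_measurement[i]]
    r <- stats::cor(x, y)              # point-biserial
    expect_equal(sign(r), fac$strongest_direction[i],
                 label = paste("sign for", fac$phenotype[i]))
    expect_gt(abs(r), 0.05)
  }
})

test_that("sites differ in demographics but share effect directions", {
  co <- mid_cohort()
  pa <- co$patients[co$patients$site_id == "A", ]
  pb <- co$patients[co$patients$site_id == "B", ]
  expect_gt(mean(pa$age), mean(pb$age) + 1)
  expect_gt(mean(pb$race_ethnicity == "Black"),
            mean(pa$race_ethnicity == "Black") + 0.05)
  # site B's prevalence multiplier raises prevalence for the same phenotypes
  reg <- co$registry
  expect_gt(mean(co$disease$B[, "509"]), mean(co$disease$A[, "509"]))
  # design AUCs (effect recoverability) agree in rank across sites
  fa <- reg$design_auc_A[reg$class == "factor"]
  fb <- reg$design_auc_B[reg$class == "factor"]
  expect_gt(stats::cor(fa, fb, use = "complete.obs"), 0.8)
})

test_that("measurements equal generating parameters when noise is zero", {
  base <- stats::setNames(morphology_defaults()$mean, MORPH_PARAMS)
  m <- drop(derive_measurements(base, noise_sd = 0))
  expect_equal(unname(m["Heart Rate"]), unname(base["hr"]))
  expect_equal(unname(m["Mean QRS duration"]), unname(base["qrs"]))
  m60 <- drop(derive_measurements(`[<-`(base, "hr", 60), noise_sd = 0))
  expect_equal(unname(m60["Number of QRS Complexes"]), 10)  # 60 bpm, 10 s
  expect_error(derive_measurements(base, names = "No Such Measurement"),
               "unknown measurement")
})

test_that("the heart-rate measurement tracks the planted septic factor", {
  co <- mid_cohort()
  pats <- co$patients[co$patients$site_id == "A", ]
  first_ecg <- !duplicated(co$ecgs$patient_id)
  ecg_a <- co$ecgs$ecg_id[first_ecg & co$ecgs$site_id == "A"]
  f1 <- pats$F1[match(co$ecgs$patient_id[match(ecg_a, co$ecgs$ecg_id)],
                      pats$patient_id)]
  expect_gt(stats::cor(f1, co$measurements[ecg_a, "Heart Rate"]), 0.3)
})

test_that("statement rules use strict inequalities and are empty at population means", {
  base <- stats::setNames(morphology_defaults()$mean, MORPH_PARAMS)
  m101 <- drop(derive_measurements(`[<-`(base, "hr", 101), noise_sd = 0))
  m100 <- drop(derive_measurements(`[<-`(base, "hr", 100), noise_sd = 0))
  expect_true("sinus tachycardia" %in% derive_statements(m101))
  expect_false("sinus tachycardia" %in% derive_statements(m100))
  m_base <- drop(derive_measurements(base, noise_sd = 0))
  expect_length(derive_statements(m_base), 0)
})

test_that("cohort files round-trip through the writer", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  pats <- read.csv(file.path(dir, "patients.csv"))
  expect_equal(nrow(pats), nrow(co$patients))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(gt$registry), 60)
})
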