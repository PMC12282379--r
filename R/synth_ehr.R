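# Seeded two-site synthetic EHR + ECG cohort generator with a registry of
# planted ground-truth effects.

#' Generator configuration
#'
#' Assembles and validates the configuration for [generate_cohort()]. The
#' defaults are the package's desk-scale study conditions: two sites of
#' 10,000 patients each with 1-3 ECGs per patient, 60 phenotypes
#' (25 factor-driven, 5 demographic-only, 30 null), four latent comorbidity
#' factors, a 40-measurement device panel, and 10 s, 500 Hz 12-lead records.
#'
#' @param n_patients_per_site patients simulated at each site.
#' @param n_phenotypes number of registry phenotypes (must match `registry`).
#' @param n_latent_factors latent comorbidity factors per patient.
#' @param n_measurements size of the device measurement panel (fixed panel of
#'   40 names, see [measurement_names()]).
#' @param sample_rate waveform sampling rate, Hz.
#' @param duration record length, seconds.
#' @param seed integer seed controlling every random draw.
#' @param ecgs_per_patient integer vector sampled uniformly per patient.
#' @param event_rate probability that a diseased patient's ECG anchors a
#'   diagnosis event.
#' @param window_outside_frac fraction of diagnosis events deliberately
#'   placed outside the 30-day association window (31-120 days away).
#' @param date_range calendar-day range for ECG acquisition dates.
#' @param meas_noise_frac measurement noise SD as a fraction of each
#'   measurement's person-to-person SD.
#' @param meas_idio_frac SD of a measurement-specific patient-level
#'   idiosyncrasy (electrode placement, device calibration, habitus) shared
#'   by all of a patient's ECGs, as a fraction of the person-to-person SD;
#'   it makes each panel measurement carry information beyond the common
#'   morphology parameters.
#' @param noise_amp,wander_amp,wander_freq waveform white-noise SD (mV),
#'   baseline-wander amplitude (mV) and frequency (Hz).
#' @param sites list of two site parameter lists, see [default_sites()].
#' @param registry planted effect registry, see [default_registry()].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients_per_site = 10000,
                             n_phenotypes = 60,
                             n_latent_factors = 4,
                             n_measurements = 40,
                             sample_rate = 500,
                             duration = 10,
                             seed = 1,
                             ecgs_per_patient = 1:3,
                             event_rate = 0.85,
                             window_outside_frac = 0.2,
                             date_range = c(0, 3650),
                             meas_noise_frac = 0.12,
                             meas_idio_frac = 0.2,
                             noise_amp = 0.015,
                             wander_amp = 0.05,
                             wander_freq = 0.33,
                             sites = default_sites(),
                             registry = default_registry()) {
  cfg <- list(n_patients_per_site = n_patients_per_site,
              n_phenotypes = n_phenotypes,
              n_latent_factors = n_latent_factors,
              n_measurements = n_measurements,
              sample_rate = sample_rate, duration = duration, seed = seed,
              ecgs_per_patient = ecgs_per_patient, event_rate = event_rate,
              window_outside_frac = window_outside_frac,
              date_range = date_range, meas_noise_frac = meas_noise_frac,
              meas_idio_frac = meas_idio_frac,
              noise_amp = noise_amp, wander_amp = wander_amp,
              wander_freq = wander_freq, sites = sites, registry = registry)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  counts <- c(cfg$n_patients_per_site, cfg$n_phenotypes,
              cfg$n_latent_factors, cfg$n_measurements, cfg$sample_rate,
              cfg$duration)
  if (any(counts <= 0)) stop("configuration error: all counts must be positive")
  if (cfg$n_measurements != length(measurement_names()))
    stop("configuration error: the measurement panel is fixed at ",
         length(measurement_names()), " names")
  if (cfg$n_phenotypes != nrow(cfg$registry))
    stop("configuration error: n_phenotypes must match the registry")
  validate_registry(cfg$registry, cfg$n_latent_factors)
  if (length(cfg$sites) != 2) stop("configuration error: exactly two sites")
  for (s in cfg$sites) {
    if (abs(sum(s$race_probs) - 1) > 1e-8)
      stop("configuration error: race/ethnicity proportions must sum to 1")
    if (s$prev_multiplier < 0)
      stop("configuration error: site prevalence multiplier must be >= 0")
  }
  if (cfg$window_outside_frac < 0 || cfg$window_outside_frac > 1)
    stop("configuration error: window_outside_frac must be in [0,1]")
  cfg
}

#' Default two-site demographic mixes
#'
#' Site A emulates an academic-centre cohort (mean patient age 61, SD 17,
#' majority non-Hispanic White); site B is older-code-richer with a different
#' race/ethnicity mix and a 1.3x odds prevalence multiplier. Effect
#' directions are shared between sites by construction.
#'
#' @return named list of two site parameter lists.
#' @export
default_sites <- function() {
  list(
    A = list(site_id = "A", age_mean = 61, age_sd = 17, female_frac = 0.48,
             race_probs = c("Non-Hispanic White" = 0.567, "Asian" = 0.103,
                            "Black" = 0.054, "Hispanic White" = 0.022,
                            "Other" = 0.254),
             bmi_mean = 27, bmi_sd = 5, prev_multiplier = 1.0),
    B = list(site_id = "B", age_mean = 58, age_sd = 16, female_frac = 0.52,
             race_probs = c("Non-Hispanic White" = 0.40, "Asian" = 0.06,
                            "Black" = 0.164, "Hispanic White" = 0.102,
                            "Other" = 0.274),
             bmi_mean = 28.5, bmi_sd = 5.5, prev_multiplier = 1.3))
}

#' Generate a seeded two-site synthetic cohort
#'
#' Draws patients (demographics + latent comorbidity factors), per-patient
#' disease states as logistic functions of the planted effects, timestamped
#' ICD-like diagnosis events anchored to ECG dates (a configured fraction
#' deliberately outside the association window), per-ECG generating
#' morphology parameters, the noisy 40-measurement device panel, and
#' rule-based interpretation statements. Waveforms are synthesized lazily via
#' [ecg_waveform()].
#'
#' @param config a [generator_config()].
#' @return object of class `ecg_cohort`: list with `patients`, `diagnoses`,
#'   `ecgs`, `true_params` (matrix), `measurements` (matrix), `statements`
#'   (long data frame), `disease` (patient x phenotype ground-truth states),
#'   `registry` (augmented with per-site design AUCs and the strongest
#'   planted measurement), and `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  set.seed(config$seed)
  reg <- config$registry
  de_list <- attr(reg, "direct_effects")
  tab <- morphology_defaults()
  dem_coef <- demographic_coefficients()
  L <- factor_loadings(config$n_latent_factors)
  pop_sd <- measurement_population_sd(config$duration, config$n_latent_factors)
  mnames <- measurement_names()
  n <- config$n_patients_per_site
  P <- nrow(reg)

  site_out <- lapply(config$sites, function(site) {
    ## ---- patients ----
    age <- pmin(pmax(stats::rnorm(n, site$age_mean, site$age_sd), 18), 95)
    female <- stats::rbinom(n, 1, site$female_frac)
    race <- sample(names(site$race_probs), n, replace = TRUE,
                   prob = site$race_probs)
    bmi <- pmin(pmax(stats::rnorm(n, site$bmi_mean, site$bmi_sd), 16), 55)
    f <- matrix(stats::rnorm(n * config$n_latent_factors), nrow = n,
                dimnames = list(NULL, rownames(L)))
    age_z <- (age - 60) / 17
    bmi_z <- (bmi - 27) / 5
    patient_id <- sprintf("P%s%05d", site$site_id, seq_len(n))

    ## ---- patient-level morphology ----
    base <- matrix(tab$mean, nrow = n, ncol = length(MORPH_PARAMS),
                   byrow = TRUE, dimnames = list(NULL, MORPH_PARAMS))
    dem_part <- cbind(age_z, female, bmi_z) %*% t(dem_coef)
    fac_part <- f %*% L
    pat_noise <- matrix(stats::rnorm(n * length(MORPH_PARAMS)), nrow = n) %*%
      diag(tab$sd_patient)
    params_patient <- base + dem_part + fac_part + pat_noise
    params_patient <- pmin(pmax(params_patient,
                                matrix(tab$lower, n, length(MORPH_PARAMS),
                                       byrow = TRUE)),
                           matrix(tab$upper, n, length(MORPH_PARAMS),
                                  byrow = TRUE))
    colnames(params_patient) <- MORPH_PARAMS

    ## ---- disease states ----
    mm_patient <- measurement_means(rate_adjust_qt(params_patient),
                                    config$duration)
    idio_sd <- config$meas_idio_frac * pop_sd
    idio_sd[colnames(mm_patient) == "Number of QRS Complexes"] <- 0
    idio <- matrix(stats::rnorm(n * ncol(mm_patient)), nrow = n) %*%
      diag(idio_sd)
    mm_patient <- mm_patient + idio
    mm_z <- scale(mm_patient)  # site-empirical standardization
    lin <- matrix(0, nrow = n, ncol = P,
                  dimnames = list(patient_id, reg$phenotype))
    for (j in seq_len(P)) {
      lj <- rep(0, n)
      if (!is.na(reg$factor[j]) && reg$beta[j] != 0)
        lj <- lj + reg$beta[j] * f[, reg$factor[j]]
      if (reg$age_coef[j] != 0) lj <- lj + reg$age_coef[j] * age_z
      if (reg$sex_coef[j] != 0) lj <- lj + reg$sex_coef[j] * female
      dej <- de_list[[reg$phenotype[j]]]
      if (!is.null(dej)) lj <- lj + drop(mm_z[, names(dej), drop = FALSE] %*% dej)
      lin[, j] <- lj
    }
    b0 <- vapply(seq_len(P), function(j) {
      mult <- site$prev_multiplier * reg$prev_multiplier[j]
      if (mult == 0 || reg$base_prev[j] <= 0) return(-Inf)
      root <- stats::uniroot(function(b)
        mean(stats::plogis(b + lin[, j])) - reg$base_prev[j],
        lower = -25, upper = 15, tol = 1e-9)$root
      root + log(mult)
    }, numeric(1))
    prob <- stats::plogis(sweep(lin, 2, b0, "+"))
    prob[, !is.finite(b0)] <- 0
    disease <- matrix(stats::rbinom(n * P, 1, prob), nrow = n,
                      dimnames = dimnames(lin))

    ## ---- ECGs ----
    k <- if (length(config$ecgs_per_patient) == 1) {
      rep(config$ecgs_per_patient, n)
    } else sample(config$ecgs_per_patient, n, replace = TRUE)
    idx <- rep(seq_len(n), k)
    n_ecg <- length(idx)
    ecg_date <- sample(seq(config$date_range[1], config$date_range[2]),
                       n_ecg, replace = TRUE)
    ecg_id <- sprintf("E%s%06d", site$site_id, seq_len(n_ecg))
    ecg_noise <- matrix(stats::rnorm(n_ecg * length(MORPH_PARAMS)),
                        nrow = n_ecg) %*% diag(tab$sd_ecg)
    params_ecg <- params_patient[idx, , drop = FALSE] + ecg_noise
    params_ecg <- pmin(pmax(params_ecg,
                            matrix(tab$lower, n_ecg, length(MORPH_PARAMS),
                                   byrow = TRUE)),
                       matrix(tab$upper, n_ecg, length(MORPH_PARAMS),
                              byrow = TRUE))
    colnames(params_ecg) <- MORPH_PARAMS
    params_ecg <- rate_adjust_qt(params_ecg)
    rownames(params_ecg) <- ecg_id
    meas <- derive_measurements(params_ecg,
                                noise_sd = config$meas_noise_frac * pop_sd,
                                duration = config$duration)
    meas <- meas + idio[idx, , drop = FALSE]
    rownames(meas) <- ecg_id

    ## ---- diagnosis events ----
    dis_idx <- which(disease == 1, arr.ind = TRUE)
    if (nrow(dis_idx) > 0) {
      ecg_dt <- data.table::data.table(pat = idx, date = ecg_date)
      dis_dt <- data.table::data.table(pat = dis_idx[, 1],
                                       phen = reg$phenotype[dis_idx[, 2]])
      ev <- as.data.frame(merge(dis_dt, ecg_dt, by = "pat",
                                allow.cartesian = TRUE))
      ev <- ev[stats::runif(nrow(ev)) < config$event_rate, , drop = FALSE]
      n_ev <- nrow(ev)
      inside <- stats::runif(n_ev) >= config$window_outside_frac
      delta <- ifelse(inside,
                      round(stats::runif(n_ev, -30, 30)),
                      sample(c(-1, 1), n_ev, TRUE) *
                        round(stats::runif(n_ev, 31, 120)))
      code_pick <- sample(1:2, n_ev, replace = TRUE)
      diagnoses <- data.frame(
        patient_id = patient_id[ev$pat],
        code = paste0("C", gsub(".", "x", ev$phen, fixed = TRUE), "-",
                      code_pick),
        date = ev$date + delta, stringsAsFactors = FALSE)
    } else {
      diagnoses <- data.frame(patient_id = character(), code = character(),
                              date = integer(), stringsAsFactors = FALSE)
    }

    ## ---- assemble ----
    patients <- data.frame(patient_id = patient_id, site_id = site$site_id,
                           age = age, sex = ifelse(female == 1, "F", "M"),
                           race_ethnicity = race, bmi = bmi,
                           stringsAsFactors = FALSE)
    patients <- cbind(patients, as.data.frame(f))
    ecgs <- data.frame(ecg_id = ecg_id, patient_id = patient_id[idx],
                       site_id = site$site_id, date = ecg_date,
                       stringsAsFactors = FALSE)
    ## design AUC: detectability of each phenotype from patient morphology.
    ## For factor phenotypes the score is the posterior (best linear)
    ## estimate of the driving factor given the morphology parameters; for
    ## direct-effect and demographic phenotypes the planted linear predictor
    ## itself is morphology- resp. demographics-based.
    Sigma <- crossprod(L) + diag(tab$sd_patient^2)
    f_hat <- (params_patient - base - dem_part) %*% solve(Sigma, t(L))
    design_auc <- vapply(seq_len(P), function(j) {
      y <- disease[, j]
      if (sum(y) == 0 || sum(y) == n) return(NA_real_)
      score <- if (!is.na(reg$factor[j]) && reg$beta[j] != 0)
        f_hat[, reg$factor[j]] else lin[, j]
      if (stats::sd(score) == 0) return(NA_real_)
      auroc(score, y)
    }, numeric(1))
    list(patients = patients, ecgs = ecgs, diagnoses = diagnoses,
         true_params = params_ecg, measurements = meas, disease = disease,
         design_auc = design_auc)
  })

  statements_of <- function(meas) {
    st <- derive_statements(meas)
    lens <- lengths(st)
    data.frame(ecg_id = rep(rownames(meas), lens),
               statement = unlist(st, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, lapply(site_out, `[[`, "measurements"))
  out <- list(
    patients = do.call(rbind, c(lapply(site_out, `[[`, "patients"),
                                make.row.names = FALSE)),
    diagnoses = do.call(rbind, c(lapply(site_out, `[[`, "diagnoses"),
                                 make.row.names = FALSE)),
    ecgs = do.call(rbind, c(lapply(site_out, `[[`, "ecgs"),
                            make.row.names = FALSE)),
    true_params = do.call(rbind, lapply(site_out, `[[`, "true_params")),
    measurements = measurements,
    statements = statements_of(measurements),
    disease = lapply(site_out, `[[`, "disease"),
    registry = annotate_registry(reg, site_out, config),
    config = config)
  class(out) <- "ecg_cohort"
  out
}

# Attach per-site design AUCs and the strongest planted measurement (name and
# direction) to the registry.
annotate_registry <- function(reg, site_out, config) {
  for (s in names(site_out))
    reg[[paste0("design_auc_", s)]] <- site_out[[s]]$design_auc
  J <- measurement_jacobian(config$duration)
  L <- factor_loadings(config$n_latent_factors)
  pop_sd <- measurement_population_sd(config$duration, config$n_latent_factors)
  de_list <- attr(reg, "direct_effects")
  strongest <- character(nrow(reg)); direction <- numeric(nrow(reg))
  shifts <- matrix(0, nrow(reg), length(pop_sd),
                   dimnames = list(reg$phenotype, names(pop_sd)))
  for (j in seq_len(nrow(reg))) {
    shift <- rep(0, length(pop_sd))
    if (!is.na(reg$factor[j]) && reg$beta[j] != 0)
      shift <- drop(J %*% L[reg$factor[j], ]) / pop_sd
    dej <- de_list[[reg$phenotype[j]]]
    if (!is.null(dej)) shift[match(names(dej), names(pop_sd))] <-
        shift[match(names(dej), names(pop_sd))] + dej
    shifts[j, ] <- shift
    if (any(shift != 0)) {
      k <- which.max(abs(shift))
      strongest[j] <- names(pop_sd)[k]
      direction[j] <- sign(shift[k])
    } else {
      strongest[j] <- NA_character_; direction[j] <- NA_real_
    }
  }
  reg$strongest_measurement <- strongest
  reg$strongest_direction <- direction
  attr(reg, "measurement_shift") <- shifts
  reg
}

#' Derive the noisy device measurement panel
#'
#' Each measurement equals its generating-parameter value plus independent
#' Gaussian measurement noise. The QRS-complex count is an exact function of
#' heart rate and record duration and carries no noise.
#'
#' @param params matrix (or named vector) of generating morphology parameters.
#' @param noise_sd named numeric vector of per-measurement noise SDs; the
#'   default scales each measurement's person-to-person SD by `noise_frac`.
#'   Use 0 for noise-free measurements.
#' @param duration record length in seconds.
#' @param noise_frac fallback fractional noise scale when `noise_sd` is NULL.
#' @param names optional subset of measurement names to return; unknown names
#'   are an error.
#' @return matrix of measurements (rows = ECGs).
#' @export
derive_measurements <- function(params, noise_sd = NULL, duration = 10,
                                noise_frac = 0.2, names = NULL) {
  mm <- measurement_means(params, duration)
  if (is.null(noise_sd))
    noise_sd <- noise_frac * measurement_population_sd(duration)
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, ncol(mm))
  noise_sd <- rep_len(noise_sd, ncol(mm))
  noise_sd[colnames(mm) == "Number of QRS Complexes"] <- 0
  noise <- matrix(stats::rnorm(length(mm)), nrow = nrow(mm)) %*% diag(noise_sd)
  out <- mm + noise
  if (!is.null(names)) {
    unknown <- setdiff(names, colnames(out))
    if (length(unknown)) stop("unknown measurement name(s): ",
                              paste(unknown, collapse = ", "))
    out <- out[, names, drop = FALSE]
  }
  out
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat("Synthetic two-site ECG cohort\n")
  cat("  patients:", nrow(x$patients), " ECGs:", nrow(x$ecgs),
      " diagnosis events:", nrow(x$diagnoses), "\n")
  cat("  phenotypes:", nrow(x$registry),
      sprintf("(%d factor-driven, %d demographic, %d null)\n",
              sum(x$registry$class == "factor"),
              sum(x$registry$class == "demographic"),
              sum(x$registry$class == "null")))
  invisible(x)
}

#' Write cohort tables to a directory
#'
#' Emits `patients.csv`, `diagnoses.csv`, `ecgs.csv`, `measurements.csv`,
#' `statements.csv`, `phecode_map.csv` and `ground_truth.json`.
#'
#' @param cohort an `ecg_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(patients = "patients.csv", diagnoses = "diagnoses.csv",
             ecgs = "ecgs.csv", statements = "statements.csv")
  for (nm in names(files))
    utils::write.csv(cohort[[nm]], file.path(dir, files[nm]),
                     row.names = FALSE)
  meas <- data.frame(ecg_id = rownames(cohort$measurements),
                     cohort$measurements, check.names = FALSE)
  utils::write.csv(meas, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(default_phecode_map(cohort$config$registry),
                   file.path(dir, "phecode_map.csv"), row.names = FALSE)
  gt <- cohort$registry
  attr(gt, "measurement_shift") <- NULL
  jsonlite::write_json(
    list(registry = gt,
         direct_effects = attr(cohort$config$registry, "direct_effects")),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(file.path(dir, c(unname(files), "measurements.csv",
                             "phecode_map.csv", "ground_truth.json")))
}
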