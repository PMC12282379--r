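# ECG morphology model: generating parameters, lead projections, and the
# device-style measurement panel derived from them.

ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

ECG_WAVES <- c("P", "Q", "R", "S", "T")

# Fixed dipole-style projection of each wave's global amplitude onto the 12
# leads. Q and S are rendered as negative deflections (see `wave_sign`).
lead_projection <- function() {
  m <- rbind(
    P = c(0.40, 0.90, 0.50, -0.70, 0.10, 0.70, 0.30, 0.35, 0.40, 0.45, 0.45, 0.40),
    Q = c(0.50, 0.80, 0.40, -0.70, 0.30, 0.60, 0.20, 0.30, 0.50, 0.80, 0.90, 0.80),
    R = c(0.60, 1.00, 0.45, -0.80, 0.25, 0.70, -0.35, 0.25, 0.65, 1.15, 1.10, 0.90),
    S = c(0.40, 0.60, 0.30, -0.50, 0.20, 0.45, 1.20, 1.00, 0.80, 0.50, 0.40, 0.30),
    T = c(0.60, 0.90, 0.35, -0.75, 0.20, 0.65, 0.20, 0.55, 0.75, 0.95, 0.85, 0.70))
  colnames(m) <- ECG_LEADS
  m
}

wave_sign <- c(P = 1, Q = -1, R = 1, S = -1, T = 1)

# Per-ECG generating morphology parameters. Units: ms for intervals, mV for
# amplitudes, bpm for heart rate.
MORPH_PARAMS <- c("hr", "pr", "qrs", "qt", "p_dur", "qtc_disp",
                  "p_amp", "q_amp", "r_amp", "s_amp", "t_amp")

morphology_defaults <- function() {
  tab <- data.frame(
    param      = MORPH_PARAMS,
    mean       = c(72, 160, 95, 390, 100, 30, 0.15, 0.06, 1.05, 0.30, 0.30),
    sd_patient = c(7, 11, 7, 14, 7, 7, 0.030, 0.015, 0.090, 0.050, 0.050),
    sd_ecg     = c(2, 3, 2, 3, 2.5, 2, 0.008, 0.004, 0.025, 0.012, 0.012),
    lower      = c(35, 80, 60, 250, 50, 5, 0.02, 0, 0.10, 0, 0.02),
    upper      = c(180, 320, 200, 600, 180, 120, 0.50, 0.40, 3.0, 1.5, 1.2),
    stringsAsFactors = FALSE)
  rownames(tab) <- tab$param
  tab
}

# Demographic imprint on morphology, per standardized age ((age-60)/17),
# female indicator and standardized BMI ((bmi-27)/5). These are deliberately
# strong: the generator's contract is that age and sex are well recoverable
# from the waveform, so that purely demographic phenotypes are ECG-detectable.
demographic_coefficients <- function() {
  m <- matrix(0, nrow = length(MORPH_PARAMS), ncol = 3,
              dimnames = list(MORPH_PARAMS, c("age_z", "female", "bmi_z")))
  m["hr", ]    <- c(-4.0, 3.0, 0)
  m["pr", ]    <- c(22.0, 0, 0)      # AV conduction slows markedly with age
  m["qrs", ]   <- c(8.0, -9.0, 0)
  m["qt", ]    <- c(4.0, 36.0, 0)    # longer repolarization in women
  m["p_dur", ] <- c(16.0, 0, 0)
  m["p_amp", ] <- c(-0.02, 0, 0)
  m["r_amp", ] <- c(-0.28, -0.32, -0.06)
  m["s_amp", ] <- c(-0.05, -0.14, 0)
  m["t_amp", ] <- c(-0.06, -0.05, 0)
  m
}

# Latent comorbidity factors -> morphology loadings (per +1 SD of factor).
# Factor themes: 1 systemic infection / respiratory failure, 2 marrow /
# white-cell, 3 hepatic, 4 renal / fluid overload.
factor_loadings <- function(n_factors = 4) {
  m <- matrix(0, nrow = n_factors, ncol = length(MORPH_PARAMS),
              dimnames = list(paste0("F", seq_len(n_factors)), MORPH_PARAMS))
  # every loading acts on a waveform-visible parameter so that detectors
  # reading the waveform and detectors reading the measurement panel see the
  # same planted signal (qtc dispersion is measurement noise only)
  m["F1", c("hr", "r_amp", "t_amp", "p_dur")] <- c(14, -0.20, -0.10, -7.5)
  m["F2", c("hr", "qrs", "p_dur", "q_amp", "s_amp")] <-
    c(11, -11, -11, 0.031, 0.09)
  m["F3", c("r_amp", "hr", "s_amp", "t_amp")] <- c(-0.16, 9, 0.06, -0.075)
  m["F4", c("pr", "t_amp", "p_amp", "qt")] <- c(15, 0.11, 0.07, 12.5)
  m
}

#' Names of the synthetic device measurement panel
#'
#' A fixed 40-name stand-in for a proprietary automatic ECG measurement set.
#' Includes every name used by the bundled sparse-model fixtures and the
#' baseline battery.
#'
#' @return character vector of 40 measurement names.
#' @export
measurement_names <- function() {
  c("Number of QRS Complexes", "Heart Rate", "RR interval mean",
    "Mean QRS duration", "QRS Duration in aVF", "QRS Duration in V2",
    "Mean QTc", "QT interval in V5", "QTc dispersion",
    "PR interval in aVR", "PR interval in II", "PR segment in V2",
    "P Duration in II", "P + P' Duration in aVF", "P + P' Duration in V4",
    "P + P' Duration in V6", "P Amplitude in II", "P Amplitude in V1",
    "P Amplitude in aVF", "Q Amplitude in aVF", "Q Amplitude in V5",
    "R Amplitude in II", "R Amplitude in V1", "R Amplitude in V4",
    "R Amplitude in V5", "R Amplitude in aVL", "S Amplitude in V1",
    "S Amplitude in V2", "S Amplitude in aVL", "S Amplitude in V5",
    "T Amplitude in I", "T Amplitude in II", "T Amplitude in aVR",
    "T Amplitude in V5", "QRS total peak to peak amplitude in aVR",
    "QRS total peak to peak amplitude in II",
    "QRS total peak to peak amplitude in V4",
    "QRS total peak to peak amplitude in V5",
    "T-wave area in aVR", "T-wave area in V5")
}

# Rate-adjust the drawn QT interval: the generator draws QT on the reference
# scale (heart rate 72) and the effective per-ECG QT shortens with the RR
# interval (Bazett), so QTc carries the drawn value rather than heart rate.
rate_adjust_qt <- function(params) {
  rr_s <- 60 / params[, "hr"]
  params[, "qt"] <- params[, "qt"] * sqrt(rr_s / (60 / 72))
  params
}

# Number of rendered R peaks for a heart rate (bpm) and duration (s); first
# R peak sits at 0.3 * RR. Shared by the synthesizer and the measurement
# panel so the two are consistent by construction.
n_qrs_complexes <- function(hr, duration) {
  floor(duration * hr / 60 - 0.3 + 1e-9) + 1
}

#' Noise-free measurement panel implied by generating parameters
#'
#' Maps a matrix of morphology parameters to the expected value of each of
#' the 40 panel measurements (no measurement noise added).
#'
#' @param params numeric matrix (rows = ECGs) with columns `MORPH_PARAMS`,
#'   or a named vector for a single ECG.
#' @param duration record length in seconds (for the QRS-complex count).
#' @return matrix (rows = ECGs) with 40 named measurement columns.
#' @export
measurement_means <- function(params, duration = 10) {
  if (is.null(dim(params))) params <- matrix(params, nrow = 1,
                                             dimnames = list(NULL, names(params)))
  M <- lead_projection()
  p <- function(nm) params[, nm]
  rr_s <- 60 / p("hr")
  qtc <- p("qt") / sqrt(rr_s)
  amp <- function(wave, lead, base) wave_sign[wave] * base * M[wave, lead]
  p2p <- function(lead) abs(p("r_amp") * M["R", lead]) +
    p("s_amp") * abs(M["S", lead])
  t_area <- function(lead) p("t_amp") * M["T", lead] * 0.08 * sqrt(2 * pi)
  out <- cbind(
    `Number of QRS Complexes` = n_qrs_complexes(p("hr"), duration),
    `Heart Rate` = p("hr"),
    `RR interval mean` = 60000 / p("hr"),
    `Mean QRS duration` = p("qrs"),
    `QRS Duration in aVF` = p("qrs"),
    `QRS Duration in V2` = 1.02 * p("qrs"),
    `Mean QTc` = qtc,
    `QT interval in V5` = p("qt"),
    `QTc dispersion` = p("qtc_disp"),
    `PR interval in aVR` = p("pr"),
    `PR interval in II` = p("pr"),
    `PR segment in V2` = p("pr") - p("p_dur"),
    `P Duration in II` = p("p_dur"),
    `P + P' Duration in aVF` = 1.05 * p("p_dur"),
    `P + P' Duration in V4` = 1.05 * p("p_dur"),
    `P + P' Duration in V6` = 1.05 * p("p_dur"),
    `P Amplitude in II` = amp("P", "II", p("p_amp")),
    `P Amplitude in V1` = amp("P", "V1", p("p_amp")),
    `P Amplitude in aVF` = amp("P", "aVF", p("p_amp")),
    `Q Amplitude in aVF` = amp("Q", "aVF", p("q_amp")),
    `Q Amplitude in V5` = amp("Q", "V5", p("q_amp")),
    `R Amplitude in II` = amp("R", "II", p("r_amp")),
    `R Amplitude in V1` = amp("R", "V1", p("r_amp")),
    `R Amplitude in V4` = amp("R", "V4", p("r_amp")),
    `R Amplitude in V5` = amp("R", "V5", p("r_amp")),
    `R Amplitude in aVL` = amp("R", "aVL", p("r_amp")),
    `S Amplitude in V1` = amp("S", "V1", p("s_amp")),
    `S Amplitude in V2` = amp("S", "V2", p("s_amp")),
    `S Amplitude in aVL` = amp("S", "aVL", p("s_amp")),
    `S Amplitude in V5` = amp("S", "V5", p("s_amp")),
    `T Amplitude in I` = amp("T", "I", p("t_amp")),
    `T Amplitude in II` = amp("T", "II", p("t_amp")),
    `T Amplitude in aVR` = amp("T", "aVR", p("t_amp")),
    `T Amplitude in V5` = amp("T", "V5", p("t_amp")),
    `QRS total peak to peak amplitude in aVR` = p2p("aVR"),
    `QRS total peak to peak amplitude in II` = p2p("II"),
    `QRS total peak to peak amplitude in V4` = p2p("V4"),
    `QRS total peak to peak amplitude in V5` = p2p("V5"),
    `T-wave area in aVR` = t_area("aVR"),
    `T-wave area in V5` = t_area("V5"))
  out
}

# Finite-difference Jacobian of the measurement panel with respect to the
# generating parameters, evaluated at the population baseline. Used for the
# measurement noise scale and for registering planted effect directions.
measurement_jacobian <- function(duration = 10) {
  tab <- morphology_defaults()
  base <- stats::setNames(tab$mean, tab$param)
  m0 <- drop(measurement_means(base, duration))
  J <- matrix(0, nrow = length(m0), ncol = length(base),
              dimnames = list(names(m0), names(base)))
  for (pp in names(base)) {
    h <- max(1e-4, 1e-4 * abs(base[pp]))
    up <- base; up[pp] <- up[pp] + h
    dn <- base; dn[pp] <- dn[pp] - h
    J[, pp] <- (drop(measurement_means(up, duration)) -
                drop(measurement_means(dn, duration))) / (2 * h)
  }
  # the QRS count is a step function of heart rate; use its smooth slope
  J["Number of QRS Complexes", ] <- 0
  J["Number of QRS Complexes", "hr"] <- duration / 60
  J
}

# Person-to-person SD of each measurement implied by the patient-level
# parameter SDs (linearized, demographic + factor variance included).
measurement_population_sd <- function(duration = 10, n_factors = 4) {
  tab <- morphology_defaults()
  J <- measurement_jacobian(duration)
  dem <- demographic_coefficients()
  L <- factor_loadings(n_factors)
  # independent sources: patient residual, age_z (var 1), female (var .25),
  # bmi_z (var 1), each latent factor (var 1)
  v <- (J %*% diag(tab$sd_patient))^2 %*% rep(1, length(MORPH_PARAMS))
  v <- v + (J %*% dem[, "age_z"])^2 + 0.25 * (J %*% dem[, "female"])^2 +
    (J %*% dem[, "bmi_z"])^2
  for (f in seq_len(n_factors)) v <- v + (J %*% L[f, ])^2
  sqrt(drop(v))
}

#' Deterministic interpretation statements from a measurement vector
#'
#' Emits clinician-style interpretation strings from fixed, strict-inequality
#' thresholds on the measurement panel.
#'
#' @param measurements named numeric vector or matrix (rows = ECGs) carrying
#'   the panel names of [measurement_names()].
#' @param thresholds named list of rule thresholds (see defaults in source).
#' @return a character vector of statements for a single ECG, or a list of
#'   such vectors for a matrix input.
#' @export
derive_statements <- function(measurements, thresholds = statement_thresholds()) {
  single <- is.null(dim(measurements))
  if (single) measurements <- matrix(measurements, nrow = 1,
                                     dimnames = list(NULL, names(measurements)))
  g <- function(nm) measurements[, nm]
  res <- list(
    "sinus tachycardia" = g("Heart Rate") > thresholds$tachycardia_hr,
    "sinus bradycardia" = g("Heart Rate") < thresholds$bradycardia_hr,
    "prolonged QT" = g("Mean QTc") > thresholds$prolonged_qtc,
    "right atrial enlargement" =
      g("P Amplitude in II") > thresholds$rae_p_amplitude,
    "low voltage" =
      g("QRS total peak to peak amplitude in V5") < thresholds$low_voltage_p2p,
    "first degree AV block" = g("PR interval in II") > thresholds$avb_pr)
  out <- lapply(seq_len(nrow(measurements)), function(i) {
    names(res)[vapply(res, function(x) x[i], logical(1))]
  })
  if (single) out[[1]] else out
}

#' @rdname derive_statements
#' @export
statement_thresholds <- function() {
  list(tachycardia_hr = 100, bradycardia_hr = 50, prolonged_qtc = 470,
       rae_p_amplitude = 0.25, low_voltage_p2p = 0.65, avb_pr = 200)
}
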