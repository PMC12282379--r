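# Parametric 12-lead waveform synthesizer: Gaussian-bump beat templates
# timed by RR/PR/QRS/QT, projected onto leads by a fixed projection matrix,
# with sinusoidal baseline wander and white noise.

#' Synthesize one 12-lead waveform
#'
#' Renders each beat as P/Q/R/S/T Gaussian bumps whose timing follows the
#' generating RR, PR, QRS and QT parameters and whose per-lead amplitudes
#' follow the fixed lead projection matrix, then adds sinusoidal baseline
#' wander and white noise.
#'
#' @param params named vector of generating morphology parameters
#'   (see `MORPH_PARAMS`: `hr` bpm, `pr`/`qrs`/`qt`/`p_dur` ms, amplitudes mV).
#' @param sample_rate Hz.
#' @param duration seconds.
#' @param noise_amp white-noise SD in mV (0 for a clean template).
#' @param wander_amp,wander_freq baseline-wander amplitude (mV) and
#'   frequency (Hz); amplitude 0 disables wander.
#' @param seed optional seed for the noise draws (the template itself is
#'   deterministic).
#' @return numeric matrix, 12 rows (leads I, II, III, aVR, aVL, aVF, V1-V6)
#'   by `sample_rate * duration` columns, in millivolts.
#' @export
synthesize_waveform <- function(params, sample_rate = 500, duration = 10,
                                noise_amp = 0.015, wander_amp = 0.05,
                                wander_freq = 0.33, seed = NULL) {
  p <- as.list(params[MORPH_PARAMS])
  if (any(!is.finite(unlist(p)))) stop("non-finite morphology parameters")
  if (p$hr <= 0) stop("heart rate must be positive")
  rr <- 60 / p$hr                      # seconds
  pr_s <- p$pr / 1000; qrs_s <- p$qrs / 1000
  qt_s <- p$qt / 1000; pd_s <- p$p_dur / 1000
  # rejection: the T wave must end before the next R complex begins, and a
  # full P wave must fit inside one RR interval
  if (0.75 * qt_s + 0.16 >= rr || pr_s + pd_s >= rr)
    stop("rejected: parameters imply overlapping beats")
  n <- round(sample_rate * duration)
  t <- (seq_len(n) - 1) / sample_rate
  r_times <- seq(0.3 * rr, duration, by = rr)
  # wave centers relative to the R peak and Gaussian widths
  centers <- c(P = -pr_s, Q = -0.30 * qrs_s, R = 0, S = 0.30 * qrs_s,
               T = 0.75 * qt_s)
  widths <- c(P = pd_s / 4, Q = qrs_s / 8, R = qrs_s / 5, S = qrs_s / 8,
              T = 0.08)
  amps <- c(P = p$p_amp, Q = p$q_amp, R = p$r_amp, S = p$s_amp, T = p$t_amp)
  sources <- matrix(0, nrow = length(ECG_WAVES), ncol = n,
                    dimnames = list(ECG_WAVES, NULL))
  for (w in ECG_WAVES) {
    sig <- widths[w]
    for (rc in r_times) {
      c0 <- rc + centers[w]
      i0 <- max(1L, floor((c0 - 4 * sig) * sample_rate) + 1L)
      i1 <- min(n, ceiling((c0 + 4 * sig) * sample_rate) + 1L)
      if (i1 < i0) next
      tt <- t[i0:i1]
      sources[w, i0:i1] <- sources[w, i0:i1] +
        amps[w] * exp(-(tt - c0)^2 / (2 * sig^2))
    }
  }
  M <- lead_projection() * wave_sign[ECG_WAVES]
  x <- t(M) %*% sources                # 12 x n
  rownames(x) <- ECG_LEADS
  if (wander_amp > 0 || noise_amp > 0) {
    if (!is.null(seed)) set.seed(seed)
    if (wander_amp > 0) {
      phase <- stats::runif(12, 0, 2 * pi)
      x <- x + wander_amp *
        sin(outer(rep(2 * pi * wander_freq, 12), t) + phase)
    }
    if (noise_amp > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, noise_amp), nrow = 12)
  }
  x
}

#' Waveform for one (or several) cohort ECGs
#'
#' Lazily synthesizes the waveform(s) for ECG records of an [generate_cohort()]
#' cohort, using a per-record seed derived from the cohort seed so repeated
#' calls are reproducible.
#'
#' @param cohort an `ecg_cohort`.
#' @param ecg_ids character vector of ECG ids (default: all).
#' @return a single 12 x samples matrix if one id is given, else a named list.
#' @export
ecg_waveform <- function(cohort, ecg_ids = cohort$ecgs$ecg_id) {
  cfg <- cohort$config
  pos <- match(ecg_ids, rownames(cohort$true_params))
  if (anyNA(pos)) stop("unknown ecg_id(s): ",
                       paste(ecg_ids[is.na(pos)], collapse = ", "))
  out <- lapply(seq_along(pos), function(i) {
    synthesize_waveform(cohort$true_params[pos[i], ],
                        sample_rate = cfg$sample_rate,
                        duration = cfg$duration,
                        noise_amp = cfg$noise_amp,
                        wander_amp = cfg$wander_amp,
                        wander_freq = cfg$wander_freq,
                        seed = (cfg$seed * 1000003L + pos[i]) %% 2147483629L)
  })
  names(out) <- ecg_ids
  if (length(out) == 1) out[[1]] else out
}

#' Simple threshold R-peak counter
#'
#' Counts R peaks in a single-lead trace as local maxima above a fraction of
#' the global maximum; used for waveform/measurement consistency checks.
#'
#' @param x numeric vector (one lead).
#' @param frac detection threshold as a fraction of `max(x)`.
#' @return integer peak count.
#' @export
count_r_peaks <- function(x, frac = 0.6) {
  thr <- frac * max(x)
  above <- x > thr
  # rising edges of the above-threshold regions
  sum(diff(c(FALSE, above)) == 1)
}
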