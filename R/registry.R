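# The planted ground-truth effect registry: which phenotypes exist, what
# drives them (latent comorbidity factors, demographics, direct measurement
# effects, or nothing), and how prevalent they are.

#' Default planted phenotype registry
#'
#' Sixty phecode-style phenotypes: 25 disease-factor-driven (two of them via
#' direct measurement effects), 5 demographic-only, 30 pure null. Each carries
#' a phecode-like id (decimal suffixes denote hierarchy children), a category,
#' a planted effect class, the driving latent factor and loading strength, and
#' demographic logit coefficients. All effect directions are shared across
#' sites.
#'
#' @return `data.frame` with one row per phenotype and attribute
#'   `direct_effects` (named list of named measurement-effect vectors, on the
#'   standardized measurement scale).
#' @export
default_registry <- function() {
  fd <- function(id, desc, cat, factor, beta, prev)
    data.frame(phenotype = id, description = desc, category = cat,
               class = "factor", factor = factor, beta = beta,
               age_coef = 0, sex_coef = 0, base_prev = prev,
               prev_multiplier = 1, stringsAsFactors = FALSE)
  dem <- function(id, desc, cat, age, sex, prev)
    data.frame(phenotype = id, description = desc, category = cat,
               class = "demographic", factor = NA_integer_, beta = 0,
               age_coef = age, sex_coef = sex, base_prev = prev,
               prev_multiplier = 1, stringsAsFactors = FALSE)
  nul <- function(id, cat)
    data.frame(phenotype = id, description = paste0("Null phenotype ", id,
               " (synthetic)"), category = cat,
               class = "null", factor = NA_integer_, beta = 0,
               age_coef = 0, sex_coef = 0, base_prev = 0.08,
               prev_multiplier = 1, stringsAsFactors = FALSE)
  reg <- rbind(
    fd("038",    "Septicaemia-like syndrome (synthetic)", "infectious diseases", 1L, 2.4, 0.15),
    fd("038.1",  "Gram-negative septicaemia-like (synthetic)", "infectious diseases", 1L, 2.3, 0.12),
    fd("480",    "Bacterial pneumonia-like (synthetic)", "respiratory", 1L, 2.3, 0.14),
    fd("509",    "Respiratory failure-like (synthetic)", "respiratory", 1L, 3.0, 0.16),
    fd("994.2",  "Systemic inflammatory response-like (synthetic)", "injuries & poisonings", 1L, 2.3, 0.12),
    fd("427.2",  "Cardiac arrest-like (synthetic)", "circulatory system", 1L, 2.4, 0.12),
    fd("276.11", "Hyperosmolality-like (synthetic)", "endocrine/metabolic", 1L, 1.1, 0.12),
    fd("288.11", "Neutropenia-like (synthetic)", "hematopoietic", 2L, 2.4, 0.15),
    fd("204",    "Leukaemia-like (synthetic)", "neoplasms", 2L, 2.2, 0.14),
    fd("204.1",  "Lymphoid leukaemia-like (synthetic)", "neoplasms", 2L, 2.3, 0.12),
    fd("284.1",  "Pancytopenia-like (synthetic)", "hematopoietic", 2L, 2.4, 0.13),
    fd("117",    "Mycoses-like (synthetic)", "infectious diseases", 2L, 2.3, 0.12),
    fd("285",    "Anaemia-like (synthetic)", "hematopoietic", 2L, 1.0, 0.14),
    fd("571",    "Chronic liver disease-like (synthetic)", "digestive", 3L, 2.6, 0.15),
    fd("571.5",  "Cirrhosis-like (synthetic)", "digestive", 3L, 2.4, 0.12),
    fd("573",    "Liver necrosis-like (synthetic)", "digestive", 3L, 2.5, 0.12),
    fd("530.7",  "Oesophageal bleeding-like (synthetic)", "digestive", 3L, 2.4, 0.12),
    fd("575",    "Biliary disorder-like (synthetic)", "digestive", 3L, 1.1, 0.12),
    fd("585",    "Renal failure-like (synthetic)", "genitourinary", 4L, 2.4, 0.15),
    fd("276.6",  "Fluid overload-like (synthetic)", "endocrine/metabolic", 4L, 2.2, 0.14),
    fd("275.53", "Phosphorus disorder-like (synthetic)", "endocrine/metabolic", 4L, 2.2, 0.12),
    fd("514",    "Pulmonary congestion-like (synthetic)", "respiratory", 4L, 2.2, 0.13),
    fd("428",    "Congestive heart failure-like (synthetic)", "circulatory system", 4L, 2.2, 0.15),
    fd("577.2",  "Ascites-like (synthetic, direct measurement effects)", "digestive", NA_integer_, 0, 0.13),
    fd("519",    "Lung transplant-like (synthetic, direct measurement effects)", "respiratory", NA_integer_, 0, 0.12),
    dem("626", "Menstrual disorder analogue (synthetic)", "genitourinary", -1.8, 2.8, 0.12),
    dem("290", "Dementia-like (synthetic)", "mental disorders", 2.5, 0, 0.10),
    dem("600", "Prostatic hyperplasia-like (synthetic)", "genitourinary", 1.5, -3.0, 0.10),
    dem("174", "Breast neoplasm-like (synthetic)", "neoplasms", 0.8, 2.5, 0.10),
    dem("627", "Menopausal disorder-like (synthetic)", "genitourinary", 0, 3.0, 0.10),
    nul("401", "circulatory system"), nul("394", "circulatory system"),
    nul("411", "circulatory system"), nul("425", "circulatory system"),
    nul("426", "circulatory system"), nul("433", "circulatory system"),
    nul("442", "circulatory system"), nul("447", "circulatory system"),
    nul("250", "endocrine/metabolic"), nul("272", "endocrine/metabolic"),
    nul("296", "mental disorders"), nul("300", "mental disorders"),
    nul("327", "neurological"), nul("338", "neurological"),
    nul("340", "neurological"), nul("345", "neurological"),
    nul("362", "sense organs"), nul("366", "sense organs"),
    nul("475", "respiratory"), nul("495", "respiratory"),
    nul("531", "digestive"), nul("550", "digestive"),
    nul("560", "digestive"), nul("592", "genitourinary"),
    nul("599", "genitourinary"), nul("614", "genitourinary"),
    nul("696", "dermatologic"), nul("710", "musculoskeletal"),
    nul("715", "musculoskeletal"), nul("800", "injuries & poisonings"))
  rownames(reg) <- reg$phenotype
  attr(reg, "direct_effects") <- list(
    "577.2" = c("QRS total peak to peak amplitude in V5" = -0.9,
                "Heart Rate" = 0.8, "Mean QTc" = 0.6),
    "519" = c("Mean QTc" = -0.7, "PR interval in aVR" = -0.6,
              "P Amplitude in II" = 0.9))
  reg
}

validate_registry <- function(reg, n_factors) {
  stopifnot(is.data.frame(reg), nrow(reg) > 0)
  if (anyDuplicated(reg$phenotype)) stop("duplicate phenotype ids in registry")
  if (!all(reg$class %in% c("factor", "demographic", "null")))
    stop("every phenotype must have class 'factor', 'demographic' or 'null'")
  bad <- !is.na(reg$factor) & (reg$factor < 1 | reg$factor > n_factors)
  if (any(bad)) stop("factor index out of range for: ",
                     paste(reg$phenotype[bad], collapse = ", "))
  if (any(reg$prev_multiplier < 0)) stop("prevalence multipliers must be >= 0")
  de <- attr(reg, "direct_effects")
  if (!is.null(de)) {
    unknown <- setdiff(unlist(lapply(de, names)), measurement_names())
    if (length(unknown))
      stop("direct effects on unknown measurements: ",
           paste(unknown, collapse = ", "))
  }
  invisible(reg)
}

#' Synthetic diagnosis-code to phecode mapping table
#'
#' Two ICD-like codes per registry phenotype, in the CSV shape accepted by
#' [load_phecode_map()] (`code`, `phecode`, `description`, `category`).
#'
#' @param registry a phenotype registry, see [default_registry()].
#' @return `data.frame` with one row per diagnosis code.
#' @export
default_phecode_map <- function(registry = default_registry()) {
  do.call(rbind, lapply(seq_len(nrow(registry)), function(i) {
    ph <- registry$phenotype[i]
    data.frame(code = paste0("C", gsub(".", "x", ph, fixed = TRUE), "-",
                             1:2),
               phecode = ph, description = registry$description[i],
               category = registry$category[i], stringsAsFactors = FALSE)
  }))
}

# Solve for the logit intercept giving a target population prevalence when
# the linear predictor is b0 + N(0, gauss_sd) + sex_coef * female.
calibrate_intercept <- function(target_prev, gauss_sd, sex_coef = 0,
                                female_frac = 0.5) {
  if (target_prev <= 0) return(-Inf)
  if (target_prev >= 1) return(Inf)
  z <- seq(-6, 6, length.out = 241)
  w <- stats::dnorm(z); w <- w / sum(w)
  prev_at <- function(b0) {
    p1 <- sum(w * stats::plogis(b0 + gauss_sd * z + sex_coef))
    p0 <- sum(w * stats::plogis(b0 + gauss_sd * z))
    female_frac * p1 + (1 - female_frac) * p0
  }
  stats::uniroot(function(b0) prev_at(b0) - target_prev,
                 lower = -20, upper = 10, tol = 1e-9)$root
}
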