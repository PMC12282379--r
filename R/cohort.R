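# Phecode label construction: ICD -> phecode mapping with hierarchy closure,
# the time-window ECG/diagnosis association, patient-level splits, and the
# phenotype inclusion filter.

#' Phecode hierarchy by decimal-string truncation
#'
#' The parent of `"204.11"` is `"204.1"`, whose parent is `"204"`; integer
#' roots have no parent.
#'
#' @param phecode character vector of phecode ids.
#' @return `phecode_parent`: parent id or `NA` at a root.
#'   `phecode_ancestors`: list of all ancestors (nearest first).
#' @export
phecode_parent <- function(phecode) {
  has_dec <- grepl(".", phecode, fixed = TRUE)
  out <- rep(NA_character_, length(phecode))
  trimmed <- sub(".$", "", phecode[has_dec])
  trimmed <- sub("\\.$", "", trimmed)
  out[has_dec] <- trimmed
  out
}

#' @rdname phecode_parent
#' @export
phecode_ancestors <- function(phecode) {
  lapply(phecode, function(p) {
    anc <- character()
    while (!is.na(p <- phecode_parent(p))) anc <- c(anc, p)
    anc
  })
}

#' Load a diagnosis-code to phecode mapping table
#'
#' @param path CSV file with columns `code`, `phecode` and optionally
#'   `description`, `category`; or a data frame of that shape.
#' @return validated `data.frame`.
#' @export
load_phecode_map <- function(path) {
  map <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(code = "character",
                                   phecode = "character"))
  if (nrow(map) == 0) stop("configuration error: empty phecode map")
  if (!all(c("code", "phecode") %in% names(map)))
    stop("phecode map needs 'code' and 'phecode' columns")
  map$code <- as.character(map$code)
  map$phecode <- as.character(map$phecode)
  if (anyDuplicated(map$code))
    stop("each diagnosis code must map to at most one phecode")
  map
}

#' Map diagnosis events to phecode events
#'
#' Each event is translated via the map; unmapped codes are dropped (their
#' count is reported). With `closure = TRUE` (default) an event for a child
#' phecode also emits events for all its ancestors in the truncation
#' hierarchy, so hierarchical parents accumulate their descendants' events.
#'
#' @param events data frame with `patient_id`, `code`, `date`.
#' @param map mapping table from [load_phecode_map()].
#' @param closure label ancestors as well (set `FALSE` for leaf-only labels).
#' @return data frame `patient_id`, `phecode`, `date` (deduplicated), with
#'   attribute `n_unmapped`.
#' @export
map_icd_to_phecode <- function(events, map, closure = TRUE) {
  map <- load_phecode_map(map)
  m <- match(events$code, map$code)
  n_unmapped <- sum(is.na(m))
  ev <- data.frame(patient_id = events$patient_id[!is.na(m)],
                   phecode = map$phecode[m[!is.na(m)]],
                   date = events$date[!is.na(m)], stringsAsFactors = FALSE)
  if (closure && nrow(ev) > 0) {
    anc <- phecode_ancestors(ev$phecode)
    lens <- lengths(anc)
    if (any(lens > 0)) {
      extra <- data.frame(patient_id = rep(ev$patient_id, lens),
                          phecode = unlist(anc, use.names = FALSE),
                          date = rep(ev$date, lens),
                          stringsAsFactors = FALSE)
      ev <- rbind(ev, extra)
    }
  }
  ev <- unique(ev)
  attr(ev, "n_unmapped") <- n_unmapped
  ev
}

#' Associate phecode events with ECGs inside a time window
#'
#' An ECG is positive for a phenotype iff some event for that phenotype lies
#' within `window_days` calendar days of the ECG (inclusive boundary, so a
#' 30-day window includes an exact 30-day gap). All ECGs are kept, including
#' ECGs with no associated events (all-negative rows).
#'
#' @param ecgs data frame with `ecg_id`, `patient_id`, `date`.
#' @param events phecode events from [map_icd_to_phecode()].
#' @param window_days half-width of the association window (days, >= 0).
#' @param phenotypes phenotype universe for the columns (default: those seen
#'   in `events`).
#' @return sparse logical label matrix (`Matrix::sparseMatrix`), ECGs x
#'   phenotypes, with dimnames.
#' @export
associate_labels <- function(ecgs, events, window_days = 30,
                             phenotypes = NULL) {
  stopifnot(window_days >= 0)
  if (is.null(phenotypes)) phenotypes <- sort(unique(events$phecode))
  # events for patients with no ECGs simply never match
  e_dt <- data.table::data.table(patient_id = ecgs$patient_id,
                                 ecg_row = seq_len(nrow(ecgs)),
                                 date = ecgs$date)
  v_dt <- data.table::data.table(patient_id = events$patient_id,
                                 phecode = events$phecode,
                                 evdate = events$date)
  hit <- as.data.frame(merge(e_dt, v_dt, by = "patient_id",
                             allow.cartesian = TRUE))
  hit <- hit[abs(hit$date - hit$evdate) <= window_days, , drop = FALSE]
  hit <- unique(hit[, c("ecg_row", "phecode")])
  hit <- hit[hit$phecode %in% phenotypes, , drop = FALSE]
  Matrix::sparseMatrix(i = hit$ecg_row,
                       j = match(hit$phecode, phenotypes),
                       x = 1,
                       dims = c(nrow(ecgs), length(phenotypes)),
                       dimnames = list(ecgs$ecg_id, phenotypes))
}

# FNV-1a style string hash mixed with a seed, mapped to [0, 1). Stable
# across sessions and independent of the R RNG stream.
hash_unit <- function(ids, seed) {
  vapply(ids, function(id) {
    h <- (2166136261 + seed * 7919) %% 2147483647
    for (ch in utf8ToInt(id)) h <- (h * 16777619 + ch * 31 + seed) %% 2147483647
    # one more scramble round
    h <- (h * 48271) %% 2147483647
    h / 2147483647
  }, numeric(1), USE.NAMES = FALSE)
}

#' Patient-level train/tune/test split
#'
#' Assigns each patient to a split so that all of a patient's ECGs share a
#' split. `method = "hash"` thresholds a seeded hash of the patient id
#' (expected proportions equal the ratio); `method = "quota"` assigns exact
#' quotas by seeded hash order.
#'
#' @param patient_ids character vector of unique patient ids.
#' @param ratio positive weights for (train, tune, test); default `c(5,1,4)`.
#' @param seed integer seed.
#' @param method `"hash"` or `"quota"`.
#' @return factor of levels `train`, `tune`, `test`, named by patient id.
#' @export
split_patients <- function(patient_ids, ratio = c(5, 1, 4), seed = 1,
                           method = c("hash", "quota")) {
  method <- match.arg(method)
  stopifnot(length(ratio) == 3, all(ratio > 0))
  if (anyDuplicated(patient_ids)) stop("patient ids must be unique")
  cuts <- cumsum(ratio) / sum(ratio)
  u <- hash_unit(patient_ids, seed)
  lv <- c("train", "tune", "test")
  if (method == "hash") {
    s <- lv[1 + findInterval(u, cuts[1:2])]
  } else {
    n <- length(patient_ids)
    quota <- diff(c(0, floor(cuts * n)))
    quota[3] <- n - sum(quota[1:2])
    s <- rep(lv, quota)[rank(u, ties.method = "first")]
  }
  stats::setNames(factor(s, levels = lv), patient_ids)
}

#' Phenotype inclusion filter
#'
#' Includes a phenotype iff it has at least `min_total` positive ECGs overall
#' and at least `min_per_split` in each of the train, tune and test splits.
#'
#' @param labels label matrix (ECGs x phenotypes).
#' @param ecg_split factor/character of split per ECG row.
#' @param min_total,min_per_split inclusion thresholds (defaults 100 / 10).
#' @return data frame per phenotype: counts, `included`, `reason`.
#' @export
filter_phenotypes <- function(labels, ecg_split, min_total = 100,
                              min_per_split = 10) {
  ecg_split <- factor(ecg_split, levels = c("train", "tune", "test"))
  stopifnot(length(ecg_split) == nrow(labels))
  total <- Matrix::colSums(labels)
  per <- vapply(levels(ecg_split), function(s)
    Matrix::colSums(labels[ecg_split == s, , drop = FALSE]),
    numeric(ncol(labels)))
  if (is.null(dim(per))) per <- matrix(per, nrow = 1,
                                       dimnames = list(NULL, names(per)))
  res <- data.frame(phenotype = colnames(labels), n_total = total,
                    n_train = per[, "train"], n_tune = per[, "tune"],
                    n_test = per[, "test"], stringsAsFactors = FALSE,
                    row.names = NULL)
  res$included <- res$n_total >= min_total &
    res$n_train >= min_per_split & res$n_tune >= min_per_split &
    res$n_test >= min_per_split
  res$reason <- ifelse(res$included, "",
    ifelse(res$n_total < min_total, "total_count",
           "per_split_count"))
  res
}

#' Build per-site label matrices from a cohort
#'
#' Convenience wrapper running the full labelling path on a generated
#' cohort: ICD to phecode mapping (with optional hierarchy closure), window
#' association, patient-level splitting, and the inclusion filter.
#'
#' @param cohort an `ecg_cohort`.
#' @param window_days association window (default 30).
#' @param closure hierarchy closure flag, see [map_icd_to_phecode()].
#' @param ratio,seed,method split parameters, see [split_patients()].
#' @param min_total,min_per_split inclusion thresholds.
#' @return list per site id: `labels` (sparse matrix), `split` (per-ECG
#'   factor), `filter` (inclusion table), `included` (phenotype ids).
#' @export
build_labels <- function(cohort, window_days = 30, closure = TRUE,
                         ratio = c(5, 1, 4), seed = cohort$config$seed,
                         method = "hash", min_total = 100,
                         min_per_split = 10) {
  map <- default_phecode_map(cohort$config$registry)
  phenos <- cohort$config$registry$phenotype
  ev <- map_icd_to_phecode(cohort$diagnoses, map, closure = closure)
  out <- list()
  for (s in unique(cohort$ecgs$site_id)) {
    ecgs_s <- cohort$ecgs[cohort$ecgs$site_id == s, ]
    pats_s <- cohort$patients$patient_id[cohort$patients$site_id == s]
    ev_s <- ev[ev$patient_id %in% pats_s, ]
    labels <- associate_labels(ecgs_s, ev_s, window_days, phenotypes = phenos)
    split_p <- split_patients(pats_s, ratio, seed = seed, method = method)
    ecg_split <- split_p[ecgs_s$patient_id]
    filt <- filter_phenotypes(labels, ecg_split, min_total, min_per_split)
    out[[s]] <- list(labels = labels, split = ecg_split, filter = filt,
                     included = filt$phenotype[filt$included],
                     ecg_ids = ecgs_s$ecg_id)
  }
  out
}
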