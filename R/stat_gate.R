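# Rank statistics, multiple-testing control and the two-site replication gate.

#' Area under the ROC curve (midrank formulation)
#'
#' Computes the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with tied scores counted 1/2. Identical to the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric vector of real-valued scores (logits or probabilities;
#'   AUROC is invariant to monotone transforms).
#' @param labels binary vector (0/1 or logical) of the same length.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(.9, .8, .1, .2), c(1, 1, 0, 0)) # 1
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Mann-Whitney U statistic
#'
#' @inheritParams auroc
#' @return U computed from midranks (the statistic for the positive group).
#' @export
mwu_u <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  n1 <- sum(labels == 1L)
  r <- rank(scores, ties.method = "average")
  sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
}

check_binary_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not contain NA")
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("undefined metric: need at least one positive and one negative")
  labels
}

#' Two-tailed Mann-Whitney U test
#'
#' Tests the null hypothesis that scores for positive and negative ECGs are
#' drawn from the same distribution. For small samples
#' (`choose(n, min(n1, n0)) <= exact_limit`) the two-tailed p-value is computed
#' by complete enumeration of all label assignments to the observed score
#' multiset (so ties are handled exactly); otherwise a tie-corrected normal
#' approximation without continuity correction is used.
#'
#' @inheritParams auroc
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit maximum number of enumerated assignments for the exact
#'   path under `"auto"`.
#' @return list with elements `U`, `p`, `method`, `n_pos`, `n_neg`.
#' @export
mwu_test <- function(scores, labels, method = c("auto", "exact", "normal"),
                     exact_limit = 20000) {
  method <- match.arg(method)
  labels <- check_binary_labels(scores, labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L); n <- n1 + n0
  u <- mwu_u(scores, labels)
  n_comb <- suppressWarnings(choose(n, min(n1, n0)))
  if (method == "auto")
    method <- if (is.finite(n_comb) && n_comb <= exact_limit) "exact" else "normal"
  if (method == "exact") {
    if (!is.finite(n_comb) || n_comb > 5e6)
      stop("exact enumeration infeasible for this sample size")
    r <- rank(scores, ties.method = "average")
    idx <- utils::combn(n, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n0 / 2
    # two-tailed: assignments at least as extreme (distance from the mean)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    mu <- n1 * n0 / 2
    ties <- rle(sort(scores))$lengths
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u, p = 1, method = method,
                                 n_pos = n1, n_neg = n0))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(p, 1)
  }
  list(U = u, p = p, method = method, n_pos = n1, n_neg = n0)
}

#' Bonferroni significance gate
#'
#' Flags phenotypes whose p-value falls below `alpha / n_tests`. The cutoff
#' for `alpha = 0.01` over 1243 tested phenotypes is approximately 8e-6.
#'
#' @param p numeric vector of two-tailed p-values.
#' @param alpha family-wise level (default 0.01).
#' @param n_tests number of tests in the family (defaults to `length(p)`).
#' @return logical vector: `p < alpha / n_tests`.
#' @export
significance_gate <- function(p, alpha = 0.01, n_tests = length(p)) {
  if (n_tests <= 0) stop("n_tests must be positive")
  p < bonferroni_cutoff(alpha, n_tests)
}

#' @rdname significance_gate
#' @export
bonferroni_cutoff <- function(alpha = 0.01, n_tests) {
  if (n_tests <= 0) stop("n_tests must be positive")
  alpha / n_tests
}

#' Evaluate per-phenotype detection at one site
#'
#' Computes, for each phenotype column of a label matrix, the AUROC, the
#' Mann-Whitney U statistic and two-tailed p-value, the positive/negative
#' counts, AUPRC, and the specificity-closest-to-target operating point.
#'
#' @param scores matrix (ECG x phenotype) of real-valued scores.
#' @param labels binary matrix of identical shape and column names.
#' @param site_id character tag stored in the result.
#' @param target_specificity operating-point target (default 0.90).
#' @param mwu_method passed to [mwu_test()].
#' @return `data.frame` with one row per phenotype (class `gate_result`).
#' @export
gate_results <- function(scores, labels, site_id = "A",
                         target_specificity = 0.90, mwu_method = "auto") {
  stopifnot(nrow(scores) == nrow(labels), ncol(scores) == ncol(labels))
  ids <- colnames(labels)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(labels)))
  rows <- lapply(seq_len(ncol(labels)), function(j) {
    y <- as.numeric(labels[, j]); s <- as.numeric(scores[, j])
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) {
      return(data.frame(phenotype = ids[j], site = site_id, n_pos = n1,
                        n_neg = n0, U = NA_real_, p = NA_real_,
                        auroc = NA_real_, auprc = NA_real_,
                        threshold = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, ppv = NA_real_, f1 = NA_real_,
                        stringsAsFactors = FALSE))
    }
    mw <- mwu_test(s, y, method = mwu_method)
    op <- operating_point(s, y, target_specificity = target_specificity)
    data.frame(phenotype = ids[j], site = site_id, n_pos = n1, n_neg = n0,
               U = mw$U, p = mw$p, auroc = mw$U / (n1 * n0),
               auprc = auprc(s, y), threshold = op$threshold,
               sensitivity = op$sensitivity, specificity = op$specificity,
               ppv = op$ppv, f1 = op$f1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gate_result", class(out))
  out
}

#' Two-site replication gate
#'
#' Applies the multi-step filter: Bonferroni significance at the discovery
#' site, a minimum positive-ECG count at the discovery site, the same count
#' filter at the replication site, then AUC thresholds (default 0.80 at the
#' discovery site and 0.75 at the replication site; `reversed = TRUE` swaps
#' them). Per-stage survivor counts are returned as an audit funnel.
#'
#' @param results_a,results_b `gate_result` data frames for the two sites.
#' @param alpha,n_tests Bonferroni parameters; `n_tests` defaults to the
#'   number of phenotypes tested at site A.
#' @param min_count minimum positive ECGs required at each site (default 500).
#' @param thr_a,thr_b AUC thresholds for sites A and B.
#' @param reversed swap the two AUC thresholds (sensitivity analysis).
#' @return list with `shortlist` (phenotype ids), `table` (per-phenotype flags
#'   and the stage at which a phenotype was dropped) and `funnel` (named stage
#'   counts: tested, significant, count_a, count_b, auc_gate).
#' @export
replication_gate <- function(results_a, results_b, alpha = 0.01,
                             n_tests = nrow(results_a), min_count = 500,
                             thr_a = 0.80, thr_b = 0.75, reversed = FALSE) {
  if (reversed) { tmp <- thr_a; thr_a <- thr_b; thr_b <- tmp }
  a <- results_a[, c("phenotype", "n_pos", "p", "auroc")]
  names(a) <- c("phenotype", "n_pos_a", "p_a", "auroc_a")
  b <- results_b[, c("phenotype", "n_pos", "auroc")]
  names(b) <- c("phenotype", "n_pos_b", "auroc_b")
  tab <- merge(a, b, by = "phenotype", all.x = TRUE)
  tab$significant <- !is.na(tab$p_a) & significance_gate(tab$p_a, alpha, n_tests)
  tab$count_a_ok <- tab$significant & tab$n_pos_a >= min_count
  tab$count_b_ok <- tab$count_a_ok & !is.na(tab$n_pos_b) & tab$n_pos_b >= min_count
  tab$shortlist <- tab$count_b_ok & !is.na(tab$auroc_a) & !is.na(tab$auroc_b) &
    tab$auroc_a >= thr_a & tab$auroc_b >= thr_b
  tab$dropped_at <- ifelse(tab$shortlist, "",
    ifelse(!tab$significant, "significance",
      ifelse(!tab$count_a_ok, "count_a",
        ifelse(!tab$count_b_ok, "count_b", "auc_gate"))))
  funnel <- c(tested = nrow(tab), significant = sum(tab$significant),
              count_a = sum(tab$count_a_ok), count_b = sum(tab$count_b_ok),
              auc_gate = sum(tab$shortlist))
  list(shortlist = tab$phenotype[tab$shortlist], table = tab, funnel = funnel)
}

#' Operating point at a target specificity
#'
#' Chooses, among candidate thresholds (midpoints between consecutive distinct
#' observed scores, plus sentinels beyond the extremes), the one whose
#' specificity is closest to the target, breaking ties toward the higher
#' specificity, and reports the confusion matrix and derived metrics there.
#'
#' @inheritParams auroc
#' @param target_specificity target (default 0.90).
#' @return list: `threshold`, `sensitivity`, `specificity`, `ppv`, `f1`, and
#'   confusion counts `tp`, `fp`, `tn`, `fn` (prediction positive when
#'   `score >= threshold`).
#' @export
operating_point <- function(scores, labels, target_specificity = 0.90) {
  labels <- check_binary_labels(scores, labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  s <- sort(unique(scores))
  m <- length(s)
  cand <- c(s[1] - 1, if (m > 1) (s[-1] + s[-m]) / 2, s[m] + 1)
  # negatives with score <= s_i, cumulative over the distinct values
  cn <- cumsum(vapply(split(labels == 0L, match(scores, s))[as.character(
    seq_len(m))], sum, numeric(1)))
  tn <- c(0, cn)                       # per candidate threshold
  spec <- tn / n0
  key1 <- abs(spec - target_specificity)
  ord <- order(key1, -spec)
  thr <- cand[ord[1]]
  pred <- scores >= thr
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L); fn <- sum(!pred & labels == 1L)
  sens <- tp / n1; spec <- tn / n0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(ppv) || ppv + sens == 0) 0 else 2 * ppv * sens / (ppv + sens)
  list(threshold = thr, sensitivity = sens, specificity = spec,
       ppv = ppv, f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the precision-recall curve
#'
#' Step interpolation over ranked scores: positives are accumulated from the
#' highest score down and the area is the sum of `precision * delta_recall`
#' over distinct thresholds.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  n1 <- sum(y)
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp); rec <- tp / n1
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Cross-site AUC agreement summary
#'
#' @param aucs_a,aucs_b named numeric vectors of AUCs over a common phenotype
#'   set (names are intersected).
#' @return list: `n`, `frac_within_05`, `frac_within_10`, and among phenotypes
#'   with a gap above 0.10, counts of which site was higher.
#' @export
cross_site_agreement <- function(aucs_a, aucs_b) {
  common <- intersect(names(aucs_a), names(aucs_b))
  if (length(common) == 0) stop("no common phenotypes")
  d <- aucs_a[common] - aucs_b[common]
  list(n = length(common),
       frac_within_05 = mean(abs(d) <= 0.05),
       frac_within_10 = mean(abs(d) <= 0.10),
       n_gap_a_higher = sum(d > 0.10),
       n_gap_b_higher = sum(d < -0.10))
}
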