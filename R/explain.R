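# Sparse interpretable linear detectors (lasso path selection + unregularized
# refit) and interpretation-statement odds ratios.

#' Lasso-path feature selection
#'
#' Walks the lasso regularization path from strong to weak penalty on the
#' z-scored training measurements and records the order in which features
#' enter the active set. Features on the exclusion list (the mechanized
#' stand-in for hand-examination) never enter; optionally, the later
#' entrant of any highly correlated pair is pruned. The first `k_max`
#' entrants are returned in entry order.
#'
#' @param measurements training measurement matrix (will be z-scored).
#' @param labels binary training labels.
#' @param k_max maximum number of selected features (default 7).
#' @param exclude_list feature names that must not be selected.
#' @param cor_prune drop the later entrant of a pair with `|r| > cor_limit`
#'   (default FALSE).
#' @param cor_limit correlation threshold for pruning (default 0.9).
#' @return character vector of 2..k_max names in entry order.
#' @export
lasso_select <- function(measurements, labels, k_max = 7,
                         exclude_list = character(), cor_prune = FALSE,
                         cor_limit = 0.9) {
  X <- as.matrix(measurements)
  keep <- setdiff(colnames(X), exclude_list)
  X <- X[, keep, drop = FALSE]
  s <- apply(X, 2, stats::sd)
  X <- X[, s > 1e-12, drop = FALSE]
  if (ncol(X) < 2) stop("selection error: fewer than 2 selectable features")
  Xz <- scale(X)
  fit <- glmnet::glmnet(Xz, labels, family = "binomial", alpha = 1,
                        nlambda = 100, standardize = FALSE)
  beta <- as.matrix(fit$beta)
  entry <- apply(beta != 0, 1, function(v) if (any(v)) which(v)[1] else Inf)
  ord <- names(sort(entry[is.finite(entry)]))
  if (cor_prune && length(ord) > 1) {
    R <- stats::cor(Xz[, ord, drop = FALSE])
    drop_set <- character()
    for (a in seq_along(ord)) for (b in seq_len(a - 1)) {
      if (abs(R[a, b]) > cor_limit && !(ord[b] %in% drop_set))
        drop_set <- c(drop_set, ord[a])
    }
    ord <- setdiff(ord, drop_set)
  }
  if (length(ord) < 2) stop("selection error: fewer than 2 features entered")
  utils::head(ord, k_max)
}

#' Refit an unregularized sparse model on selected measurements
#'
#' Plain logistic regression on the selected, z-scored (training statistics)
#' measurements. On perfect separation the fit falls back to a minimal
#' ridge penalty with a warning.
#'
#' @param selected ordered selected measurement names.
#' @param measurements measurement matrix (ECG x measurement).
#' @param labels binary vector.
#' @param split factor `train`/`tune`/`test`; the fit uses the training
#'   split and the reported AUROC the test split.
#' @param phenotype optional phenotype id stored on the model.
#' @return object of class `sparse_linear_model`: `phenotype`, `selected`,
#'   `weights` (standardized scale), `intercept`, `center`, `scale`,
#'   `auroc_train`, `auroc_test`.
#' @export
refit_sparse <- function(selected, measurements, labels, split = NULL,
                         phenotype = NA_character_) {
  if (is.null(split)) split <- rep("train", length(labels))
  tr <- split == "train"
  X <- as.matrix(measurements[, selected, drop = FALSE])
  mu <- colMeans(X[tr, , drop = FALSE])
  s <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  s[s < 1e-12] <- 1
  Xz <- sweep(sweep(X, 2, mu), 2, s, "/")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, Xz[tr, , drop = FALSE]), labels[tr],
                   family = stats::binomial()))
  co <- fit$coefficients
  if (any(!is.finite(co)) || any(abs(co) > 50)) {
    warning("perfect separation: falling back to a minimal ridge penalty")
    rf <- glmnet::glmnet(Xz[tr, , drop = FALSE], labels[tr],
                         family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
    co <- c(rf$a0, as.numeric(rf$beta))
  }
  m <- list(phenotype = phenotype, selected = selected,
            weights = stats::setNames(co[-1], selected), intercept = co[1],
            center = mu, scale = s)
  class(m) <- "sparse_linear_model"
  zs <- drop(Xz %*% m$weights) + m$intercept
  m$auroc_train <- auroc(zs[tr], labels[tr])
  te <- split == "test"
  m$auroc_test <- if (any(te)) auroc(zs[te], labels[te]) else NA_real_
  m
}

#' Score a sparse linear model
#'
#' `logit = intercept + sum(weights * x)` on the standardized measurement
#' scale; the probability is the logistic transform. Raw-scale inputs are
#' standardized with the model's stored training center/scale when
#' available.
#'
#' @param model a `sparse_linear_model` (or a fixture model with `weights`
#'   and `intercept`).
#' @param x named vector or matrix of measurements; must supply every
#'   selected name.
#' @param standardized is `x` already on the standardized scale?
#' @return list: `logit`, `probability` (vectors for matrix input).
#' @export
score_sparse <- function(model, x, standardized = TRUE) {
  sel <- names(model$weights)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  missing <- setdiff(sel, colnames(x))
  if (length(missing)) stop("input error: missing measurement(s): ",
                            paste(missing, collapse = ", "))
  xs <- x[, sel, drop = FALSE]
  if (!standardized) {
    if (is.null(model$center)) stop("model carries no standardization scale")
    xs <- sweep(sweep(xs, 2, model$center), 2, model$scale, "/")
  }
  logit <- drop(xs %*% model$weights) + model$intercept
  list(logit = logit, probability = stats::plogis(logit))
}

#' Transfer AUC of a frozen sparse model onto other labels
#'
#' @param model a `sparse_linear_model`.
#' @param measurements measurement matrix for the evaluation cohort.
#' @param labels_other binary labels of the target phenotype.
#' @param standardized is the measurement matrix already standardized?
#' @return AUROC of the frozen model's scores against the target labels.
#' @export
transfer_auc <- function(model, measurements, labels_other,
                         standardized = FALSE) {
  sc <- score_sparse(model, measurements, standardized = standardized)
  auroc(sc$logit, labels_other)
}

#' Bundled sparse-model fixtures
#'
#' Loads the package's published-model fixture file: named measurement
#' weights (standardized scale) and intercepts for five conditions
#' (neutropenia, respiratory failure, lung transplant, disorders of
#' menstruation, ascites). These reference models are scorable via
#' [score_sparse()]; they carry no standardization constants, so inputs
#' must already be standardized.
#'
#' @return named list of `sparse_linear_model`-shaped objects.
#' @export
load_sparse_fixtures <- function() {
  path <- system.file("extdata", "sparse_model_fixtures.json",
                      package = "ecgphewas")
  if (path == "") path <- file.path("inst", "extdata",
                                    "sparse_model_fixtures.json")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) {
    out <- list(phenotype = m$phenotype,
                selected = names(m$weights),
                weights = unlist(m$weights), intercept = m$intercept,
                center = NULL, scale = NULL,
                auroc_train = NA_real_, auroc_test = m$auc)
    class(out) <- "sparse_linear_model"
    out
  })
}

#' Odds ratios of conditions and of top-risk given interpretation statements
#'
#' For each statement and phenotype, builds the 2x2 table of statement
#' presence against (a) the condition label and (b) membership in the top
#' `top_frac` of that phenotype's risk scores, and reports both odds ratios.
#' A 0.5 Haldane-Anscombe correction is applied to every cell whenever any
#' cell is zero.
#'
#' @param statements long data frame `ecg_id`, `statement`.
#' @param labels binary matrix (ECG x phenotype) with ECG ids as rownames.
#' @param scores score matrix aligned to `labels`.
#' @param phenotypes phenotypes to evaluate (default: all columns).
#' @param top_frac top-risk fraction (default 0.05: score at or above the
#'   95th percentile).
#' @param highlight_threshold flag rows with either OR at or above this
#'   value (default 5).
#' @return data frame: `statement`, `phenotype`, `or_condition`, `or_top`,
#'   cell counts, `highlight`.
#' @export
statement_odds_ratios <- function(statements, labels, scores,
                                  phenotypes = colnames(labels),
                                  top_frac = 0.05,
                                  highlight_threshold = 5) {
  ecg_ids <- rownames(labels)
  all_st <- sort(unique(statements$statement))
  rows <- list()
  for (st in all_st) {
    has <- ecg_ids %in% statements$ecg_id[statements$statement == st]
    if (!any(has)) { warning("statement never occurs: ", st); next }
    for (p in phenotypes) {
      y <- as.numeric(labels[, p]) == 1
      thr <- stats::quantile(scores[, p], 1 - top_frac, type = 7)
      top <- scores[, p] >= thr
      rows[[length(rows) + 1]] <- data.frame(
        statement = st, phenotype = p,
        or_condition = odds_ratio_2x2(has, y),
        or_top = odds_ratio_2x2(has, top),
        n_statement = sum(has), n_condition = sum(y),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$highlight <- pmax(out$or_condition, out$or_top) >= highlight_threshold
  out
}

#' 2x2 odds ratio with Haldane-Anscombe correction
#'
#' `OR = (a*d)/(b*c)` for the table of `x` (exposure) by `y` (outcome);
#' 0.5 is added to every cell when any cell is zero.
#'
#' @param x,y logical vectors, or `a,b,c,d` counts via `counts`.
#' @param counts optional numeric vector `c(a, b, c, d)` = (x&y, x&!y,
#'   !x&y, !x&!y).
#' @return odds ratio (finite and positive after correction).
#' @export
odds_ratio_2x2 <- function(x = NULL, y = NULL, counts = NULL) {
  if (is.null(counts)) {
    counts <- c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  }
  if (any(counts == 0)) counts <- counts + 0.5
  (counts[1] * counts[4]) / (counts[2] * counts[3])
}
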