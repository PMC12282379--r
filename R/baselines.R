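# The baseline battery: univariate predictors, the demographic linear model,
# measurement-based ridge/tree models, and gap summaries against a reference
# detector.

#' Direction-agnostic univariate AUROC
#'
#' Evaluates a single feature as a detector, allowing either direction to
#' correlate with disease: reports `max(A, 1 - A)` for raw AUROC `A` and the
#' winning direction. A constant feature is degenerate and scores 0.5.
#'
#' @param feature numeric vector.
#' @param labels binary vector.
#' @return list: `auroc`, `direction` (`"high"`/`"low"`/`"degenerate"`),
#'   `raw_auroc`.
#' @export
univariate_auc <- function(feature, labels) {
  if (stats::sd(feature) == 0)
    return(list(auroc = 0.5, direction = "degenerate", raw_auroc = 0.5))
  a <- auroc(feature, labels)
  list(auroc = max(a, 1 - a),
       direction = if (a >= 0.5) "high" else "low",
       raw_auroc = a)
}

# expand demographics into the model matrix used by the demographic baseline
demographic_design <- function(demographics, levels_race = NULL) {
  stopifnot(all(c("age", "sex", "bmi") %in% names(demographics)))
  race <- as.character(demographics$race_ethnicity)
  if (is.null(levels_race)) levels_race <- sort(unique(race))
  unseen <- !(race %in% levels_race)
  if (any(unseen)) {
    warning(sum(unseen), " observation(s) with unseen race/ethnicity ",
            "mapped to the reference level")
    race[unseen] <- levels_race[1]
  }
  race <- factor(race, levels = levels_race)
  X <- cbind(age = demographics$age,
             female = as.numeric(demographics$sex == "F"),
             bmi = demographics$bmi,
             stats::model.matrix(~ race)[, -1, drop = FALSE])
  list(X = X, levels_race = levels_race)
}

#' Demographic baseline model
#'
#' Ridge-regularized logistic model on age, sex, one-hot race/ethnicity and
#' BMI; the penalty is selected on the tune split by binomial deviance.
#'
#' @param demographics data frame with `age`, `sex`, `race_ethnicity`,
#'   `bmi`, one row per ECG.
#' @param labels binary vector per ECG.
#' @param split factor `train`/`tune`/`test` per ECG.
#' @return list: `auroc` (test), `scores` (all rows), `fit`, `name`.
#' @export
fit_demographic_model <- function(demographics, labels, split) {
  tr <- split == "train"; tu <- split == "tune"
  dd <- demographic_design(demographics[tr, , drop = FALSE])
  Xtr <- dd$X
  Xall <- demographic_design(demographics, dd$levels_race)$X
  fit <- glmnet::glmnet(Xtr, labels[tr], family = "binomial", alpha = 0,
                        nlambda = 30)
  ptu <- stats::predict(fit, Xall[tu, , drop = FALSE])
  dev <- apply(ptu, 2, function(z) mean(bce_with_logits(z, labels[tu])))
  lam <- fit$lambda[which.min(dev)]
  scores <- drop(stats::predict(fit, Xall, s = lam))
  te <- split == "test"
  list(auroc = auroc(scores[te], labels[te]), scores = scores, fit = fit,
       lambda = lam, name = "demographic")
}

#' Measurement-based baseline models
#'
#' Ridge-logistic (penalty tuned on the tune split) or gradient-boosted
#' trees (depth and rounds tuned on the tune split by binary logistic
#' loss); `random_forest` is available behind the same interface.
#' Measurements are imputed by the training-split median and z-scored on
#' training statistics before linear fits.
#'
#' @param measurements numeric matrix (ECG x measurement).
#' @param labels binary vector per ECG.
#' @param split factor `train`/`tune`/`test`.
#' @param model `"ridge_logistic"`, `"boosted_trees"` or `"random_forest"`.
#' @return list: `auroc` (test), `scores`, `name`, `tuning`.
#' @export
fit_measurement_model <- function(measurements, labels, split,
                                  model = c("ridge_logistic", "boosted_trees",
                                            "random_forest")) {
  model <- match.arg(model)
  tr <- split == "train"; tu <- split == "tune"; te <- split == "test"
  X <- as.matrix(measurements)
  # drop all-missing columns, impute by training-split median
  all_na <- apply(X[tr, , drop = FALSE], 2, function(v) all(is.na(v)))
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " all-missing measurement column(s)")
    X <- X[, !all_na, drop = FALSE]
  }
  med <- apply(X[tr, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]

  if (model == "ridge_logistic") {
    mu <- colMeans(X[tr, , drop = FALSE])
    s <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    s[s < 1e-12] <- 1
    Xz <- sweep(sweep(X, 2, mu), 2, s, "/")
    fit <- glmnet::glmnet(Xz[tr, , drop = FALSE], labels[tr],
                          family = "binomial", alpha = 0, nlambda = 30,
                          standardize = FALSE)
    ptu <- stats::predict(fit, Xz[tu, , drop = FALSE])
    dev <- apply(ptu, 2, function(z) mean(bce_with_logits(z, labels[tu])))
    lam <- fit$lambda[which.min(dev)]
    scores <- drop(stats::predict(fit, Xz, s = lam))
    tuning <- list(lambda = lam)
  } else if (model == "boosted_trees") {
    grid <- expand.grid(depth = c(2, 4), nrounds = c(50, 150))
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = labels[tr])
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = grid$depth[g], eta = 0.1, nthread = 1),
        data = dtr, nrounds = grid$nrounds[g], verbose = 0)
      ztu <- stats::predict(fit, X[tu, , drop = FALSE], outputmargin = TRUE)
      loss <- mean(bce_with_logits(ztu, labels[tu]))
      if (is.null(best) || loss < best$loss)
        best <- list(fit = fit, loss = loss, g = g)
    }
    scores <- stats::predict(best$fit, X, outputmargin = TRUE)
    tuning <- as.list(grid[best$g, ])
  } else {
    if (!requireNamespace("ranger", quietly = TRUE))
      stop("the random_forest baseline needs the 'ranger' package")
    df <- data.frame(y = factor(labels[tr]), X[tr, , drop = FALSE],
                     check.names = TRUE)
    fit <- ranger::ranger(y ~ ., data = df, probability = TRUE,
                          num.trees = 300, num.threads = 1, seed = 1)
    newd <- data.frame(X, check.names = TRUE)
    scores <- ranger::predictions(stats::predict(fit, newd,
                                                 num.threads = 1))[, "1"]
    tuning <- list(num.trees = 300)
  }
  list(auroc = auroc(scores[te], labels[te]), scores = scores,
       name = model, tuning = tuning)
}

#' Run the baseline battery for a set of phenotypes
#'
#' Computes, per phenotype: direction-agnostic univariate AUROCs for age and
#' the configured measurements, the demographic model AUROC, and the
#' measurement-model AUROCs.
#'
#' @param measurements matrix (ECG x measurement).
#' @param demographics data frame per ECG.
#' @param labels binary matrix (ECG x phenotype).
#' @param split factor `train`/`tune`/`test`.
#' @param phenotypes columns of `labels` to evaluate (default all with both
#'   classes in the test split).
#' @param univariate_measurements measurement names used as univariate
#'   predictors (defaults to the heart rate, corrected QT and aVR T-wave
#'   area trio).
#' @param models measurement model types to fit.
#' @return data frame: `phenotype`, `baseline`, `auroc`, `direction`.
#' @export
baseline_battery <- function(measurements, demographics, labels, split,
                             phenotypes = NULL,
                             univariate_measurements =
                               c("Heart Rate", "Mean QTc", "T-wave area in aVR"),
                             models = c("ridge_logistic", "boosted_trees")) {
  te <- split == "test"
  if (is.null(phenotypes)) {
    ok <- vapply(colnames(labels), function(p) {
      y <- labels[te, p]; sum(y) > 0 && sum(y) < length(y)
    }, logical(1))
    phenotypes <- colnames(labels)[ok]
  }
  rows <- list()
  for (p in phenotypes) {
    y <- as.numeric(labels[, p])
    ua <- univariate_auc(demographics$age[te], y[te])
    rows[[length(rows) + 1]] <- data.frame(
      phenotype = p, baseline = "age", auroc = ua$auroc,
      direction = ua$direction, stringsAsFactors = FALSE)
    for (m in univariate_measurements) {
      um <- univariate_auc(measurements[te, m], y[te])
      rows[[length(rows) + 1]] <- data.frame(
        phenotype = p, baseline = paste0("univariate: ", m),
        auroc = um$auroc, direction = um$direction, stringsAsFactors = FALSE)
    }
    dm <- fit_demographic_model(demographics, y, split)
    rows[[length(rows) + 1]] <- data.frame(
      phenotype = p, baseline = "demographic", auroc = dm$auroc,
      direction = NA_character_, stringsAsFactors = FALSE)
    for (mod in models) {
      mm <- fit_measurement_model(measurements, y, split, mod)
      rows[[length(rows) + 1]] <- data.frame(
        phenotype = p, baseline = mod, auroc = mm$auroc,
        direction = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Gap summary between a reference detector and a baseline
#'
#' @param aucs_ref,aucs_base named AUC vectors over a common phenotype set.
#' @param gaps gap thresholds summarized (default 0.05 and 0.10).
#' @return list: `n`, `mean_gap` (ref minus base), per-threshold fractions
#'   where the reference wins by more than the gap (`frac_ref_better_05`,
#'   `_10`) and where the baseline does (`frac_base_better_*`), and
#'   `baseline_wins` (phenotypes where the baseline wins by > the first gap).
#' @export
compare_models <- function(aucs_ref, aucs_base, gaps = c(0.05, 0.10)) {
  common <- intersect(names(aucs_ref), names(aucs_base))
  if (length(common) == 0) stop("no common phenotypes")
  d <- aucs_ref[common] - aucs_base[common]
  out <- list(n = length(common), mean_gap = mean(d))
  for (g in gaps) {
    tag <- gsub("\\.", "", sprintf("%02d", round(100 * g)))
    out[[paste0("frac_ref_better_", tag)]] <- mean(d > g)
    out[[paste0("frac_base_better_", tag)]] <- mean(d < -g)
  }
  out$baseline_wins <- common[d < -gaps[1]]
  out
}
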