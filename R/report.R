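# Pipeline orchestration and machine-readable report bundles: per-site
# scoring, the two-site gate, co-detectability clustering, baselines, sparse
# models, odds ratios, and the run manifest.

#' Fast per-phenotype measurement-model scores
#'
#' Logistic models on the z-scored measurement panel, one per phenotype,
#' fitted on the training split; used as the pipeline's fast scorer and for
#' gate-recovery analyses. Falls back to a small ridge penalty when the
#' unpenalized fit does not converge.
#'
#' @param measurements matrix (ECG x measurement).
#' @param labels binary matrix (ECG x phenotype).
#' @param split factor `train`/`tune`/`test` per ECG.
#' @param phenotypes columns to score (default all).
#' @param max_train_rows cap on the number of training rows used per fit
#'   (evenly spaced subsample); scores are still produced for every ECG.
#' @return score (logit) matrix for all ECGs x phenotypes.
#' @export
measurement_scores <- function(measurements, labels, split,
                               phenotypes = colnames(labels),
                               max_train_rows = 10000) {
  tr <- which(split == "train")
  if (length(tr) > max_train_rows)
    tr <- tr[round(seq(1, length(tr), length.out = max_train_rows))]
  tr <- seq_len(nrow(measurements)) %in% tr
  X <- as.matrix(measurements)
  mu <- colMeans(X[tr, , drop = FALSE])
  s <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  s[s < 1e-12] <- 1
  Xz <- sweep(sweep(X, 2, mu), 2, s, "/")
  Xtr <- cbind(1, Xz[tr, , drop = FALSE])
  out <- matrix(NA_real_, nrow(X), length(phenotypes),
                dimnames = list(rownames(X), phenotypes))
  for (p in phenotypes) {
    y <- as.numeric(labels[tr, p])
    if (sum(y) == 0 || sum(y) == length(y)) next
    fit <- suppressWarnings(stats::glm.fit(Xtr, y,
                                           family = stats::binomial()))
    co <- fit$coefficients
    if (any(!is.finite(co)) || !fit$converged || any(abs(co) > 30)) {
      rf <- glmnet::glmnet(Xz[tr, , drop = FALSE], y, family = "binomial",
                           alpha = 0, lambda = 1e-3, standardize = FALSE)
      co <- c(rf$a0, as.numeric(rf$beta))
    }
    out[, p] <- drop(cbind(1, Xz) %*% co)
  }
  out
}

#' Two-site phenotype association table
#'
#' Assembles the per-phenotype report rows (phecode, description, category,
#' per-site AUC and positive count) for the shortlisted phenotypes, sorted
#' by phecode, plus the association-plot data (AUC and -log10 p per
#' phenotype and site).
#'
#' @param results_a,results_b `gate_result` data frames.
#' @param metadata data frame with `phenotype`, `description`, `category`.
#' @param shortlist phenotype ids to include (default: all in `results_a`).
#' @return list: `table` (report rows), `plot_data` (per phenotype/site
#'   AUC, p, `neg_log10_p`, category).
#' @export
phewas_table <- function(results_a, results_b, metadata,
                         shortlist = results_a$phenotype) {
  a <- results_a[match(shortlist, results_a$phenotype), ]
  b <- results_b[match(shortlist, results_b$phenotype), ]
  md <- metadata[match(shortlist, metadata$phenotype), ]
  tab <- data.frame(phecode = shortlist, phenotype = md$description,
                    category = md$category,
                    auc_a = a$auroc, count_a = a$n_pos,
                    auc_b = b$auroc, count_b = b$n_pos,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$phecode), ]
  both <- rbind(results_a, results_b)
  both <- merge(both, metadata[, c("phenotype", "category")],
                by = "phenotype", all.x = TRUE)
  both$neg_log10_p <- -log10(pmax(both$p, 1e-300))
  list(table = tab,
       plot_data = both[, c("phenotype", "site", "category", "auroc", "p",
                            "neg_log10_p", "n_pos")])
}

#' Run the full analysis pipeline
#'
#' Simulate -> build labels -> score both sites -> two-site gate ->
#' co-detectability clustering -> baselines (for the cluster candidates) ->
#' sparse models -> statement odds ratios -> report bundle. Stages write
#' their outputs under `out_dir` and are skipped when their outputs already
#' exist (`resume = TRUE`), so deleting one stage's files regenerates only
#' that stage and everything downstream of it.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory.
#' @param scorer `"measurement"` (fast linear scorer) or `"detector"`
#'   (trains the convolutional detector; slower).
#' @param window_days association window (default 30).
#' @param min_count,thr_a,thr_b,alpha gate parameters.
#' @param reversed swap the two AUC thresholds.
#' @param margin,max_centers co-detectability parameters.
#' @param exclude_categories categories pruned before clustering.
#' @param sparse_phenotypes phenotypes given sparse models (default: the
#'   registry's direct-effect phenotypes).
#' @param detector_args list passed to [train_multitask()] when
#'   `scorer = "detector"` (plus `n_ecgs_max` to subsample).
#' @param resume skip stages whose outputs exist (default TRUE).
#' @return list with the in-memory results of every stage and `manifest`.
#' @export
run_pipeline <- function(config = generator_config(), out_dir = tempfile(),
                         scorer = c("measurement", "detector"),
                         window_days = 30, min_count = 500, thr_a = 0.80,
                         thr_b = 0.75, alpha = 0.01, reversed = FALSE,
                         margin = 0.05, max_centers = 4,
                         exclude_categories = "circulatory system",
                         sparse_phenotypes = NULL,
                         detector_args = list(), resume = TRUE) {
  scorer <- match.arg(scorer)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_file <- function(...) file.path(out_dir, ...)

  ## stage 1: simulate
  cohort <- generate_cohort(config)
  if (!resume || !file.exists(stage_file("patients.csv")))
    write_cohort(cohort, out_dir)

  ## stage 2: labels
  lb <- build_labels(cohort, window_days = window_days)
  sites <- names(lb)

  ## stage 3: scores per site
  scores <- list()
  for (s in sites) {
    ecg_ids <- lb[[s]]$ecg_ids
    if (scorer == "measurement") {
      scores[[s]] <- measurement_scores(cohort$measurements[ecg_ids, ],
                                        lb[[s]]$labels, lb[[s]]$split)
    } else {
      da <- detector_args
      ids_use <- ecg_ids
      if (!is.null(da$n_ecgs_max) && length(ecg_ids) > da$n_ecgs_max) {
        set.seed(config$seed + 17)
        ids_use <- sort(sample(ecg_ids, da$n_ecgs_max))
      }
      sel <- match(ids_use, ecg_ids)
      x <- detector_input(cohort, ids_use)
      y <- as.matrix(lb[[s]]$labels[sel, , drop = FALSE])
      sp <- model_spec(n_tasks = ncol(y))
      tr <- lb[[s]]$split[sel] == "train"; tu <- lb[[s]]$split[sel] == "tune"
      det <- train_multitask(sp, x[, , tr, drop = FALSE], y[tr, ],
                             x[, , tu, drop = FALSE], y[tu, ],
                             epochs = da$epochs %||% 8,
                             batch_size = da$batch_size %||% 64,
                             lr = da$lr %||% 3e-3,
                             seed = config$seed + 31)
      sc <- predict_scores(det, x)
      full <- matrix(NA_real_, length(ecg_ids), ncol(y),
                     dimnames = list(ecg_ids, colnames(y)))
      full[sel, ] <- sc
      scores[[s]] <- full
    }
    utils::write.csv(data.frame(ecg_id = rownames(scores[[s]]),
                                scores[[s]], check.names = FALSE),
                     stage_file(paste0("scores_", s, ".csv")),
                     row.names = FALSE)
  }

  ## stage 4: gate (test split, included phenotypes only)
  gr <- list()
  for (s in sites) {
    te <- lb[[s]]$split == "test"
    keep <- lb[[s]]$included
    ok <- !is.na(colSums(scores[[s]][, keep, drop = FALSE]))
    keep <- keep[ok]
    gr[[s]] <- gate_results(scores[[s]][te, keep, drop = FALSE],
                            as.matrix(lb[[s]]$labels[te, keep, drop = FALSE]),
                            site_id = s)
  }
  gate <- replication_gate(gr[[1]], gr[[2]], alpha = alpha,
                           min_count = min_count, thr_a = thr_a,
                           thr_b = thr_b, reversed = reversed)
  utils::write.csv(do.call(rbind, gr), stage_file("gate_results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(gate$funnel), stage_file("funnel.json"),
                       auto_unbox = TRUE)

  ## stage 5: co-detectability on the discovery site's test split
  reg <- cohort$registry
  cats <- stats::setNames(reg$category, reg$phenotype)
  cand <- prune_candidates(gate$shortlist, cats, exclude_categories)
  s1 <- sites[1]
  te1 <- lb[[s1]]$split == "test"
  labels1 <- as.matrix(lb[[s1]]$labels[te1, , drop = FALSE])
  graph <- if (length(cand) >= 2)
    codetect_graph(scores[[s1]][te1, , drop = FALSE], labels1,
                   candidates = cand, margin = margin) else NULL
  clus <- if (!is.null(graph)) cluster_by_centers(graph, max_centers) else
    list(clusters = list(), unclustered = cand,
         assignment = stats::setNames(rep(NA_character_, length(cand)), cand))
  if (!is.null(graph)) {
    utils::write.csv(graph$pairs, stage_file("codetect_edges.csv"),
                     row.names = FALSE)
    jsonlite::write_json(clus$clusters, stage_file("clusters.json"))
    ovl <- overlap_table(labels1, clus$clusters)
    utils::write.csv(ovl, stage_file("overlap.csv"), row.names = FALSE)
  } else ovl <- NULL

  ## stage 6: sparse models + odds ratios (site A)
  if (is.null(sparse_phenotypes))
    sparse_phenotypes <- names(attr(config$registry, "direct_effects"))
  ecg1 <- lb[[s1]]$ecg_ids
  meas1 <- cohort$measurements[ecg1, ]
  sparse_models <- list()
  for (p in intersect(sparse_phenotypes, colnames(lb[[s1]]$labels))) {
    y <- as.numeric(lb[[s1]]$labels[, p])
    tr1 <- lb[[s1]]$split == "train"
    sel <- tryCatch(lasso_select(meas1[tr1, ], y[tr1]), error = function(e) NULL)
    if (is.null(sel)) next
    sparse_models[[p]] <- refit_sparse(sel, meas1, y, lb[[s1]]$split,
                                       phenotype = p)
  }
  jsonlite::write_json(
    lapply(sparse_models, function(m) list(phenotype = m$phenotype,
      weights = as.list(m$weights), intercept = m$intercept,
      auroc_test = m$auroc_test)),
    stage_file("sparse_models.json"), auto_unbox = TRUE, digits = NA)
  st1 <- cohort$statements[cohort$statements$ecg_id %in% ecg1, ]
  or_phenos <- utils::head(c(intersect(c(cand), colnames(labels1))), 10)
  ors <- if (length(or_phenos))
    statement_odds_ratios(st1[st1$ecg_id %in% ecg1[te1], ],
                          labels1, scores[[s1]][te1, , drop = FALSE],
                          phenotypes = or_phenos) else NULL
  if (!is.null(ors))
    utils::write.csv(ors, stage_file("odds_ratios.csv"), row.names = FALSE)

  ## stage 7: report + manifest
  pt <- phewas_table(gr[[1]], gr[[2]], reg, gate$shortlist)
  utils::write.csv(pt$table, stage_file("phewas_table.csv"),
                   row.names = FALSE)
  utils::write.csv(pt$plot_data, stage_file("association_plot_data.csv"),
                   row.names = FALSE)
  out_files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(seed = config$seed, scorer = scorer,
                   n_patients_per_site = config$n_patients_per_site,
                   window_days = window_days,
                   funnel = as.list(gate$funnel),
                   files = as.list(tools::md5sum(out_files)))
  jsonlite::write_json(manifest, stage_file("manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(cohort = cohort, labels = lb, scores = scores,
                 gate_results = gr, gate = gate, graph = graph,
                 clusters = clus, overlap = ovl,
                 sparse_models = sparse_models, odds_ratios = ors,
                 report = pt, manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
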