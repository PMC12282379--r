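# Shared desk-scale recovery replicates: each replicate generates a fresh
# two-site cohort at the default scale, scores it with the measurement-panel
# detector, runs the two-site gate, the co-detectability clustering, and the
# sparse-model recovery. The gate, cluster and sparse acceptance checks all
# read from the same replicates.

recovery_replicates <- function(n_reps = 10, base_seed = 9000) {
  if (!is.null(.cohort_cache$recovery)) return(.cohort_cache$recovery)
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- generator_config(seed = base_seed + r)
    co <- generate_cohort(cfg)
    lb <- build_labels(co)
    gr <- list()
    scA <- NULL
    for (s in c("A", "B")) {
      sc <- measurement_scores(co$measurements[lb[[s]]$ecg_ids, ],
                               lb[[s]]$labels, lb[[s]]$split,
                               max_train_rows = 8000)
      if (s == "A") scA <- sc
      te <- lb[[s]]$split == "test"
      keep <- lb[[s]]$included
      gr[[s]] <- gate_results(sc[te, keep, drop = FALSE],
                              as.matrix(lb[[s]]$labels[te, keep,
                                                       drop = FALSE]),
                              site_id = s)
    }
    gate <- replication_gate(gr$A, gr$B)
    reg <- co$registry
    strong <- reg$phenotype[!is.na(reg$design_auc_A) &
                              reg$class == "factor" &
                              reg$design_auc_A >= 0.85]
    nulls <- reg$phenotype[reg$class == "null"]

    ## co-detectability clustering on the discovery site's test split
    cats <- stats::setNames(reg$category, reg$phenotype)
    cand <- prune_candidates(gate$shortlist, cats)
    teA <- lb$A$split == "test"
    labsA <- as.matrix(lb$A$labels[teA, , drop = FALSE])
    ari <- NA_real_
    if (length(cand) >= 4) {
      graph <- codetect_graph(scA[teA, , drop = FALSE], labsA,
                              candidates = cand)
      clus <- cluster_by_centers(graph, max_centers = 4)
      fac_nodes <- intersect(cand, reg$phenotype[reg$class == "factor" &
                                                   !is.na(reg$factor)])
      truth <- reg$factor[match(fac_nodes, reg$phenotype)]
      got <- clus$assignment[fac_nodes]
      got[is.na(got)] <- paste0("singleton", seq_len(sum(is.na(got))))
      ari <- adjusted_rand(truth, got)
    }

    ## sparse recovery for the three-measurement phenotype
    planted <- attr(cfg$registry, "direct_effects")[["577.2"]]
    trA <- lb$A$split == "train"
    y577 <- as.numeric(lb$A$labels[, "577.2"])
    meas_A <- co$measurements[lb$A$ecg_ids, ]
    sel <- lasso_select(meas_A[trA, ], y577[trA], k_max = 7)
    refit <- refit_sparse(intersect(sel, names(planted)), meas_A, y577,
                          lb$A$split, phenotype = "577.2")
    sign_ok <- all(sign(refit$weights) ==
                     sign(planted[names(refit$weights)]))

    list(strong = strong, nulls = nulls, shortlist = gate$shortlist,
         funnel = gate$funnel, gr = gr, ari = ari,
         sparse_selected = sel, sparse_all3 = all(names(planted) %in% sel),
         sparse_sign_ok = sign_ok)
  })
  .cohort_cache$recovery <- out
  out
}
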