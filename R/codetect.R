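# Co-detectability analysis: cross-AUC relation between phenotype detectors,
# category/hierarchy pruning, greedy central-phenotype clustering, and the
# overlap table.

#' Prune shortlisted phenotypes by category and hierarchy
#'
#' Drops phenotypes in the excluded categories (e.g. the cardiovascular
#' system), then drops any phenotype whose phecode ancestor (by
#' decimal-string truncation) is still present in the remaining set, so only
#' the highest surviving member of each hierarchy chain is kept.
#'
#' @param shortlist character vector of phenotype ids.
#' @param categories named character vector mapping phenotype id to category.
#' @param exclude_categories categories to remove (default
#'   `"circulatory system"`).
#' @return character vector of candidate phenotype ids.
#' @export
prune_candidates <- function(shortlist, categories,
                             exclude_categories = "circulatory system") {
  unknown <- setdiff(shortlist, names(categories))
  if (length(unknown)) stop("integrity error: unknown phenotype id(s): ",
                            paste(unknown, collapse = ", "))
  keep <- shortlist[!(categories[shortlist] %in% exclude_categories)]
  anc <- phecode_ancestors(keep)
  is_desc <- vapply(anc, function(a) any(a %in% keep), logical(1))
  keep[!is_desc]
}

#' Co-detectability of a phenotype pair
#'
#' Phenotypes i and j are co-detectable when each one's labels are detected
#' by the *other* phenotype's detector with an AUC no more than `margin`
#' lower than by its own detector. `symmetric = FALSE` requires the relation
#' in one direction only.
#'
#' @param auc_ii,auc_ij AUC of score i / score j against label i.
#' @param auc_jj,auc_ji AUC of score j / score i against label j.
#' @param margin allowed AUC deficit (default 0.05).
#' @param symmetric require both directions (default TRUE).
#' @return logical.
#' @export
co_detectable <- function(auc_ii, auc_ij, auc_jj, auc_ji, margin = 0.05,
                          symmetric = TRUE) {
  fwd <- auc_ij >= auc_ii - margin
  bwd <- auc_ji >= auc_jj - margin
  if (symmetric) fwd & bwd else fwd | bwd
}

#' Build the co-detectability graph
#'
#' Computes, for every pair of candidate phenotypes, the cross-AUC quadruple
#' (each phenotype's labels scored by its own and by the other phenotype's
#' detector) on one site's score matrix, and the resulting co-detectability
#' edges.
#'
#' @param scores score matrix (ECG x phenotype), columns named.
#' @param labels binary label matrix of the same shape.
#' @param candidates phenotype ids to relate (default: all columns).
#' @param margin AUC deficit margin (default 0.05).
#' @param symmetric both-direction requirement (default TRUE).
#' @return object of class `codetect_graph`: list with `nodes`, `own_auc`,
#'   `pairs` (data frame with the quadruple and `co_detectable` flag), and
#'   `edges` (the co-detectable pairs).
#' @export
codetect_graph <- function(scores, labels, candidates = colnames(labels),
                           margin = 0.05, symmetric = TRUE) {
  stopifnot(all(candidates %in% colnames(scores)),
            all(candidates %in% colnames(labels)))
  n <- length(candidates)
  own <- vapply(candidates, function(p) {
    y <- as.numeric(labels[, p])
    if (sum(y) == 0 || sum(y) == length(y)) return(NA_real_)
    auroc(scores[, p], y)
  }, numeric(1))
  pairs <- NULL
  if (n >= 2) {
    cmb <- utils::combn(candidates, 2)
    rows <- lapply(seq_len(ncol(cmb)), function(q) {
      i <- cmb[1, q]; j <- cmb[2, q]
      yi <- as.numeric(labels[, i]); yj <- as.numeric(labels[, j])
      auc_ij <- auroc(scores[, j], yi)
      auc_ji <- auroc(scores[, i], yj)
      data.frame(i = i, j = j, auc_ii = own[i], auc_ij = auc_ij,
                 auc_jj = own[j], auc_ji = auc_ji,
                 co_detectable = co_detectable(own[i], auc_ij, own[j],
                                               auc_ji, margin, symmetric),
                 stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, rows)
  }
  out <- list(nodes = candidates, own_auc = own, pairs = pairs,
              edges = if (is.null(pairs)) NULL else
                pairs[pairs$co_detectable, c("i", "j")],
              margin = margin, symmetric = symmetric)
  class(out) <- "codetect_graph"
  out
}

#' Greedy central-phenotype clustering
#'
#' Iteratively selects the node participating in the most co-detectable
#' pairs as a cluster centre (ties broken by higher own AUC, then
#' lexicographic id), assigns its co-detectable neighbours to it, removes
#' the assigned nodes, and repeats up to `max_centers` times. Remaining
#' nodes are reported unclustered.
#'
#' @param graph a `codetect_graph`.
#' @param max_centers maximum number of clusters (default 4).
#' @return list: `clusters` (named list centre -> member ids, centre
#'   included), `unclustered`, `assignment` (named vector phenotype ->
#'   centre id or `NA`).
#' @export
cluster_by_centers <- function(graph, max_centers = 4) {
  nodes <- graph$nodes
  edges <- graph$edges
  clusters <- list()
  if (length(nodes) == 0)
    return(list(clusters = clusters, unclustered = character(),
                assignment = stats::setNames(character(), character())))
  active <- nodes
  for (ct in seq_len(max_centers)) {
    e <- edges[edges$i %in% active & edges$j %in% active, , drop = FALSE]
    if (is.null(e) || nrow(e) == 0) break
    deg <- table(factor(c(e$i, e$j), levels = active))
    if (max(deg) == 0) break
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      own <- graph$own_auc[cand]
      cand <- cand[order(-own, cand)]
    }
    center <- cand[1]
    nbrs <- unique(c(e$j[e$i == center], e$i[e$j == center]))
    clusters[[center]] <- c(center, sort(nbrs))
    active <- setdiff(active, c(center, nbrs))
  }
  assignment <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (c0 in names(clusters)) assignment[clusters[[c0]]] <- c0
  list(clusters = clusters, unclustered = active, assignment = assignment)
}

#' Cluster overlap proportions
#'
#' For each cluster member m with centre c, the proportion of ECGs positive
#' for m that are also positive for c. A member with zero positives is
#' reported as `NA`.
#'
#' @param labels binary label matrix (ECG x phenotype).
#' @param clusters named list centre -> member ids (as from
#'   [cluster_by_centers()]).
#' @return data frame: `center`, `phenotype`, `overlap`.
#' @export
overlap_table <- function(labels, clusters) {
  rows <- lapply(names(clusters), function(c0) {
    yc <- as.numeric(labels[, c0])
    do.call(rbind, lapply(clusters[[c0]], function(m) {
      ym <- as.numeric(labels[, m])
      ov <- if (sum(ym) == 0) NA_real_ else sum(ym * yc) / sum(ym)
      data.frame(center = c0, phenotype = m, overlap = ov,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b equal-length vectors of cluster labels (`NA` allowed; treated
#'   as a shared "unassigned" label only if present in both).
#' @return adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.character(a); b <- as.character(b)
  a[is.na(a)] <- ".na"; b[is.na(b)] <- ".na"
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
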