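# Co-detectability relation, pruning, greedy clustering, overlaps.

test_that("candidate pruning removes excluded categories then hierarchy descendants", {
  cats <- c("204" = "neoplasms", "204.1" = "neoplasms",
            "204.11" = "neoplasms", "288.11" = "hematopoietic",
            "428" = "circulatory system")
  out <- prune_candidates(c("204", "204.1", "204.11", "288.11", "428"), cats)
  expect_setequal(out, c("204", "288.11"))
  # no hierarchy relations: unchanged
  cats2 <- c(a = "x", b = "x")
  expect_setequal(prune_candidates(c("a", "b"), cats2,
                                   exclude_categories = "none"), c("a", "b"))
  # an all-cardiovascular shortlist prunes to nothing
  cats3 <- c(p1 = "circulatory system", p2 = "circulatory system")
  expect_length(prune_candidates(c("p1", "p2"), cats3), 0)
  expect_error(prune_candidates("zz", cats), "integrity")
})

test_that("the co-detectability margin rule matches its definition", {
  # both cross AUCs within 0.05 of the own AUCs
  expect_true(co_detectable(0.86, 0.84, 0.84, 0.84))
  # a 0.06 deficit on one side fails the symmetric rule
  expect_false(co_detectable(0.86, 0.80, 0.84, 0.84))
  expect_true(co_detectable(0.86, 0.80, 0.84, 0.84, symmetric = FALSE))
  # identical score columns: cross equals own
  expect_true(co_detectable(0.8, 0.8, 0.7, 0.7))
})

test_that("identical score columns are always co-detectable in the graph", {
  set.seed(2)
  sc <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  sc[, 2] <- sc[, 1]
  y <- matrix(rbinom(200, 1, 0.3), 100, 2,
              dimnames = list(NULL, c("a", "b")))
  g <- codetect_graph(sc, y)
  expect_true(g$pairs$co_detectable[1])
})

test_that("increasing the margin never removes edges", {
  set.seed(5)
  sc <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("p", 1:6)))
  y <- (sc + matrix(rnorm(600), 100)) > 0.5
  storage.mode(y) <- "integer"; colnames(y) <- paste0("p", 1:6)
  g1 <- codetect_graph(sc, y, margin = 0.03)
  g2 <- codetect_graph(sc, y, margin = 0.10)
  e1 <- paste(g1$edges$i, g1$edges$j)
  e2 <- paste(g2$edges$i, g2$edges$j)
  expect_true(all(e1 %in% e2))
})

mk_graph <- function(nodes, edges, own = NULL) {
  if (is.null(own)) own <- stats::setNames(rep(0.85, length(nodes)), nodes)
  pairs <- if (length(edges)) data.frame(
    i = vapply(edges, `[`, character(1), 1),
    j = vapply(edges, `[`, character(1), 2),
    co_detectable = TRUE, stringsAsFactors = FALSE) else NULL
  structure(list(nodes = nodes, own_auc = own, pairs = pairs,
                 edges = pairs), class = "codetect_graph")
}

test_that("greedy clustering handles canonical graphs", {
  # star: hub plus 5 leaves, one centre
  star <- mk_graph(c("hub", paste0("l", 1:5)),
                   lapply(paste0("l", 1:5), function(l) c("hub", l)))
  cl <- cluster_by_centers(star, max_centers = 1)
  expect_equal(names(cl$clusters), "hub")
  expect_length(cl$unclustered, 0)
  # two disjoint triangles, two centres, nothing unclustered
  tri <- mk_graph(c("a1", "a2", "a3", "b1", "b2", "b3"),
                  list(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
                       c("b1", "b2"), c("b1", "b3"), c("b2", "b3")))
  cl2 <- cluster_by_centers(tri, max_centers = 2)
  expect_length(cl2$clusters, 2)
  expect_length(cl2$unclustered, 0)
  expect_setequal(unlist(cl2$clusters), tri$nodes)
  # empty graph
  empty <- mk_graph(character(), list())
  expect_length(cluster_by_centers(empty)$clusters, 0)
})

# exhaustive implementation of the same greedy rule, for the oracle check
cluster_oracle <- function(graph, max_centers = 4) {
  active <- graph$nodes
  edges <- graph$edges
  clusters <- list()
  repeat {
    if (length(clusters) >= max_centers) break
    e <- edges[edges$i %in% active & edges$j %in% active, , drop = FALSE]
    if (is.null(e) || nrow(e) == 0) break
    deg <- sapply(active, function(v) sum(e$i == v) + sum(e$j == v))
    if (max(deg) == 0) break
    cand <- active[deg == max(deg)]
    own <- graph$own_auc[cand]
    cand <- cand[order(-own, cand)]
    ctr <- cand[1]
    nb <- unique(c(e$j[e$i == ctr], e$i[e$j == ctr]))
    clusters[[ctr]] <- c(ctr, sort(nb))
    active <- setdiff(active, c(ctr, nb))
  }
  clusters
}

test_that("greedy clustering matches the exhaustive oracle on random graphs", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    nodes <- paste0("n", 1:n)
    all_pairs <- utils::combn(nodes, 2)
    pick <- runif(ncol(all_pairs)) < 0.4
    edges <- lapply(which(pick), function(q) all_pairs[, q])
    own <- stats::setNames(round(runif(n, 0.7, 0.95), 3), nodes)
    g <- mk_graph(nodes, edges, own)
    expect_identical(cluster_by_centers(g, 3)$clusters, cluster_oracle(g, 3))
  }
})

test_that("overlap proportions count shared positives among member positives", {
  lab <- matrix(0, 6, 2, dimnames = list(paste0("e", 1:6), c("c", "m")))
  lab[1:3, "c"] <- 1
  lab[1:4, "m"] <- 1
  ot <- overlap_table(lab, list(c = c("c", "m")))
  expect_equal(ot$overlap[ot$phenotype == "m"], 0.75)
  expect_equal(ot$overlap[ot$phenotype == "c"], 1.00)  # centre vs itself
  lab2 <- lab; lab2[, "m"] <- c(0, 0, 0, 1, 1, 0)      # disjoint sets
  expect_equal(overlap_table(lab2, list(c = c("c", "m")))$overlap[2], 0)
  lab3 <- lab; lab3[, "m"] <- 0                        # zero positives
  expect_true(is.na(overlap_table(lab3, list(c = c("c", "m")))$overlap[2]))
})

test_that("the adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(4)
  for (i in 1:20) {
    a <- sample(1:4, 30, TRUE)
    b <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
})
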