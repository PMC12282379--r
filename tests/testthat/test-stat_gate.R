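# Rank statistics, the Mann-Whitney test, and the multi-step gate.

# brute-force pairwise AUROC oracle: fraction of (pos, neg) pairs won, ties
# counted one half
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("midrank AUROC equals the pairwise-counting oracle and the U identity holds", {
  expect_equal(auroc(c(.9, .8, .1, .2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auroc(c(.8, .4, .6, .2), c(1, 1, 0, 0)), 0.75)
  set.seed(7)
  for (i in 1:300) {
    n <- sample(4:25, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    a <- auroc(scores, labels)
    expect_equal(a, auroc_oracle(scores, labels), tolerance = 1e-12)
    u <- mwu_u(scores, labels)
    expect_equal(a * sum(labels == 1) * sum(labels == 0), u,
                 tolerance = 1e-12)
  }
})

test_that("AUROC requires both classes", {
  expect_error(auroc(1:3, c(1, 1, 1)), "undefined")
  expect_error(auroc(1:3, c(0, 0, 0)), "undefined")
})

test_that("exact MWU p-value matches complete enumeration on the toy example", {
  r <- mwu_test(c(.9, .8, .1, .2), c(1, 1, 0, 0))
  expect_equal(r$U, 4)
  expect_equal(r$method, "exact")
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
})

test_that("identical score multisets give p = 1", {
  r <- mwu_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$p, 1.0)
})

test_that("normal-approximation MWU is calibrated under the null", {
  set.seed(11)
  n_sim <- 400
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    s <- rnorm(60)
    y <- rep(c(1, 0), each = 30)
    rej[i] <- mwu_test(s, y, method = "normal")$p < 0.05
  }
  # 95% binomial CI around 0.05 at 400 simulations
  expect_gt(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / n_sim))
  expect_lt(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("midrank AUROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    s <- round(rnorm(n), 1)              # ties included
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("MWU agrees with wilcox.test on continuous data", {
  set.seed(3)
  s <- rnorm(80); y <- rbinom(80, 1, 0.4)
  r <- mwu_test(s, y, method = "normal")
  w <- wilcox.test(s[y == 1], s[y == 0], exact = FALSE, correct = FALSE)
  expect_equal(r$U, unname(w$statistic))
  expect_equal(r$p, w$p.value, tolerance = 1e-10)
})

test_that("Bonferroni gate uses alpha / n_tests", {
  expect_equal(signif(bonferroni_cutoff(0.01, 1243), 1), 8e-6)
  expect_true(significance_gate(1e-6, 0.01, 1243))
  expect_false(significance_gate(1e-5, 0.01, 1243))
  expect_error(significance_gate(0.5, 0.01, 0), "positive")
})

test_that("replication gate applies significance, count and AUC filters in order", {
  mk <- function(phen, n_pos, p, auc, site)
    data.frame(phenotype = phen, site = site, n_pos = n_pos, n_neg = 10000,
               U = NA, p = p, auroc = auc, auprc = NA, threshold = NA,
               sensitivity = NA, specificity = NA, ppv = NA, f1 = NA)
  a <- rbind(mk("sep", 17133, 1e-12, 0.84, "A"),
             mk("x1", 5000, 1e-12, 0.82, "A"),
             mk("x2", 400, 1e-12, 0.90, "A"),
             mk("x3", 5000, 1e-3, 0.90, "A"),
             mk("x4", 5000, 1e-12, 0.78, "A"))
  b <- rbind(mk("sep", 26357, 1e-12, 0.79, "B"),
             mk("x1", 5000, 1e-12, 0.74, "B"),
             mk("x2", 5000, 1e-12, 0.90, "B"),
             mk("x3", 5000, 1e-12, 0.90, "B"),
             mk("x4", 5000, 1e-12, 0.85, "B"))
  g <- replication_gate(a, b, n_tests = 1243)
  expect_equal(g$shortlist, "sep")     # the septicaemia-shaped row passes
  tab <- g$table
  expect_equal(tab$dropped_at[tab$phenotype == "x1"], "auc_gate")
  expect_equal(tab$dropped_at[tab$phenotype == "x2"], "count_a")
  expect_equal(tab$dropped_at[tab$phenotype == "x3"], "significance")
  expect_equal(unname(g$funnel), c(5, 4, 3, 3, 1))
  # reversed criteria swap the two thresholds: the replication site now
  # needs 0.80 (dropping the 0.79 septicaemia-shaped row) while the
  # discovery site only needs 0.75 (admitting x4)
  g_rev <- replication_gate(a, b, n_tests = 1243, reversed = TRUE)
  expect_false("sep" %in% g_rev$shortlist)
  expect_true("x4" %in% g_rev$shortlist)
})

test_that("lowering the AUC thresholds never shrinks the shortlist", {
  set.seed(21)
  mk <- function(site) data.frame(
    phenotype = paste0("p", 1:40), site = site, n_pos = 501 + rpois(40, 300),
    n_neg = 9000, U = NA, p = 10^-runif(40, 2, 12),
    auroc = runif(40, 0.6, 0.95), auprc = NA, threshold = NA,
    sensitivity = NA, specificity = NA, ppv = NA, f1 = NA)
  a <- mk("A"); b <- mk("B")
  g1 <- replication_gate(a, b, thr_a = 0.80, thr_b = 0.75)
  g2 <- replication_gate(a, b, thr_a = 0.75, thr_b = 0.70)
  expect_true(all(g1$shortlist %in% g2$shortlist))
})

test_that("operating point hits the achievable specificity closest to target", {
  # 10 negatives with distinct scores: specificities are multiples of 0.1
  scores <- c(1:10 / 10, 0.95, 0.99)
  labels <- c(rep(0, 10), 1, 1)
  op <- operating_point(scores, labels, target_specificity = 0.90)
  expect_equal(op$specificity, 0.90)
  expect_equal(op$sensitivity, 1.0)
  # metric / confusion-count internal consistency
  expect_equal(op$sensitivity, op$tp / (op$tp + op$fn))
  expect_equal(op$ppv, op$tp / (op$tp + op$fp))
  expect_equal(op$f1, 2 * op$ppv * op$sensitivity / (op$ppv + op$sensitivity))
  expect_equal(op$tp + op$fp + op$tn + op$fn, length(labels))
  # perfect separation: sensitivity 1 at the chosen threshold
  op2 <- operating_point(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(op2$sensitivity, 1.0)
})

test_that("AUPRC matches hand-enumerated step areas", {
  expect_equal(auprc(c(10, 9, 1, 2), c(1, 1, 0, 0)), 1.0)
  # ranked labels 1,0,1,0: area = 1/2 * 1 + 1/2 * 2/3
  expect_equal(auprc(c(4, 3, 2, 1), c(1, 0, 1, 0)), 0.5 + 0.5 * 2 / 3)
  set.seed(5)
  s <- rnorm(4000); y <- rbinom(4000, 1, 0.15)
  expect_equal(auprc(s, y), mean(y), tolerance = 0.05)
})

test_that("cross-site agreement fractions follow the AUC gaps", {
  a <- c(p1 = 0.80, p2 = 0.80, p3 = 0.90)
  expect_equal(cross_site_agreement(a, a)$frac_within_05, 1.0)
  b <- c(p1 = 0.74, p2 = 0.80, p3 = 0.78)
  cs <- cross_site_agreement(a, b)
  expect_equal(cs$frac_within_05, 1 / 3)
  expect_equal(cs$frac_within_10, 2 / 3)
  expect_equal(cs$n_gap_a_higher, 1)
  expect_error(cross_site_agreement(c(x = 1), c(y = 1)), "common")
})
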