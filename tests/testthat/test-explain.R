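# Sparse model selection/refit/scoring, transfer AUCs, odds ratios.

# standardized synthetic measurement table with a known 3-feature phenotype
sparse_sim <- function(n = 3000, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("m", 1:10)))
  true_w <- c(m2 = 1.2, m5 = -1.0, m7 = 0.8)
  z <- -2 + drop(X[, names(true_w)] %*% true_w)
  y <- rbinom(n, 1, plogis(z))
  split <- factor(rep(c("train", "tune", "test"), length.out = n),
                  levels = c("train", "tune", "test"))
  list(X = X, y = y, split = split, true_w = true_w)
}

test_that("lasso selection finds planted features first and honours constraints", {
  d <- sparse_sim()
  sel <- lasso_select(d$X[d$split == "train", ], d$y[d$split == "train"],
                      k_max = 7)
  expect_setequal(utils::head(sel, 3), names(d$true_w))
  # exclusions never appear
  sel_ex <- lasso_select(d$X[d$split == "train", ], d$y[d$split == "train"],
                         k_max = 7, exclude_list = "m2")
  expect_false("m2" %in% sel_ex)
  # k_max truncates in entry order
  sel2 <- lasso_select(d$X[d$split == "train", ], d$y[d$split == "train"],
                       k_max = 2)
  expect_length(sel2, 2)
  # nesting: the k_max = 5 set is a prefix of the k_max = 7 set
  sel5 <- lasso_select(d$X[d$split == "train", ], d$y[d$split == "train"],
                       k_max = 5)
  expect_identical(sel5, utils::head(sel, 5))
  expect_error(lasso_select(d$X[, 1, drop = FALSE], d$y), "fewer than 2")
})

test_that("the unregularized refit recovers planted weights and signs", {
  d <- sparse_sim(n = 10000, seed = 2)
  m <- refit_sparse(names(d$true_w), d$X, d$y, d$split, phenotype = "toy")
  expect_s3_class(m, "sparse_linear_model")
  expect_equal(unname(sign(m$weights)), unname(sign(d$true_w)))
  expect_equal(unname(m$weights), unname(d$true_w), tolerance = 0.12)
  expect_gt(m$auroc_test, 0.8)
  # relaxation: the unpenalized training AUROC is at least the lasso fit's
  Xtr <- d$X[d$split == "train", ]
  ytr <- d$y[d$split == "train"]
  lf <- glmnet::glmnet(scale(Xtr[, names(d$true_w)]), ytr,
                       family = "binomial", alpha = 1, lambda = 0.02,
                       standardize = FALSE)
  lasso_auc <- auroc(drop(predict(lf, scale(Xtr[, names(d$true_w)]))), ytr)
  expect_gte(m$auroc_train + 1e-9, lasso_auc)
})

test_that("scoring the bundled reference models composes intercepts exactly", {
  fx <- load_sparse_fixtures()
  z <- lapply(fx, function(m)
    score_sparse(m, stats::setNames(rep(0, length(m$weights)),
                                    names(m$weights)))$logit)
  expect_equal(unname(z$ascites), -5.61)
  expect_equal(unname(z$neutropenia), -4.88)
  expect_equal(unname(z$respiratory_failure), -3.52)
  expect_equal(unname(z$lung_transplant), -6.30)
  expect_equal(unname(z$menstrual_disorders), -6.75)
  # a unit increase in one standardized feature moves the logit by its weight
  m <- fx$ascites
  x1 <- stats::setNames(rep(0, length(m$weights)), names(m$weights))
  x2 <- x1; x2["Number of QRS Complexes"] <- 1
  expect_equal(score_sparse(m, x2)$logit - score_sparse(m, x1)$logit,
               unname(m$weights["Number of QRS Complexes"]))
  expect_error(score_sparse(m, c(x = 1)), "missing measurement")
})

test_that("standardization round-trips: raw-scale scoring reproduces the fit's predictor", {
  d <- sparse_sim(n = 2000, seed = 3)
  m <- refit_sparse(names(d$true_w), d$X, d$y, d$split)
  tr <- d$split == "train"
  z_raw <- score_sparse(m, d$X[tr, ], standardized = FALSE)$logit
  Xz <- sweep(sweep(d$X[tr, names(d$true_w)], 2, m$center), 2, m$scale, "/")
  z_std <- drop(Xz %*% m$weights) + m$intercept
  expect_equal(z_raw, z_std, tolerance = 1e-12)
})

test_that("a frozen model transfers to related labels and stays at chance on nulls", {
  d <- sparse_sim(n = 6000, seed = 4)
  m <- refit_sparse(names(d$true_w), d$X, d$y, d$split)
  te <- d$split == "test"
  # applied to its own phenotype it reproduces the stored test AUROC
  expect_equal(transfer_auc(m, d$X[te, ], d$y[te]), m$auroc_test,
               tolerance = 1e-8)
  # a correlated sibling phenotype (same generating features, jittered)
  set.seed(9)
  z_sib <- -2 + drop(d$X[, names(d$true_w)] %*% (d$true_w * 0.9)) +
    rnorm(6000, 0, 0.5)
  y_sib <- rbinom(6000, 1, plogis(z_sib))
  expect_gt(transfer_auc(m, d$X[te, ], y_sib[te]), m$auroc_test - 0.1)
  y_null <- rbinom(6000, 1, 0.2)
  expect_lt(abs(transfer_auc(m, d$X[te, ], y_null[te]) - 0.5), 0.07)
})

test_that("odds ratios follow the 2x2 arithmetic with Haldane correction", {
  expect_equal(odds_ratio_2x2(counts = c(10, 90, 10, 890)),
               (10 * 890) / (90 * 10), tolerance = 1e-12)
  # zero cell: finite and positive after correction
  or0 <- odds_ratio_2x2(counts = c(0, 50, 10, 940))
  expect_true(is.finite(or0) && or0 > 0)
  # invariances: swapping both margins leaves the OR; transposing inverts it
  cnt <- c(12, 30, 7, 200)
  expect_equal(odds_ratio_2x2(counts = cnt),
               odds_ratio_2x2(counts = cnt[c(4, 3, 2, 1)]))
  expect_equal(odds_ratio_2x2(counts = cnt),
               1 / odds_ratio_2x2(counts = cnt[c(2, 1, 4, 3)]))
})

test_that("statement odds ratios detect dependence and stay near 1 under independence", {
  set.seed(6)
  n <- 4000
  y <- rbinom(n, 1, 0.15)
  sc <- rnorm(n) + 1.5 * y
  has_dep <- rbinom(n, 1, plogis(-3 + 2.5 * y)) == 1
  has_ind <- rbinom(n, 1, 0.1) == 1
  labels <- matrix(y, ncol = 1, dimnames = list(sprintf("e%04d", 1:n), "P"))
  scores <- matrix(sc, ncol = 1, dimnames = dimnames(labels))
  st <- rbind(
    data.frame(ecg_id = rownames(labels)[has_dep], statement = "dep"),
    data.frame(ecg_id = rownames(labels)[has_ind], statement = "ind"))
  ors <- statement_odds_ratios(st, labels, scores)
  expect_gt(ors$or_condition[ors$statement == "dep"], 5)
  expect_gt(ors$or_top[ors$statement == "dep"], 2)
  expect_equal(ors$or_condition[ors$statement == "ind"], 1, tolerance = 0.45)
  expect_true(ors$highlight[ors$statement == "dep"])
})
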