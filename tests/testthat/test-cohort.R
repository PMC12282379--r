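# Phecode mapping, hierarchy closure, window association, splits and the
# inclusion filter.

toy_map <- data.frame(code = c("a1", "a2", "b1", "c1"),
                      phecode = c("204.11", "204.11", "204.1", "288.11"),
                      stringsAsFactors = FALSE)

test_that("phecode hierarchy truncates decimal strings to integer roots", {
  expect_equal(phecode_parent("204.11"), "204.1")
  expect_equal(phecode_parent("204.1"), "204")
  expect_true(is.na(phecode_parent("204")))
  expect_equal(phecode_ancestors("204.11")[[1]], c("204.1", "204"))
  expect_equal(phecode_ancestors("288.11")[[1]], c("288.1", "288"))
})

test_that("mapping translates codes, drops unmapped, and closes over the hierarchy", {
  ev <- data.frame(patient_id = c("p1", "p1", "p2"),
                   code = c("a1", "zz", "c1"), date = c(10, 20, 30))
  out <- map_icd_to_phecode(ev, toy_map)
  expect_equal(attr(out, "n_unmapped"), 1)
  # a 204.11 event also labels 204.1 and 204 via closure
  p1 <- out[out$patient_id == "p1", "phecode"]
  expect_setequal(p1, c("204.11", "204.1", "204"))
  # leaf-only mode
  out_leaf <- map_icd_to_phecode(ev, toy_map, closure = FALSE)
  expect_setequal(out_leaf$phecode[out_leaf$patient_id == "p1"], "204.11")
  # two codes to the same phecode on one date collapse to one event
  ev2 <- data.frame(patient_id = "p1", code = c("a1", "a2"), date = 5)
  out2 <- map_icd_to_phecode(ev2, toy_map, closure = FALSE)
  expect_equal(nrow(out2), 1)
  expect_error(map_icd_to_phecode(ev, toy_map[0, ]), "empty")
})

test_that("window association is inclusive at the boundary and keeps all ECGs", {
  ecgs <- data.frame(ecg_id = c("e1", "e2", "e3"),
                     patient_id = "p1", date = c(100, 100, 500))
  ev <- data.frame(patient_id = "p1", phecode = "204", date = 130)
  lab <- associate_labels(ecgs[1, ], ev, window_days = 30)
  expect_equal(as.numeric(lab["e1", "204"]), 1)      # |delta| = 30 inclusive
  ev31 <- data.frame(patient_id = "p1", phecode = "204", date = 131)
  lab31 <- associate_labels(ecgs[1, ], ev31, window_days = 30)
  expect_equal(as.numeric(lab31["e1", "204"]), 0)
  # all ECGs stay in the matrix, unlabeled ones as all-negative rows
  lab_all <- associate_labels(ecgs, ev, window_days = 30)
  expect_equal(nrow(lab_all), 3)
  expect_equal(as.numeric(lab_all["e3", "204"]), 0)
})

test_that("one event labels exactly the ECGs within the window", {
  ecgs <- data.frame(ecg_id = c("e1", "e2", "e3"), patient_id = "p1",
                     date = c(25, 60, 90))
  ev <- data.frame(patient_id = "p1", phecode = "X", date = 50)
  lab <- associate_labels(ecgs, ev, window_days = 30)
  expect_equal(as.numeric(lab[, "X"]), c(1, 1, 0))
})

test_that("the association window is symmetric and monotone in its width", {
  set.seed(13)
  for (i in 1:25) {
    ecgs <- data.frame(ecg_id = paste0("e", 1:6), patient_id = "p1",
                       date = sample(0:200, 6))
    ev <- data.frame(patient_id = "p1", phecode = "X",
                     date = sample(0:200, 3))
    w <- sample(0:40, 1)
    lab <- associate_labels(ecgs, ev, window_days = w)
    # symmetry: negating the time axis swaps which comes first
    lab_swap <- associate_labels(transform(ecgs, date = -date),
                                 transform(ev, date = -date),
                                 window_days = w)
    expect_equal(as.matrix(lab), as.matrix(lab_swap))
    # monotonicity: a wider window never removes positives
    lab_wide <- associate_labels(ecgs, ev, window_days = w + 10)
    expect_true(all(lab_wide >= lab))
  }
})

test_that("patient splits are deterministic, exact under quota, and phenotype-independent", {
  ids <- sprintf("P%03d", 1:10)
  s1 <- split_patients(ids, seed = 4, method = "quota")
  expect_equal(as.numeric(table(s1)), c(5, 1, 4))
  expect_identical(s1, split_patients(ids, seed = 4, method = "quota"))
  # hash mode: expected proportions at larger n
  ids2 <- sprintf("P%05d", 1:4000)
  s2 <- split_patients(ids2, seed = 1, method = "hash")
  expect_equal(unname(as.numeric(table(s2)) / 4000), c(0.5, 0.1, 0.4),
               tolerance = 0.05)
  expect_identical(s2, split_patients(ids2, seed = 1, method = "hash"))
  expect_false(identical(s2, split_patients(ids2, seed = 2, method = "hash")))
})

test_that("every ECG of a patient inherits one split", {
  lb <- mid_labels()
  co <- mid_cohort()
  ecgs_a <- co$ecgs[co$ecgs$site_id == "A", ]
  per_pat <- tapply(as.character(lb$A$split), ecgs_a$patient_id,
                    function(x) length(unique(x)))
  expect_true(all(per_pat == 1))
  expect_equal(length(lb$A$split), nrow(ecgs_a))
})

test_that("the inclusion filter matches brute-force enumeration", {
  set.seed(8)
  labels <- matrix(rbinom(20 * 6, 1, 0.4), 20, 6,
                   dimnames = list(NULL, paste0("p", 1:6)))
  split <- factor(sample(c("train", "tune", "test"), 20, TRUE),
                  levels = c("train", "tune", "test"))
  res <- filter_phenotypes(labels, split, min_total = 5, min_per_split = 2)
  for (j in seq_len(6)) {
    manual <- sum(labels[, j]) >= 5 &&
      all(sapply(c("train", "tune", "test"),
                 function(s) sum(labels[split == s, j]) >= 2))
    expect_equal(res$included[j], manual)
  }
})

test_that("inclusion thresholds behave as specified at the boundaries", {
  mk <- function(n_train, n_tune, n_test) {
    n <- n_train + n_tune + n_test
    labels <- matrix(1, n, 1, dimnames = list(NULL, "p"))
    split <- factor(rep(c("train", "tune", "test"),
                        c(n_train, n_tune, n_test)),
                    levels = c("train", "tune", "test"))
    filter_phenotypes(labels, split)$included
  }
  expect_true(mk(80, 10, 10))          # total exactly 100, each split >= 10
  expect_false(mk(79, 10, 10))         # total 99
  expect_false(mk(131, 9, 10))         # per-split rule violated
})
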