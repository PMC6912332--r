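test_that("confusion counting satisfies its identities", {
  cc <- confusion(c("malign", "benign"), c("malign", "benign"))
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(1, 1, 0, 0))
  # a constant all-benign classifier on 50 malign + 11 benign
  cc2 <- confusion(rep("benign", 61), rep(c("malign", "benign"), c(50, 11)))
  expect_equal(c(cc2$tp, cc2$fn, cc2$tn, cc2$fp), c(0, 50, 11, 0))
  expect_equal(cc2$n_positive, 50)
  expect_equal(cc2$n_negative, 11)
  expect_error(confusion("malign", c("malign", "benign")), "lengths differ")
  expect_error(confusion(character(), character()), "empty")
})

test_that("confusion counts match an elementwise tally on random pairs", {
  withr::with_seed(99, {
    pred <- sample(c("benign", "malign"), 500, replace = TRUE)
    truth <- sample(c("benign", "malign"), 500, replace = TRUE)
  })
  cc <- confusion(pred, truth)
  tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in 1:500) {
    key <- if (truth[i] == "malign") {
      if (pred[i] == "malign") "tp" else "fn"
    } else {
      if (pred[i] == "malign") "fp" else "tn"
    }
    tally[key] <- tally[key] + 1
  }
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), unname(tally[c("tp", "tn", "fp", "fn")]))
  # order invariance
  o <- sample(500)
  cc2 <- confusion(pred[o], truth[o])
  expect_equal(cc2, cc)
})

test_that("metrics follow their defining formulas", {
  perfect <- confusion(rep(c("malign", "benign"), c(50, 11)),
                       rep(c("malign", "benign"), c(50, 11)))
  expect_equal(metrics(perfect), list(accuracy = 1, specificity = 1,
                                      sensitivity = 1))
  cc <- structure(list(tp = 45, tn = 8, fp = 3, fn = 5, n_positive = 50,
                       n_negative = 11, total = 61),
                  class = "confusion_counts")
  m <- metrics(cc)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 8 / 11)
  expect_equal(m$accuracy, 53 / 61)
  # random counts against the formula oracle
  withr::with_seed(5, {
    for (rep in 1:10) {
      k <- sample(0:30, 4, replace = TRUE)
      if (sum(k) == 0) k[1] <- 1
      cc <- structure(list(tp = k[1], tn = k[2], fp = k[3], fn = k[4],
                           n_positive = k[1] + k[4], n_negative = k[2] + k[3],
                           total = sum(k)),
                      class = "confusion_counts")
      m <- metrics(cc)
      expect_equal(m$accuracy, (k[1] + k[2]) / sum(k))
      if (k[2] + k[3] > 0) expect_equal(m$specificity, k[2] / (k[2] + k[3]))
      if (k[1] + k[4] > 0) expect_equal(m$sensitivity, k[1] / (k[1] + k[4]))
    }
  })
})

test_that("metrics mark an absent class as undefined rather than erroring", {
  all_mal <- confusion(rep("malign", 5), rep("malign", 5))
  m <- metrics(all_mal)
  expect_true(is.na(m$specificity))
  expect_equal(m$sensitivity, 1)
  expect_error(metrics(structure(list(tp = 0, tn = 0, fp = 0, fn = 0,
                                      n_positive = 0, n_negative = 0, total = 0),
                                 class = "confusion_counts")), "zero total")
})

test_that("accuracy lies between sensitivity and specificity", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      pred <- sample(c("benign", "malign"), 40, replace = TRUE)
      truth <- c("benign", "malign",
                 sample(c("benign", "malign"), 38, replace = TRUE))
      m <- metrics(confusion(pred, truth))
      expect_gte(m$accuracy, min(m$sensitivity, m$specificity) - 1e-12)
      expect_lte(m$accuracy, max(m$sensitivity, m$specificity) + 1e-12)
    }
  })
})

test_that("patient-level splitting reproduces the benchmark fold sizes", {
  withr::with_seed(2, {
    f <- write_synthetic_manifest(52, 246)
  })
  co <- read_manifest(f)
  folds <- split_cohort(co, split_scheme(seed = 4))
  expect_length(folds, 5)
  labels <- setNames(vapply(co$records, `[[`, "", "label"), cohort_ids(co))
  for (fd in folds) {
    expect_length(fd$test, 61)
    expect_length(fd$train, 237)
    expect_equal(sum(labels[fd$test] == "benign"), 11)
    expect_equal(sum(labels[fd$test] == "malign"), 50)
    expect_length(intersect(fd$train, fd$test), 0)
    expect_setequal(c(fd$train, fd$test), cohort_ids(co))
  }
})

test_that("splitting is reproducible and infeasible requests error", {
  withr::with_seed(2, {
    f <- write_synthetic_manifest(12, 20)
  })
  co <- read_manifest(f)
  sch <- split_scheme(test_benign = 3, test_malign = 5, seed = 77)
  expect_identical(split_cohort(co, sch), split_cohort(co, sch))
  expect_error(split_cohort(co, split_scheme(test_benign = 13, test_malign = 5)),
               "infeasible")
})

test_that("stratified partition covers the cohort in disjoint folds", {
  withr::with_seed(8, {
    f <- write_synthetic_manifest(10, 15)
  })
  co <- read_manifest(f)
  folds <- split_cohort(co, split_scheme(mode = "stratified_partition", seed = 3))
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tests, cohort_ids(co))
  expect_equal(anyDuplicated(tests), 0)
  for (fd in folds) expect_length(intersect(fd$train, fd$test), 0)
})

test_that("cross-validation reports fold metrics and their means", {
  withr::with_seed(14, {
    f <- write_synthetic_manifest(8, 8)
  })
  co <- read_manifest(f)
  sch <- split_scheme(n_folds = 2, test_benign = 3, test_malign = 3, seed = 5)
  # degenerate always-malign pipeline, independent of training data
  fit <- function(train_cohort) "const"
  classify <- function(model, test_cohort) {
    do.call(rbind, lapply(test_cohort$records, function(r)
      data.frame(patient_id = r$patient_id, truth = r$label,
                 final_label = "malign")))
  }
  rep_ <- cross_validate(co, sch, fit, classify)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$per_fold$sensitivity, c(1, 1))
  expect_equal(rep_$per_fold$specificity, c(0, 0))
  expect_equal(rep_$mean_accuracy, mean(rep_$per_fold$accuracy))
  expect_equal(rep_$mean_accuracy, 0.5)
})

test_that("cross-validation never lets test patients into training", {
  withr::with_seed(15, {
    f <- write_synthetic_manifest(6, 6)
  })
  co <- read_manifest(f)
  seen <- list()
  fit <- function(train_cohort) cohort_ids(train_cohort)
  classify <- function(model, test_cohort) {
    expect_length(intersect(model, cohort_ids(test_cohort)), 0)
    do.call(rbind, lapply(test_cohort$records, function(r)
      data.frame(patient_id = r$patient_id, truth = r$label,
                 final_label = r$label)))
  }
  rep_ <- cross_validate(co, split_scheme(n_folds = 3, test_benign = 2,
                                          test_malign = 2, seed = 1),
                         fit, classify)
  expect_equal(rep_$mean_accuracy, 1)
})
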