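#' Confusion counts with malign as the positive class
#'
#' @param predicted,truth Equal-length character vectors of
#'   `"benign"` / `"malign"`.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`, `n_positive` (`tp + fn`), `n_negative` (`tn + fp`), `total`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` lengths differ", call. = FALSE)
  if (length(truth) == 0L)
    stop("empty prediction/truth lists", call. = FALSE)
  ok <- c("benign", "malign")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop("labels must be 'benign' or 'malign'", call. = FALSE)
  tp <- sum(predicted == "malign" & truth == "malign")
  tn <- sum(predicted == "benign" & truth == "benign")
  fp <- sum(predicted == "malign" & truth == "benign")
  fn <- sum(predicted == "benign" & truth == "malign")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 n_positive = tp + fn, n_negative = tn + fp,
                 total = tp + tn + fp + fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP %d, TN %d, FP %d, FN %d (%d positive, %d negative)>\n",
              x$tp, x$tn, x$fp, x$fn, x$n_positive, x$n_negative))
  invisible(x)
}

#' Accuracy, specificity and sensitivity from confusion counts
#'
#' Accuracy `(TP + TN) / (TP + TN + FP + FN)`, specificity `TN / (TN + FP)`,
#' sensitivity `TP / (TP + FN)`, with malign as the positive class. When a
#' class is absent the corresponding metric is `NA` (undefined), not an error.
#'
#' @param counts A [confusion()] result.
#' @return Named list `accuracy`, `specificity`, `sensitivity`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$total == 0L)
    stop("metrics undefined for zero total count", call. = FALSE)
  list(
    accuracy = (counts$tp + counts$tn) / counts$total,
    specificity = if (counts$n_negative > 0) counts$tn / counts$n_negative
                  else NA_real_,
    sensitivity = if (counts$n_positive > 0) counts$tp / counts$n_positive
                  else NA_real_
  )
}

#' Patient-level splitting scheme
#'
#' @param n_folds Number of folds (default 5).
#' @param test_benign,test_malign Test-set patient counts per class for
#'   `repeated_random` mode (defaults 11 and 50, the benchmark split that
#'   leaves 41 benign and 196 malign patients for training).
#' @param mode `"repeated_random"` — each fold draws its test patients
#'   uniformly without replacement, independently across folds;
#'   `"stratified_partition"` — disjoint near-equal test folds covering the
#'   cohort once.
#' @param seed Integer seed.
#' @return A list of class `split_scheme`.
#' @export
split_scheme <- function(n_folds = 5, test_benign = 11, test_malign = 50,
                         mode = c("repeated_random", "stratified_partition"),
                         seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_folds >= 2, test_benign >= 0, test_malign >= 0)
  structure(list(n_folds = as.integer(n_folds),
                 test_benign = as.integer(test_benign),
                 test_malign = as.integer(test_malign),
                 mode = mode, seed = as.integer(seed)),
            class = "split_scheme")
}

#' Split a cohort into patient-level train/test folds
#'
#' Splitting is by patient: all images of a patient stay on one side of the
#' boundary. Reproducible given the scheme's seed.
#'
#' @param cohort A `cohort`.
#' @param scheme A [split_scheme()].
#' @return A list of `n_folds` elements, each `list(train = ids, test = ids)`.
#' @export
split_cohort <- function(cohort, scheme) {
  stopifnot(inherits(cohort, "cohort"), inherits(scheme, "split_scheme"))
  labels <- vapply(cohort$records, `[[`, "", "label")
  ids <- cohort_ids(cohort)
  ben <- ids[labels == "benign"]; mal <- ids[labels == "malign"]
  if (scheme$mode == "repeated_random") {
    if (scheme$test_benign > length(ben) || scheme$test_malign > length(mal))
      stop(sprintf(
        "infeasible split: requested %d benign / %d malign test patients from %d / %d",
        scheme$test_benign, scheme$test_malign, length(ben), length(mal)),
        call. = FALSE)
    withr::with_seed(scheme$seed, {
      folds <- lapply(seq_len(scheme$n_folds), function(f) {
        test <- c(sample(ben, scheme$test_benign),
                  sample(mal, scheme$test_malign))
        list(train = setdiff(ids, test), test = test)
      })
    })
  } else {
    withr::with_seed(scheme$seed, {
      fb <- sample(rep_len(seq_len(scheme$n_folds), length(ben)))
      fm <- sample(rep_len(seq_len(scheme$n_folds), length(mal)))
      folds <- lapply(seq_len(scheme$n_folds), function(f) {
        test <- c(ben[fb == f], mal[fm == f])
        list(train = setdiff(ids, test), test = test)
      })
    })
  }
  folds
}

#' Cross-validated evaluation of a classification pipeline
#'
#' For each fold, fits a fresh pipeline on the training patients only and
#' classifies the test patients' images. Train/test patient disjointness is
#' asserted inside the loop. Metrics are per image by default; with
#' `aggregate_patients = TRUE` they are additionally computed per patient
#' (a patient is called malign if any of their images is).
#'
#' @param cohort A `cohort` whose image paths are readable.
#' @param scheme A [split_scheme()].
#' @param fit_fun Function `(train_cohort) -> model`.
#' @param classify_fun Function `(model, test_cohort) -> data frame` with
#'   columns `patient_id`, `truth`, `final_label` (one row per image).
#'   Defaults to running [classify_cohort()] for `cascade_model` fits.
#' @param aggregate_patients Also report patient-level folds.
#' @return An object of class `eval_report`: `per_fold` (data frame of fold,
#'   tp, tn, fp, fn, accuracy, specificity, sensitivity),
#'   `mean_accuracy`, `mean_specificity`, `mean_sensitivity`, and optionally
#'   `per_fold_patients` with its own means.
#' @export
cross_validate <- function(cohort, scheme, fit_fun, classify_fun = NULL,
                           aggregate_patients = FALSE) {
  stopifnot(inherits(cohort, "cohort"), inherits(scheme, "split_scheme"))
  if (is.null(classify_fun)) {
    classify_fun <- function(model, test_cohort) {
      stopifnot(inherits(model, "cascade_model"))
      classify_cohort(test_cohort, model$threshold_model, model$cnn_model,
                      model$params)$decisions
    }
  }
  folds <- split_cohort(cohort, scheme)
  fold_rows <- list(); pat_rows <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    if (length(intersect(fold$train, fold$test)) > 0L)
      stop(sprintf("fold %d: train and test patients overlap", f), call. = FALSE)
    model <- tryCatch(fit_fun(subset_cohort(cohort, fold$train)),
                      error = function(e) stop(sprintf(
                        "training failed in fold %d: %s", f, conditionMessage(e)),
                        call. = FALSE))
    dec <- classify_fun(model, subset_cohort(cohort, fold$test))
    cc <- confusion(dec$final_label, dec$truth)
    mm <- metrics(cc)
    fold_rows[[f]] <- data.frame(fold = f, tp = cc$tp, tn = cc$tn,
                                 fp = cc$fp, fn = cc$fn,
                                 accuracy = mm$accuracy,
                                 specificity = mm$specificity,
                                 sensitivity = mm$sensitivity)
    if (aggregate_patients) {
      ag <- lapply(split(dec, dec$patient_id), function(d)
        data.frame(truth = d$truth[1],
                   final_label = if (any(d$final_label == "malign")) "malign"
                                 else "benign"))
      ag <- do.call(rbind, unname(ag))
      ccp <- confusion(ag$final_label, ag$truth)
      mmp <- metrics(ccp)
      pat_rows[[f]] <- data.frame(fold = f, tp = ccp$tp, tn = ccp$tn,
                                  fp = ccp$fp, fn = ccp$fn,
                                  accuracy = mmp$accuracy,
                                  specificity = mmp$specificity,
                                  sensitivity = mmp$sensitivity)
    }
  }
  per_fold <- do.call(rbind, fold_rows)
  rep <- list(per_fold = per_fold,
              mean_accuracy = mean(per_fold$accuracy),
              mean_specificity = mean(per_fold$specificity),
              mean_sensitivity = mean(per_fold$sensitivity))
  if (aggregate_patients) {
    pf <- do.call(rbind, pat_rows)
    rep$per_fold_patients <- pf
    rep$mean_accuracy_patients <- mean(pf$accuracy)
    rep$mean_specificity_patients <- mean(pf$specificity)
    rep$mean_sensitivity_patients <- mean(pf$sensitivity)
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d folds>\n", nrow(x$per_fold)))
  print(transform(x$per_fold,
                  accuracy = round(accuracy, 3),
                  specificity = round(specificity, 3),
                  sensitivity = round(sensitivity, 3)), row.names = FALSE)
  cat(sprintf("means: accuracy %.3f, specificity %.3f, sensitivity %.3f\n",
              x$mean_accuracy, x$mean_specificity, x$mean_sensitivity))
  invisible(x)
}
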