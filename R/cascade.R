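#' Classify one ultrasound frame with the two-stage cascade
#'
#' Runs the full pipeline: tissue-region extraction, power spectrum of the
#' crop, fftscore under the calibrated mask, tri-state pre-classification.
#' A confident first-stage call (`benign` or `malign`) is final and the CNN
#' is never invoked; the undecided `benign_malign` band is handed to the CNN,
#' which decides on the same crop. A spectrum with no texture power (constant
#' crop) also falls through to the CNN rather than erroring, so every valid
#' tissue crop receives a label.
#'
#' @param image A [gray_image()] frame.
#' @param threshold_model A calibrated [calibrate_thresholds()] model, with
#'   its `mask` and `side` fields populated.
#' @param cnn_model A `cascade_cnn`; may be `NULL` when the undecided band is
#'   known to be empty (an error is raised only if it is actually needed).
#' @param params A [roi_params()].
#' @return An object of class `cascade_decision`: `final_label`, `stage`
#'   (`"fft"` or `"cnn"`), `fft_score`, `fft_state`, and `cnn_probability`
#'   (`NA` unless the CNN decided).
#' @export
classify_image <- function(image, threshold_model, cnn_model = NULL,
                           params = roi_params()) {
  stopifnot(inherits(threshold_model, "threshold_model"))
  if (is.null(threshold_model$mask) || is.null(threshold_model$side))
    stop("threshold model carries no mask/side; calibrate with them attached",
         call. = FALSE)
  roi <- extract_roi(image, params)
  spec <- power_spectrum(roi$cropped, threshold_model$side)
  if (spec$degenerate) {
    score <- NA_real_
    state <- "benign_malign"       # no texture signal: defer to the CNN
  } else {
    score <- fftscore(spec, threshold_model$mask)
    state <- classify_frequency(score, threshold_model)
  }
  if (state %in% c("benign", "malign")) {
    dec <- list(final_label = state, stage = "fft", fft_score = score,
                fft_state = state, cnn_probability = NA_real_)
  } else {
    if (is.null(cnn_model))
      stop("image falls in the undecided band but no CNN model was supplied",
           call. = FALSE)
    pr <- stats::predict(cnn_model, roi$cropped)
    dec <- list(final_label = pr$label, stage = "cnn", fft_score = score,
                fft_state = state, cnn_probability = pr$prob_malign)
  }
  structure(dec, class = "cascade_decision")
}

#' @export
print.cascade_decision <- function(x, ...) {
  cat(sprintf("<cascade_decision: %s (stage %s, fftscore %.4g%s)>\n",
              x$final_label, x$stage, x$fft_score,
              if (!is.na(x$cnn_probability))
                sprintf(", p_malign %.3f", x$cnn_probability) else ""))
  invisible(x)
}

#' Classify every image of a cohort
#'
#' One decision per image, in manifest order. Per-image failures (unreadable
#' file, no tissue found) are collected and reported; the run continues.
#'
#' @param cohort A `cohort` from [read_manifest()].
#' @param threshold_model A calibrated `threshold_model`.
#' @param cnn_model A `cascade_cnn` (or `NULL`, see [classify_image()]).
#' @param params A [roi_params()].
#' @param aggregate_patients Also report a per-patient label (malign if any
#'   of the patient's images is called malign).
#' @return A list with `decisions` (data frame: `patient_id`, `image_path`,
#'   `truth`, `fft_score`, `fft_state`, `stage`, `cnn_probability`,
#'   `final_label`), `failures` (data frame of `image_path`, `error`), and,
#'   when requested, `patients` (data frame of `patient_id`, `truth`,
#'   `final_label`).
#' @export
classify_cohort <- function(cohort, threshold_model, cnn_model = NULL,
                            params = roi_params(), aggregate_patients = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- list(); fails <- list()
  for (rec in cohort$records) {
    for (pth in rec$image_paths) {
      res <- tryCatch({
        img <- load_image(pth)
        d <- classify_image(img, threshold_model, cnn_model, params)
        data.frame(patient_id = rec$patient_id, image_path = pth,
                   truth = rec$label, fft_score = d$fft_score,
                   fft_state = d$fft_state, stage = d$stage,
                   cnn_probability = d$cnn_probability,
                   final_label = d$final_label, stringsAsFactors = FALSE)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(image_path = pth, error = conditionMessage(res),
                     stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  empty_dec <- data.frame(patient_id = character(), image_path = character(),
                          truth = character(), fft_score = numeric(),
                          fft_state = character(), stage = character(),
                          cnn_probability = numeric(), final_label = character(),
                          stringsAsFactors = FALSE)
  out <- list(
    decisions = if (length(rows)) do.call(rbind, rows) else empty_dec,
    failures = if (length(fails)) do.call(rbind, fails)
               else data.frame(image_path = character(), error = character())
  )
  if (aggregate_patients && nrow(out$decisions)) {
    agg <- lapply(split(out$decisions, out$decisions$patient_id), function(d)
      data.frame(patient_id = d$patient_id[1], truth = d$truth[1],
                 final_label = if (any(d$final_label == "malign")) "malign"
                               else "benign"))
    out$patients <- do.call(rbind, unname(agg))
  }
  out
}

#' Fit the full cascade on a training cohort
#'
#' Convenience fitter used by cross-validation and the command line: extracts
#' tissue crops for every training image, tunes the spectral mask (or uses a
#' fixed one), calibrates the tri-state thresholds at `alpha`, and trains the
#' CNN stage on the same crops.
#'
#' @param cohort Training `cohort`.
#' @param side Spectrum grid size (default 256).
#' @param mask Optional fixed `frequency_mask`; when `NULL` the mask is tuned
#'   over `radii` x `bar_half_widths`.
#' @param radii,bar_half_widths Candidate grids for [tune_mask()].
#' @param alpha Calibration quantile for [calibrate_thresholds()].
#' @param backbone_kind,dropout_rate,config CNN stage settings (see
#'   [build_classifier()], [train_classifier()]).
#' @param params A [roi_params()].
#' @param train_cnn Set `FALSE` to skip the CNN stage (first stage only).
#' @return A list of class `cascade_model` with `threshold_model`,
#'   `cnn_model` (or `NULL`) and `params`.
#' @export
fit_cascade <- function(cohort, side = 256, mask = NULL,
                        radii = c(8, 16, 24, 32, 48),
                        bar_half_widths = c(1, 2, 4, 8),
                        alpha = 0.05, backbone_kind = "tiny_test",
                        dropout_rate = 0.5, config = train_config(),
                        params = roi_params(), train_cnn = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  crops <- list(); labels <- character()
  for (rec in cohort$records) {
    for (pth in rec$image_paths) {
      roi <- extract_roi(load_image(pth), params)
      crops[[length(crops) + 1L]] <- roi$cropped
      labels <- c(labels, rec$label)
    }
  }
  specs <- lapply(crops, power_spectrum, side = side)
  if (is.null(mask)) {
    mask <- tune_mask(specs, labels, side = side, radii = radii,
                      bar_half_widths = bar_half_widths)
    scores <- attr(mask, "scores")
  } else {
    scores <- vapply(specs, fftscore, 0, mask = mask)
  }
  tm <- calibrate_thresholds(scores[labels == "benign"],
                             scores[labels == "malign"],
                             alpha = alpha, mask = mask, side = side)
  cnn <- NULL
  if (train_cnn) {
    cnn <- build_classifier(backbone_kind, dropout_rate = dropout_rate,
                            seed = config$seed)
    cnn <- train_classifier(cnn, crops, labels, config)
  }
  structure(list(threshold_model = tm, cnn_model = cnn, params = params),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("<cascade_model>\n  ")
  print(x$threshold_model)
  if (!is.null(x$cnn_model)) { cat("  "); print(x$cnn_model) }
  invisible(x)
}
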