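# Shared phantom-cohort fixture, generated once per test run and memoised:
# several test files exercise the same end-to-end objects (crops, spectra,
# fitted first stage) and regenerating them per file would dominate runtime.

.fixture_env <- new.env(parent = emptyenv())

# 10 benign + 10 malign phantom cohort written to a session tempdir
phantom_fixture <- function() {
  if (is.null(.fixture_env$cohort)) {
    gen <- generate_cohort(10, 10, dir = file.path(tempdir(), "phantom-fixture"),
                           seed = 20240901)
    crops <- list(); labels <- character(); paths <- character()
    rois <- list()
    for (rec in gen$cohort$records) {
      for (p in rec$image_paths) {
        roi <- extract_roi(load_image(p))
        rois[[length(rois) + 1L]] <- roi
        crops[[length(crops) + 1L]] <- roi$cropped
        labels <- c(labels, rec$label)
        paths <- c(paths, p)
      }
    }
    .fixture_env$cohort <- gen
    .fixture_env$rois <- rois
    .fixture_env$crops <- crops
    .fixture_env$labels <- labels
    .fixture_env$paths <- paths
    .fixture_env$spectra <- lapply(crops, power_spectrum, side = 256)
  }
  list(gen = .fixture_env$cohort, rois = .fixture_env$rois,
       crops = .fixture_env$crops, labels = .fixture_env$labels,
       paths = .fixture_env$paths, spectra = .fixture_env$spectra)
}

# first-stage model calibrated on the fixture with a fixed plus mask
fixture_threshold_model <- function(alpha = 0.05) {
  fx <- phantom_fixture()
  mask <- make_mask("plus", 256, bar_half_width = 1)
  scores <- vapply(fx$spectra, fftscore, 0, mask = mask)
  calibrate_thresholds(scores[fx$labels == "benign"],
                       scores[fx$labels == "malign"],
                       alpha = alpha, mask = mask, side = 256)
}

# a small manifest CSV on disk with one image row per patient; image paths
# need not exist (splitting and label bookkeeping never read them)
write_synthetic_manifest <- function(n_benign, n_malign,
                                     path = tempfile(fileext = ".csv")) {
  n <- n_benign + n_malign
  tirads <- c(sample(c("2", "3"), n_benign, replace = TRUE),
              sample(c("4a", "4b", "4c", "5"), n_malign, replace = TRUE))
  df <- data.frame(patient_id = sprintf("S%04d", seq_len(n)),
                   image_path = sprintf("img_%04d.png", seq_len(n)),
                   tirads = tirads)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
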