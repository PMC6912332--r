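#' Specification of a synthetic ultrasound phantom frame
#'
#' The phantom emulates the gross structure of a clinical ultrasound capture:
#' a near-zero background with mild electronic noise, bright annotation
#' artifacts near 255 outside the scan fan, a large speckled tissue region
#' that is the largest bright connected component of the frame, a hypoechoic
#' (darker) nodule disc inside the tissue, and — for malign cases only —
#' punctate bright calcification spots laid on a jittered axis-aligned
#' lattice inside the nodule, whose regular spacing shifts spectral energy
#' into directional high frequencies. Speckle is multiplicative
#' gamma-distributed noise (mean 1, shape `speckle_shape`), the standard
#' fully-developed-speckle surrogate.
#'
#' The label is derived, never set: a phantom is malign if and only if
#' `n_calcifications > 0`, so a malign spec with the calcifications removed
#' renders, for the same seed, an image identical to its benign twin.
#'
#' @param frame_size `c(height, width)` in pixels; default `c(360, 560)`, the
#'   shape of typical clinical capture frames.
#' @param tissue_box Named integer vector `row_min, col_min, row_max, col_max`
#'   (1-based inclusive) of the tissue region; default a centered 240 x 320
#'   box.
#' @param background_level Background intensity near 0.
#' @param n_artifacts Number of bright annotation glyphs outside the tissue.
#' @param artifact_intensity Glyph intensity near 255.
#' @param speckle_mean Mean tissue intensity.
#' @param speckle_shape Gamma shape of the multiplicative speckle (default 4).
#' @param nodule_radius Radius of the hypoechoic nodule disc.
#' @param nodule_contrast Multiplier (< 1) applied to speckle inside the
#'   nodule.
#' @param n_calcifications Number of calcification spots (0 for benign).
#' @param calcification_radius Spot radius in pixels.
#' @param calcification_intensity Spot intensity near 255.
#' @param calcification_spacing Lattice spacing between spots in pixels.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(frame_size = c(360, 560),
                         tissue_box = NULL,
                         background_level = 8,
                         n_artifacts = 3,
                         artifact_intensity = 250,
                         speckle_mean = 120,
                         speckle_shape = 4,
                         nodule_radius = 60,
                         nodule_contrast = 0.55,
                         n_calcifications = 0,
                         calcification_radius = 2,
                         calcification_intensity = 245,
                         calcification_spacing = 10,
                         seed = 1) {
  if (is.null(tissue_box)) {
    h <- frame_size[1]; w <- frame_size[2]
    tissue_box <- c(row_min = round(h / 2) - 119, col_min = round(w / 2) - 159,
                    row_max = round(h / 2) + 120, col_max = round(w / 2) + 160)
  }
  stopifnot(all(c("row_min", "col_min", "row_max", "col_max") %in% names(tissue_box)),
            tissue_box["row_min"] >= 1, tissue_box["col_min"] >= 1,
            tissue_box["row_max"] <= frame_size[1],
            tissue_box["col_max"] <= frame_size[2],
            background_level >= 0, artifact_intensity <= 255,
            speckle_mean > 0, speckle_shape > 0,
            nodule_radius > 0, nodule_contrast > 0, nodule_contrast <= 1,
            n_calcifications >= 0, calcification_radius >= 1,
            calcification_intensity <= 255, calcification_spacing >= 2)
  structure(list(frame_size = as.integer(frame_size),
                 tissue_box = tissue_box,
                 background_level = background_level,
                 n_artifacts = as.integer(n_artifacts),
                 artifact_intensity = artifact_intensity,
                 speckle_mean = speckle_mean, speckle_shape = speckle_shape,
                 nodule_radius = nodule_radius, nodule_contrast = nodule_contrast,
                 n_calcifications = as.integer(n_calcifications),
                 calcification_radius = calcification_radius,
                 calcification_intensity = calcification_intensity,
                 calcification_spacing = calcification_spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_label <- function(spec) {
  if (spec$n_calcifications > 0) "malign" else "benign"
}

disc_indices <- function(h, w, center, radius) {
  which(outer(seq_len(h) - center[1], seq_len(w) - center[2],
              function(a, b) a^2 + b^2) <= radius^2)
}

# axis-aligned lattice of n spot centers around `center`, spacing `spacing`
calcification_lattice <- function(n, center, spacing) {
  g <- ceiling(sqrt(n))
  offs <- (seq_len(g) - (g + 1) / 2) * spacing
  grid <- expand.grid(dr = offs, dc = offs)
  grid <- grid[order(grid$dr^2 + grid$dc^2), ][seq_len(n), ]
  cbind(row = center[1] + grid$dr, col = center[2] + grid$dc)
}

#' Generate one synthetic ultrasound phantom frame
#'
#' @param spec A [phantom_spec()].
#' @return A list: `image` (a [gray_image()]), `label` (`"benign"` /
#'   `"malign"`), and `ground_truth` (`tissue_box`, `nodule_center`,
#'   `nodule_radius`, `calcification_centers`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$frame_size[1]; w <- spec$frame_size[2]
  tb <- spec$tissue_box
  nod_ctr <- c(round((tb["row_min"] + tb["row_max"]) / 2),
               round((tb["col_min"] + tb["col_max"]) / 2))
  names(nod_ctr) <- c("row", "col")
  # calcifications must fit inside the nodule before any drawing happens
  calc_centers <- NULL
  if (spec$n_calcifications > 0) {
    calc_centers <- calcification_lattice(spec$n_calcifications, nod_ctr,
                                          spec$calcification_spacing)
    reach <- sqrt(max((calc_centers[, 1] - nod_ctr[1])^2 +
                      (calc_centers[, 2] - nod_ctr[2])^2)) +
      spec$calcification_radius
    if (reach > spec$nodule_radius)
      stop(sprintf(
        "invalid spec: %d calcifications at spacing %g need radius %.1f > nodule_radius %g",
        spec$n_calcifications, spec$calcification_spacing, reach,
        spec$nodule_radius), call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    img <- matrix(spec$background_level + stats::rnorm(h * w, sd = 2), h, w)
    # speckled tissue block
    ti <- tb["row_min"]:tb["row_max"]; tj <- tb["col_min"]:tb["col_max"]
    nt <- length(ti) * length(tj)
    speckle <- spec$speckle_mean *
      stats::rgamma(nt, shape = spec$speckle_shape, rate = spec$speckle_shape)
    img[ti, tj] <- speckle
    # hypoechoic nodule (deterministic given the spec)
    nod <- disc_indices(h, w, nod_ctr, spec$nodule_radius)
    img[nod] <- img[nod] * spec$nodule_contrast
    # annotation glyphs in the dark periphery, kept clear of the tissue box
    # so no plausible morphological closing can bridge them into the tissue
    if (spec$n_artifacts > 0) {
      gh <- 6L; gw <- 10L; clearance <- 20L
      placed <- 0L; guard <- 0L
      while (placed < spec$n_artifacts && guard < 1000L) {
        guard <- guard + 1L
        r0 <- sample.int(h - gh, 1L); c0 <- sample.int(w - gw, 1L)
        overlaps <- r0 <= tb["row_max"] + clearance &&
          (r0 + gh - 1L) >= tb["row_min"] - clearance &&
          c0 <= tb["col_max"] + clearance &&
          (c0 + gw - 1L) >= tb["col_min"] - clearance
        if (!overlaps) {
          img[r0:(r0 + gh - 1L), c0:(c0 + gw - 1L)] <- spec$artifact_intensity
          placed <- placed + 1L
        }
      }
    }
    # calcification spots, drawn last so a 0-spot malign spec renders the
    # benign image bit-for-bit
    if (!is.null(calc_centers)) {
      jit <- matrix(stats::runif(length(calc_centers), -1, 1), ncol = 2)
      ctrs <- round(calc_centers + jit)
      for (k in seq_len(nrow(ctrs))) {
        img[disc_indices(h, w, ctrs[k, ], spec$calcification_radius)] <-
          spec$calcification_intensity
      }
      calc_centers <- ctrs
    }
  })
  img <- pmin(pmax(img, 0), 255)
  list(image = gray_image(img),
       label = phantom_label(spec),
       ground_truth = list(tissue_box = tb, nodule_center = nod_ctr,
                           nodule_radius = spec$nodule_radius,
                           calcification_centers = calc_centers))
}

#' Generate a synthetic cohort on disk
#'
#' Draws per-patient phantom specs with jittered geometry and echogenicity
#' around `base_spec`, writes one PNG per image, a manifest CSV with
#' synthetic TI-RADS tokens (benign patients draw 2 or 3, malign patients
#' 4a/4b/4c/5, uniformly), and a ground-truth JSON sidecar.
#'
#' @param n_benign,n_malign Patient counts (total must be positive).
#' @param dir Output directory (created if missing).
#' @param base_spec A [phantom_spec()] giving the central parameter values;
#'   its `n_calcifications` is ignored (set per class).
#' @param malign_calcifications Central calcification count for malign
#'   patients (jittered by up to 2).
#' @param images_per_patient Images per patient (each its own speckle draw).
#' @param seed Master seed; every per-patient seed and jitter flows from it.
#' @return A list: `cohort` (re-read from the written manifest),
#'   `manifest` (path), `ground_truth` (per-patient list, also in
#'   `ground_truth.json`), `dir`.
#' @export
generate_cohort <- function(n_benign, n_malign, dir = tempfile("phantoms"),
                            base_spec = phantom_spec(),
                            malign_calcifications = 12,
                            images_per_patient = 1, seed = 1) {
  stopifnot(n_benign >= 0, n_malign >= 0)
  if (n_benign + n_malign == 0L)
    stop("cohort must contain at least one patient", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_total <- n_benign + n_malign
  labels <- rep(c("benign", "malign"), c(n_benign, n_malign))
  h <- base_spec$frame_size[1]; w <- base_spec$frame_size[2]
  rows <- list(); gt <- list()
  withr::with_seed(seed, {
    for (p in seq_len(n_total)) {
      pid <- sprintf("P%03d", p)
      tirads <- if (labels[p] == "benign") sample(c("2", "3"), 1)
                else sample(c("4a", "4b", "4c", "5"), 1)
      n_calc <- if (labels[p] == "benign") 0L
                else malign_calcifications + sample(-2:2, 1)
      shift <- c(sample(-10:10, 1), sample(-10:10, 1))
      tb <- base_spec$tissue_box +
        c(shift[1], shift[2], shift[1], shift[2])
      tb["row_min"] <- max(tb["row_min"], 1); tb["col_min"] <- max(tb["col_min"], 1)
      tb["row_max"] <- min(tb["row_max"], h); tb["col_max"] <- min(tb["col_max"], w)
      sp_mean <- max(40, base_spec$speckle_mean + stats::rnorm(1, sd = 8))
      gt_p <- list()
      for (im in seq_len(images_per_patient)) {
        spec <- phantom_spec(
          frame_size = base_spec$frame_size, tissue_box = tb,
          background_level = base_spec$background_level,
          n_artifacts = base_spec$n_artifacts,
          artifact_intensity = base_spec$artifact_intensity,
          speckle_mean = sp_mean, speckle_shape = base_spec$speckle_shape,
          nodule_radius = base_spec$nodule_radius,
          nodule_contrast = base_spec$nodule_contrast,
          n_calcifications = n_calc,
          calcification_radius = base_spec$calcification_radius,
          calcification_intensity = base_spec$calcification_intensity,
          calcification_spacing = base_spec$calcification_spacing,
          seed = sample.int(.Machine$integer.max - 1L, 1))
        ph <- generate_phantom(spec)
        fn <- file.path(dir, sprintf("%s_%02d.png", pid, im))
        write_image(ph$image, fn)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, image_path = fn, tirads = tirads,
          stringsAsFactors = FALSE)
        gt_p[[im]] <- ph$ground_truth
      }
      gt[[pid]] <- list(label = labels[p], images = gt_p)
    }
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  list(cohort = read_manifest(manifest), manifest = manifest,
       ground_truth = gt, dir = dir)
}
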