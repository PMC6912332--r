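#' Centered 2-D power spectrum of a grayscale image
#'
#' The image is resampled to `side` x `side` by bilinear interpolation,
#' mean-subtracted, transformed by the 2-D discrete Fourier transform,
#' center-shifted so the zero-frequency (DC) bin sits at grid position
#' `(side/2 + 1, side/2 + 1)` (1-based), and squared in magnitude.
#' Mean subtraction makes the spectrum a pure texture statistic, independent
#' of overall echogenicity.
#'
#' @param image A [gray_image()].
#' @param side Square grid size; even and at least 8. Default 256, so mask
#'   geometry (radius, bar width) is comparable across variable-size crops.
#' @return An object of class `spectrum`: `power` (side x side non-negative
#'   matrix), `side`, `total_power` (sum over all bins) and `degenerate`
#'   (`TRUE` for a constant input, whose spectrum carries no power).
#' @export
power_spectrum <- function(image, side = 256) {
  stopifnot(inherits(image, "gray_image"))
  if (side < 8 || side %% 2 != 0)
    stop("`side` must be even and at least 8", call. = FALSE)
  px <- resize_bilinear(image$pixels, side, side)
  px <- px - mean(px)
  F <- stats::fft(px)
  pw <- fftshift2(Mod(F)^2)
  tp <- sum(pw)
  structure(
    list(power = pw, side = side, total_power = tp,
         degenerate = tp <= side^2 * 1e-12),
    class = "spectrum"
  )
}

# swap quadrants so the DC bin moves from [1, 1] to [side/2 + 1, side/2 + 1]
fftshift2 <- function(m) {
  s <- nrow(m)
  idx <- c((s / 2 + 1):s, 1:(s / 2))
  m[idx, idx]
}

# bilinear resize of a plain matrix via EBImage (which stores (x, y))
resize_bilinear <- function(px, h, w) {
  if (nrow(px) == h && ncol(px) == w) return(px)
  rng <- range(px)
  scale <- max(rng[2] - rng[1], 1)
  img <- EBImage::Image(t(px - rng[1]) / scale)    # keep within [0,1] for EBImage
  out <- EBImage::resize(img, w = w, h = h, filter = "bilinear")
  t(EBImage::imageData(out)) * scale + rng[1]
}

#' Build a spectral selection mask
#'
#' The five mask shapes select frequency bins around the spectrum center:
#' `circle` (bins within `radius` of the center), `horizontal` and `vertical`
#' (bars of half-width `bar_half_width` along the central row / column),
#' `plus` (union of the two bars) and `circle_plus` (union of circle and
#' plus). Geometry that exceeds the grid is clipped, never an error.
#'
#' @param shape_kind One of `"circle"`, `"horizontal"`, `"vertical"`,
#'   `"plus"`, `"circle_plus"`.
#' @param side Grid size; must match the spectrum the mask will be applied to.
#' @param radius Circle radius in bins (circle family).
#' @param bar_half_width Bar half-width in bins (bar family).
#' @return An object of class `frequency_mask`: `shape_kind`, `side`,
#'   `radius`, `bar_half_width`, and `select` (logical side x side matrix).
#' @export
make_mask <- function(shape_kind, side, radius = NULL, bar_half_width = NULL) {
  shape_kind <- match.arg(shape_kind,
                          c("circle", "horizontal", "vertical", "plus", "circle_plus"))
  stopifnot(side >= 8, side %% 2 == 0)
  need_r <- shape_kind %in% c("circle", "circle_plus")
  need_b <- shape_kind %in% c("horizontal", "vertical", "plus", "circle_plus")
  if (need_r && (is.null(radius) || radius < 0))
    stop("`radius` must be a non-negative number for circle-family masks", call. = FALSE)
  if (need_b && (is.null(bar_half_width) || bar_half_width < 0))
    stop("`bar_half_width` must be a non-negative number for bar-family masks", call. = FALSE)
  ctr <- side / 2 + 1
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  circ <- function() (rows - ctr)^2 + (cols - ctr)^2 <= radius^2
  horiz <- function() abs(rows - ctr) <= bar_half_width
  vert <- function() abs(cols - ctr) <= bar_half_width
  select <- switch(shape_kind,
    circle = circ(),
    horizontal = horiz(),
    vertical = vert(),
    plus = horiz() | vert(),
    circle_plus = circ() | horiz() | vert()
  )
  structure(
    list(shape_kind = shape_kind, side = side,
         radius = radius, bar_half_width = bar_half_width, select = select),
    class = "frequency_mask"
  )
}

#' @export
print.frequency_mask <- function(x, ...) {
  geom <- c(if (!is.null(x$radius)) sprintf("radius %g", x$radius),
            if (!is.null(x$bar_half_width)) sprintf("bar %g", x$bar_half_width))
  cat(sprintf("<frequency_mask %s (%s) on %d grid, %d bins>\n",
              x$shape_kind, paste(geom, collapse = ", "), x$side, sum(x$select)))
  invisible(x)
}

#' Frequency-domain texture score
#'
#' The ratio `P_i / P` of spectral power inside the selected frequency region
#' to the total spectral power. Both sums exclude the zero-frequency bin, so
#' the score is invariant to image brightness and contrast scaling, and lies
#' in `[0, 1]`. Benign thyroid tissue shows a smooth, near-isotropic spectrum;
#' calcified malign nodules shift energy into directional high frequencies,
#' moving the score for masks that cover those directions.
#'
#' @param spectrum A [power_spectrum()] result (not degenerate).
#' @param mask A [make_mask()] result with the same `side`.
#' @return Score in `[0, 1]`.
#' @export
fftscore <- function(spectrum, mask) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(mask, "frequency_mask"))
  if (mask$side != spectrum$side)
    stop("mask and spectrum grid sizes differ", call. = FALSE)
  if (spectrum$degenerate)
    stop("undefined score: spectrum is degenerate (constant image)", call. = FALSE)
  ctr <- spectrum$side / 2 + 1
  pw <- spectrum$power
  dc <- pw[ctr, ctr]
  P <- spectrum$total_power - dc
  if (P <= 0)
    stop("undefined score: no spectral power outside the DC bin", call. = FALSE)
  Pi <- sum(pw[mask$select]) - if (mask$select[ctr, ctr]) dc else 0
  Pi / P
}

#' Calibrate the two-threshold tri-state pre-classifier
#'
#' Learns the score orientation (whether malign cases score high or low) and
#' the pair `(TH_LOW, TH_HIGH)` from training scores. On the oriented scale
#' (malign high), `TH_LOW` is the `alpha`-quantile of malign scores — at most
#' a fraction `alpha` of training malign cases falls below it — and `TH_HIGH`
#' is the `(1 - alpha)`-quantile of benign scores. Scores below `TH_LOW` are
#' called benign outright, above `TH_HIGH` malign outright, and the band in
#' between is the undecided (benign-malign) state handed to the second-stage
#' classifier. If the classes separate (`TH_LOW > TH_HIGH`) both thresholds
#' collapse to their midpoint and the undecided band is empty.
#'
#' @param benign_scores,malign_scores Numeric vectors, at least 2 each.
#' @param alpha Calibration quantile in `[0, 0.5)`. `alpha = 0` guarantees
#'   zero first-stage error on the calibration data itself.
#' @param mask Optional [make_mask()] to carry along with the model.
#' @param side Optional spectrum side to carry along.
#' @return An object of class `threshold_model`: `th_low`, `th_high` (on the
#'   oriented scale), `direction` (+1 if larger raw score means more malign,
#'   -1 otherwise), `alpha`, `mask`, `side`.
#' @export
calibrate_thresholds <- function(benign_scores, malign_scores, alpha = 0,
                                 mask = NULL, side = NULL) {
  if (length(benign_scores) < 2L || length(malign_scores) < 2L)
    stop("calibration needs at least 2 scores per class", call. = FALSE)
  stopifnot(alpha >= 0, alpha < 0.5)
  direction <- if (stats::median(malign_scores) >= stats::median(benign_scores)) 1 else -1
  b <- direction * benign_scores
  m <- direction * malign_scores
  th_low <- unname(stats::quantile(m, alpha, type = 7))
  th_high <- unname(stats::quantile(b, 1 - alpha, type = 7))
  if (th_low > th_high) {
    mid <- (th_low + th_high) / 2
    th_low <- th_high <- mid
  }
  structure(
    list(th_low = th_low, th_high = th_high, direction = direction,
         alpha = alpha, mask = mask, side = side),
    class = "threshold_model"
  )
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model: TH_LOW %.4g, TH_HIGH %.4g, direction %+d, alpha %g%s>\n",
    x$th_low, x$th_high, x$direction, x$alpha,
    if (x$th_low == x$th_high) " (empty undecided band)" else ""))
  invisible(x)
}

#' Tri-state frequency-domain pre-classification
#'
#' Maps a raw fftscore to one of `benign`, `benign_malign` (undecided) or
#' `malign` under a calibrated [calibrate_thresholds()] model. Boundary
#' values fall into the undecided state.
#'
#' @param score Raw score (numeric vector accepted).
#' @param model A `threshold_model`.
#' @return Character vector in `{"benign", "benign_malign", "malign"}`.
#' @export
classify_frequency <- function(score, model) {
  stopifnot(inherits(model, "threshold_model"))
  s <- model$direction * score
  ifelse(s < model$th_low, "benign",
         ifelse(s > model$th_high, "malign", "benign_malign"))
}

#' Rank-based ROC area between two score samples
#'
#' Probability that a randomly chosen positive-class score exceeds a randomly
#' chosen negative-class score, ties counted half (Mann-Whitney statistic).
#'
#' @param pos_scores,neg_scores Numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  stopifnot(np > 0, nn > 0)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Tune the spectral mask geometry on training data
#'
#' Evaluates every candidate mask — the circle family over `radii`, the bar
#' family over `bar_half_widths`, and `circle_plus` over their cross product —
#' by the area under the benign-vs-malign ROC of its fftscores on the training
#' crops, orientation-free (an AUC below 0.5 counts as its mirror image,
#' since the score direction is learned at calibration). Returns the
#' highest-ranked mask; ties break toward the mask with fewer selected bins.
#'
#' @param images List of [gray_image()] tissue crops (or precomputed
#'   `spectrum` objects).
#' @param labels Character vector of `"benign"` / `"malign"`, same length.
#' @param side Spectrum grid size.
#' @param radii Candidate circle radii.
#' @param bar_half_widths Candidate bar half-widths.
#' @return The winning `frequency_mask`, with attributes `auc` (its oriented
#'   ROC area) and `scores` (its raw training scores).
#' @export
tune_mask <- function(images, labels, side = 256,
                      radii = c(8, 16, 24, 32, 48),
                      bar_half_widths = c(1, 2, 4, 8)) {
  stopifnot(length(images) == length(labels))
  if (length(radii) == 0 && length(bar_half_widths) == 0)
    stop("empty candidate grid", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("tuning needs both classes present", call. = FALSE)
  specs <- lapply(images, function(im)
    if (inherits(im, "spectrum")) im else power_spectrum(im, side))
  cands <- c(
    lapply(radii, function(r) make_mask("circle", side, radius = r)),
    lapply(bar_half_widths, function(b) make_mask("horizontal", side, bar_half_width = b)),
    lapply(bar_half_widths, function(b) make_mask("vertical", side, bar_half_width = b)),
    lapply(bar_half_widths, function(b) make_mask("plus", side, bar_half_width = b)),
    unlist(lapply(radii, function(r) lapply(bar_half_widths, function(b)
      make_mask("circle_plus", side, radius = r, bar_half_width = b))),
      recursive = FALSE)
  )
  is_mal <- labels == "malign"
  best <- NULL; best_auc <- -Inf; best_bins <- Inf; best_scores <- NULL
  for (mk in cands) {
    sc <- vapply(specs, fftscore, 0, mask = mk)
    a <- roc_auc(sc[is_mal], sc[!is_mal])
    a <- max(a, 1 - a)
    nb <- sum(mk$select)
    if (a > best_auc || (a == best_auc && nb < best_bins)) {
      best <- mk; best_auc <- a; best_bins <- nb; best_scores <- sc
    }
  }
  attr(best, "auc") <- best_auc
  attr(best, "scores") <- best_scores
  best
}
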