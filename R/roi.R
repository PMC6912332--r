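#' Parameters for thyroid-region extraction
#'
#' @param closing_radius Radius in pixels of the disc structuring element used
#'   for morphological closing of the Otsu foreground before labeling.
#'   Ultrasound speckle fragments the binarized tissue blob; closing makes the
#'   "largest object" well defined. `0` disables closing.
#' @param fill_holes Fill interior holes of the selected component.
#' @param min_area_fraction Fraction of the frame area below which the largest
#'   component is rejected as "no tissue found". Guards against frames that
#'   are all annotation.
#' @return A list of class `roi_params`.
#' @export
roi_params <- function(closing_radius = 5, fill_holes = TRUE,
                       min_area_fraction = 0.05) {
  stopifnot(closing_radius >= 0,
            min_area_fraction >= 0, min_area_fraction < 1)
  structure(list(closing_radius = closing_radius, fill_holes = fill_holes,
                 min_area_fraction = min_area_fraction),
            class = "roi_params")
}

#' Otsu threshold of a grayscale image
#'
#' Computes the integer level in `[0, 255]` that maximizes the between-class
#' variance of the 256-bin intensity histogram, with pixels `< level` in the
#' background class and pixels `>= level` in the foreground class. Ties are
#' broken toward the smallest level.
#'
#' @param image A [gray_image()] with at least two distinct intensity values.
#' @return Integer threshold level.
#' @export
otsu_threshold <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  bins <- pmin(pmax(floor(image$pixels), 0), 255)
  h <- tabulate(as.integer(bins) + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L)
    stop("degenerate input: image has fewer than two distinct intensity levels",
         call. = FALSE)
  p <- h / sum(h)
  lv <- 0:255
  # class 0 = bins < t, class 1 = bins >= t, for candidate levels t = 0..255
  w0 <- c(0, cumsum(p))[1:256]          # P(bin < t)
  m0 <- c(0, cumsum(p * lv))[1:256]     # E[level ; bin < t]
  mt <- sum(p * lv)
  w1 <- 1 - w0
  num <- (mt * w0 - m0)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  as.integer(which.max(sigma_b) - 1L)   # which.max takes the first (smallest) tie
}

# 8-connected labeling: EBImage::bwlabel (4-connected) + merge of labels that
# touch diagonally, via connected components of the label-adjacency graph.
#' Label connected components of a binary mask
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8: diagonal neighbors connect).
#' @return Integer matrix of component labels (0 = background), labels
#'   renumbered 1..n by decreasing component area.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask))))
  lab <- t(lab)
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1L) {
    h <- nrow(lab); w <- ncol(lab)
    # pairs of distinct labels that are diagonal neighbors
    pairs <- rbind(
      cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # SE
      cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))   # NE
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs)) {
      g <- igraph::make_empty_graph(n = nlab, directed = FALSE)
      g <- igraph::add_edges(g, t(unique(pairs)))
      comp <- igraph::components(g)$membership
      lab[lab > 0L] <- comp[lab[lab > 0L]]
    }
  }
  # renumber by decreasing area for convenience
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    ord <- order(areas, decreasing = TRUE)
    remap <- integer(length(areas)); remap[ord] <- seq_along(ord)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Extract the thyroid tissue region from an ultrasound frame
#'
#' Binarizes the frame at the Otsu level (foreground = intensity at or above
#' the level, since the ultrasound background sits near zero), closes the
#' foreground morphologically, labels it with 8-connectivity, keeps the single
#' largest component (area ties broken toward the component whose centroid is
#' nearest the frame center), optionally fills its interior holes, and crops
#' the frame to the component's tight bounding box with off-mask pixels zeroed.
#'
#' @param image A non-constant [gray_image()].
#' @param params A [roi_params()].
#' @return An object of class `roi_result`: `threshold` (Otsu level), `mask`
#'   (logical matrix, frame-sized), `bbox` (named integer vector
#'   `row_min, col_min, row_max, col_max`, 1-based inclusive), and `cropped`
#'   (a [gray_image()] of the bbox extent, off-mask pixels set to 0).
#' @export
extract_roi <- function(image, params = roi_params()) {
  stopifnot(inherits(image, "gray_image"), inherits(params, "roi_params"))
  level <- otsu_threshold(image)
  fg <- image$pixels >= level
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(params$closing_radius) + 1L,
                                shape = "disc")
    fg <- t(EBImage::imageData(
      EBImage::closing(EBImage::Image(t(fg * 1)), brush))) > 0.5
  }
  lab <- label_components(fg, connectivity = 8)
  nlab <- max(lab)
  if (nlab == 0L)
    stop("no tissue found: empty foreground after binarization", call. = FALSE)
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # tie: pick the component whose centroid is nearest the frame center
    ctr <- c((image$height + 1) / 2, (image$width + 1) / 2)
    d2 <- vapply(best, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      sum((colMeans(idx) - ctr)^2)
    }, 0)
    best <- best[which.min(d2)]
  }
  mask <- lab == best
  if (params$fill_holes) {
    mask <- t(EBImage::imageData(
      EBImage::fillHull(EBImage::Image(t(mask * 1))))) > 0.5
  }
  if (sum(mask) < params$min_area_fraction * length(mask))
    stop(sprintf(
      "no tissue found: largest component covers %.1f%% of the frame (< %.1f%%)",
      100 * sum(mask) / length(mask), 100 * params$min_area_fraction),
      call. = FALSE)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  bbox <- c(row_min = rr[1], col_min = cc[1], row_max = rr[2], col_max = cc[2])
  crop_px <- image$pixels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  crop_px[!mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]] <- 0
  structure(
    list(threshold = level, mask = mask, bbox = bbox,
         cropped = gray_image(crop_px, source_path = image$source_path)),
    class = "roi_result"
  )
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("<roi_result: otsu %d, bbox [%d:%d, %d:%d], area %d px>\n",
              x$threshold, x$bbox["row_min"], x$bbox["row_max"],
              x$bbox["col_min"], x$bbox["col_max"], sum(x$mask)))
  invisible(x)
}
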