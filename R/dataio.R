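#' Construct a grayscale image object
#'
#' The unit of all image processing in the package: a height-by-width matrix
#' of float intensities on the 0--255 scale.
#'
#' @param pixels Numeric matrix, rows = image rows (top to bottom), columns =
#'   image columns. All values must be finite and within `[0, 255]`.
#' @param source_path Optional provenance string (file the image came from).
#' @return An object of class `gray_image` with fields `pixels`, `height`,
#'   `width` and `source_path`.
#' @export
gray_image <- function(pixels, source_path = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("image intensities must lie within [0, 255]", call. = FALSE)
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         source_path = source_path),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%.1f, %.1f]%s>\n",
              x$height, x$width, min(x$pixels), max(x$pixels),
              if (is.null(x$source_path)) "" else paste0(", ", x$source_path)))
  invisible(x)
}

# BT.601 luminance weights for RGB -> gray reduction
.bt601 <- c(0.299, 0.587, 0.114)

#' Load an image file as a grayscale image
#'
#' Reads an 8-bit PNG or JPEG raster. Three-channel (RGB) inputs are reduced
#' to one luminance channel with the ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B); intensities are returned as floats on the
#' 0--255 scale. Alpha channels are dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @return A [gray_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image file '%s': no such file", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp")
    stop("BMP input is not supported; convert to PNG or JPEG first", call. = FALSE)
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth
    if (!is.null(depth) && depth > 8L)
      stop(sprintf("unsupported bit depth: %d-bit image (only 8-bit supported)", depth),
           call. = FALSE)
    arr <- raw
  } else {
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e) stop(sprintf(
                      "cannot read image file '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
    # EBImage stores (x, y[, c]); convert to (row, col[, c])
    arr <- EBImage::imageData(img)
    arr <- if (length(dim(arr)) == 2L) t(arr) else aperm(arr, c(2L, 1L, 3L))
  }
  px <- .collapse_channels(arr)
  gray_image(px * 255, source_path = path)
}

# arr: matrix or (h, w, c) array on the [0, 1] scale
.collapse_channels <- function(arr) {
  if (is.matrix(arr)) return(matrix(as.numeric(arr), nrow(arr), ncol(arr)))
  d <- dim(arr)
  px <- if (d[3] <= 2L) {
    arr[, , 1L]                               # gray (+ alpha dropped)
  } else {
    # RGB or RGBA: BT.601 luminance of the first three channels
    .bt601[1] * arr[, , 1L] + .bt601[2] * arr[, , 2L] + .bt601[3] * arr[, , 3L]
  }
  matrix(as.numeric(px), d[1], d[2])          # drop decoder attributes
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param image A [gray_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

.tirads_levels <- c("2", "3", "4a", "4b", "4c", "5")
.tirads_benign <- c("2", "3")

#' Map a TI-RADS score to a benign/malign label
#'
#' TI-RADS (Thyroid Imaging Reporting and Data System) scores 2 and 3 are
#' treated as benign (negative) cases; 4a, 4b, 4c and 5 as malign (positive)
#' cases. Tokens are case-insensitive and whitespace-trimmed.
#'
#' @param tirads Character vector of TI-RADS tokens in
#'   `{2, 3, 4a, 4b, 4c, 5}`.
#' @return Character vector of `"benign"` / `"malign"`.
#' @export
tirads_label <- function(tirads) {
  tok <- tolower(trimws(as.character(tirads)))
  bad <- !(tok %in% .tirads_levels)
  if (any(bad))
    stop(sprintf("unknown TI-RADS token(s): %s",
                 paste(unique(tirads[bad]), collapse = ", ")), call. = FALSE)
  ifelse(tok %in% .tirads_benign, "benign", "malign")
}

#' Read a patient manifest into a cohort
#'
#' The manifest is a UTF-8 CSV with header columns `patient_id`, `image_path`,
#' `tirads` (one row per image; a patient may own several rows) and an
#' optional `split` column with values `train`/`test`. Rows are grouped by
#' patient, labels are derived from the TI-RADS score, and per-class patient
#' counts are populated.
#'
#' @param path Path to the manifest CSV.
#' @return An object of class `cohort`: a list with `records` (one entry per
#'   patient: `patient_id`, `image_paths`, `tirads`, `label`, optional
#'   `split`), `n_benign` and `n_malign` (patient counts).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest '%s' not found", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("patient_id", "image_path", "tirads")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop("manifest is empty: no image rows", call. = FALSE)
  df$tirads <- tolower(trimws(df$tirads))
  bad <- which(!(df$tirads %in% .tirads_levels))
  if (length(bad))
    stop(sprintf("unknown TI-RADS token '%s' at manifest row %d",
                 df$tirads[bad[1]], bad[1]), call. = FALSE)
  has_split <- "split" %in% names(df)
  records <- lapply(split(df, df$patient_id), function(rows) {
    tir <- unique(rows$tirads)
    if (length(tir) > 1L)
      stop(sprintf("patient '%s' has conflicting TI-RADS values: %s",
                   rows$patient_id[1], paste(tir, collapse = ", ")),
           call. = FALSE)
    rec <- list(patient_id = rows$patient_id[1],
                image_paths = rows$image_path,
                tirads = tir,
                label = tirads_label(tir))
    if (has_split) rec$split <- rows$split[1]
    rec
  })
  names(records) <- NULL
  new_cohort(records)
}

new_cohort <- function(records) {
  labels <- vapply(records, `[[`, "", "label")
  structure(
    list(records = records,
         n_benign = sum(labels == "benign"),
         n_malign = sum(labels == "malign")),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  n_img <- sum(vapply(x$records, function(r) length(r$image_paths), 0L))
  cat(sprintf("<cohort: %d patients (%d benign, %d malign), %d images>\n",
              length(x$records), x$n_benign, x$n_malign, n_img))
  invisible(x)
}

#' Write a cohort back to manifest form
#'
#' Inverse of [read_manifest()]: one CSV row per image, carrying the
#' patient's TI-RADS token (and split assignment when present).
#'
#' @param cohort A `cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- do.call(rbind, lapply(cohort$records, function(r) {
    d <- data.frame(patient_id = r$patient_id, image_path = r$image_paths,
                    tirads = r$tirads, stringsAsFactors = FALSE)
    if (!is.null(r$split)) d$split <- r$split
    d
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a cohort to a set of patients
#'
#' @param cohort A `cohort`.
#' @param patient_ids Character vector of patient ids to keep.
#' @return A `cohort` containing only the requested patients, in cohort order.
#' @export
subset_cohort <- function(cohort, patient_ids) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- vapply(cohort$records, `[[`, "", "patient_id")
  unknown <- setdiff(patient_ids, ids)
  if (length(unknown))
    stop(sprintf("unknown patient id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  new_cohort(cohort$records[ids %in% patient_ids])
}

#' Patient ids of a cohort
#' @param cohort A `cohort`.
#' @return Character vector of patient ids in cohort order.
#' @export
cohort_ids <- function(cohort) {
  vapply(cohort$records, `[[`, "", "patient_id")
}
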