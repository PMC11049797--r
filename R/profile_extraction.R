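#' Collapse an RGB image to normalized gray values
#'
#' Averages the red, green and blue channels (unweighted, not
#' luminance-weighted) and normalizes by the bit-depth maximum, giving a
#' matrix of values in `[0, 1]` on an absolute sensor scale. The absolute
#' scale matters: the saturation cutoff used later is meaningful only
#' relative to the sensor maximum, not a per-image maximum.
#'
#' @param img A `bee_image`.
#' @return A `gray_matrix`: a list with `values` (H x W numeric in `[0,1]`)
#'   and `mask` (H x W logical, `TRUE` = excluded; all `FALSE` here).
#' @export
to_gray <- function(img) {
  stopifnot(inherits(img, "bee_image"))
  maxval <- 2^img$bit_depth - 1
  vals <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) /
    (3 * maxval)
  vals <- matrix(vals, nrow = dim(img$pixels)[1])
  structure(list(values = vals,
                 mask = matrix(FALSE, nrow(vals), ncol(vals)),
                 image_id = img$image_id),
            class = "gray_matrix")
}

#' Mask saturated and desaturated pixels
#'
#' Marks for exclusion every pixel whose normalized gray value is strictly
#' above `sat_threshold` (saturated, e.g. specular highlights on the cuticle)
#' or exactly 0 (desaturated). Values are left untouched; masked pixels are
#' simply ignored by [column_medians()].
#'
#' @param gm A `gray_matrix`.
#' @param sat_threshold Saturation cutoff in `(0, 1]`; default 0.95. A value
#'   equal to the threshold is kept (the test is strict).
#' @return The `gray_matrix` with its mask updated.
#' @export
mask_invalid <- function(gm, sat_threshold = 0.95) {
  stopifnot(inherits(gm, "gray_matrix"))
  if (!is.numeric(sat_threshold) || length(sat_threshold) != 1L ||
      sat_threshold <= 0 || sat_threshold > 1) {
    stop("sat_threshold must be in (0, 1]", call. = FALSE)
  }
  gm$mask <- gm$mask | gm$values > sat_threshold | gm$values == 0
  gm
}

#' Per-column medians of unmasked gray values
#'
#' Collapses a gray matrix into a coloration profile: one median per pixel
#' column along the abdomen's long axis. Masked pixels are excluded from the
#' medians; a column whose pixels are all masked yields `NA` (filled later by
#' [equalize_length()]). Even-count medians are the mean of the two middle
#' values (the R default).
#'
#' @param gm A `gray_matrix`.
#' @return A `coloration_profile`: numeric vector of length W (possibly with
#'   `NA` entries) with attribute `specimen_id`.
#' @export
column_medians <- function(gm) {
  stopifnot(inherits(gm, "gray_matrix"))
  v <- gm$values
  v[gm$mask] <- NA_real_
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  if (all(is.na(med))) {
    stop("all columns fully masked for '", gm$image_id, "'", call. = FALSE)
  }
  structure(med, specimen_id = gm$image_id, class = "coloration_profile")
}

#' Equalize a profile to a fixed length
#'
#' Abdomens vary in pixel length, so raw profiles differ in width. This fills
#' missing entries (fully masked columns) by linear interpolation between the
#' nearest non-missing neighbors (leading/trailing gaps take the nearest
#' value), then resamples the profile to `L` points by linear interpolation
#' over normalized position in `[0, 1]`. A complete profile already of length
#' `L` is returned unchanged.
#'
#' @param p A `coloration_profile` (or plain numeric vector) with at least 2
#'   non-missing entries.
#' @param L Target length; default 1998 (the longest abdomen in the original
#'   study; new datasets should choose their own).
#' @return A numeric vector of length `L` with no missing entries, attribute
#'   `specimen_id` preserved, class `fixed_profile`.
#' @export
equalize_length <- function(p, L = 1998L) {
  vals <- as.numeric(p)
  L <- as.integer(L)
  if (L < 2L) stop("target length L must be >= 2", call. = FALSE)
  ok <- !is.na(vals)
  if (sum(ok) < 2L) {
    stop("profile needs at least 2 non-missing entries", call. = FALSE)
  }
  n_filled <- sum(!ok)
  if (n_filled > 0L) {
    idx <- seq_along(vals)
    vals <- stats::approx(idx[ok], vals[ok], xout = idx,
                          method = "linear", rule = 2)$y
    warning(sprintf("filled %d fully masked column(s) by interpolation%s",
                    n_filled,
                    if (!is.null(attr(p, "specimen_id")))
                      paste0(" for '", attr(p, "specimen_id"), "'") else ""),
            call. = FALSE)
  }
  if (length(vals) != L) {
    pos <- seq(0, 1, length.out = length(vals))
    vals <- stats::approx(pos, vals, xout = seq(0, 1, length.out = L),
                          method = "linear")$y
  }
  structure(vals, specimen_id = attr(p, "specimen_id"),
            n_filled_columns = n_filled, class = "fixed_profile")
}

#' Extract a fixed-length coloration profile from an image
#'
#' Full single-specimen pipeline: crop the ROI, average RGB to gray,
#' mask saturated/desaturated pixels, take per-column medians, and equalize
#' the profile length. If more than `max_masked_fraction` of columns are
#' fully masked the specimen is rejected (heavy specular reflection can
#' saturate the sensor over whole regions, leaving too little signal).
#'
#' @param img A `bee_image`.
#' @param roi An `roi_rect` for that image; defaults to the full frame.
#' @param L Target profile length (default 1998).
#' @param sat_threshold Saturation cutoff (default 0.95).
#' @param max_masked_fraction Reject the specimen when the fraction of fully
#'   masked columns exceeds this (default 0.5).
#' @return A `fixed_profile` of length `L`.
#' @export
extract_profile <- function(img, roi = NULL, L = 1998L, sat_threshold = 0.95,
                            max_masked_fraction = 0.5) {
  stopifnot(inherits(img, "bee_image"))
  if (is.null(roi)) {
    d <- dim(img$pixels)
    roi <- roi_rect(img$image_id, 0L, 0L, d[2], d[1])
  }
  cropped <- crop_roi(img, roi)
  gm <- mask_invalid(to_gray(cropped), sat_threshold)
  prof <- column_medians(gm)
  frac_masked <- mean(is.na(prof))
  if (frac_masked > max_masked_fraction) {
    stop(sprintf("specimen '%s' rejected: %.0f%% of columns fully masked",
                 img$image_id, 100 * frac_masked), call. = FALSE)
  }
  equalize_length(prof, L)
}

#' Extract profiles for a directory of images
#'
#' @param image_dir Directory containing the specimen images.
#' @param roi_table Named list of `roi_rect` from [read_roi_table()], or
#'   `NULL` to use full-frame ROIs.
#' @param L,sat_threshold,max_masked_fraction Passed to [extract_profile()].
#' @return A numeric matrix, one row per specimen (rownames = specimen ids),
#'   `L` columns.
#' @export
extract_profiles <- function(image_dir, roi_table = NULL, L = 1998L,
                             sat_threshold = 0.95, max_masked_fraction = 0.5) {
  files <- list.files(image_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files)) stop("no images found in ", image_dir, call. = FALSE)
  out <- matrix(NA_real_, nrow = length(files), ncol = L)
  ids <- character(length(files))
  for (i in seq_along(files)) {
    img <- read_image(files[i])
    roi <- if (!is.null(roi_table)) {
      if (is.null(roi_table[[img$image_id]])) {
        stop("no ROI for image '", img$image_id, "'", call. = FALSE)
      }
      roi_table[[img$image_id]]
    } else NULL
    out[i, ] <- extract_profile(img, roi, L = L, sat_threshold = sat_threshold,
                                max_masked_fraction = max_masked_fraction)
    ids[i] <- img$image_id
  }
  rownames(out) <- ids
  out
}

#' Write / read a profile matrix as CSV
#'
#' One row per specimen: `specimen_id, v0001 ... v<L>` (column count follows
#' the profile length).
#'
#' @param profiles Numeric matrix with specimen ids as rownames.
#' @param path CSV path.
#' @return `path` invisibly (write); the profile matrix (read).
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  df <- data.frame(specimen_id = rownames(profiles), profiles,
                   check.names = FALSE, row.names = NULL)
  names(df)[-1] <- sprintf("v%04d", seq_len(ncol(profiles)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "specimen_id") {
    stop("profile CSV must start with a specimen_id column", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$specimen_id
  colnames(m) <- NULL
  m
}
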