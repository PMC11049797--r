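#' Read an RGB image
#'
#' Reads a PNG, TIFF or JPEG file into a `bee_image` object. Only 3-channel
#' (RGB) images are accepted: the downstream profile extraction averages the
#' three color channels, so grayscale or RGBA inputs are rejected rather than
#' silently coerced.
#'
#' @param path Path to an image file (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @return A `bee_image`: a list with `pixels` (H x W x 3 integer array),
#'   `bit_depth` (8 or 16) and `image_id` (the file stem).
#' @details Pixel values are stored as integers on the native sensor scale,
#'   i.e. in `[0, 2^bit_depth - 1]`. JPEG is accepted on read for convenience
#'   but is lossy; analyses intended to be reproducible should use PNG or TIFF.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    bit_depth <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(raw)
    bit_depth <- if (!is.null(info$bits.per.sample)) {
      as.integer(info$bits.per.sample[1])
    } else 8L
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("reading JPEG requires the 'jpeg' package: ", path, call. = FALSE)
    }
    raw <- jpeg::readJPEG(path)
    bit_depth <- 8L
  } else {
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  }
  if (length(dim(raw)) != 3L || dim(raw)[3] != 3L) {
    nch <- if (length(dim(raw)) == 3L) dim(raw)[3] else 1L
    stop("expected 3 channels, got ", nch, ": ", path, call. = FALSE)
  }
  maxval <- 2^bit_depth - 1
  pixels <- array(as.integer(round(raw * maxval)), dim = dim(raw))
  new_bee_image(pixels, bit_depth, image_id = tools::file_path_sans_ext(basename(path)))
}

new_bee_image <- function(pixels, bit_depth, image_id) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            bit_depth %in% c(8L, 16L))
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         image_id = as.character(image_id)),
    class = "bee_image"
  )
}

#' @export
print.bee_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<bee_image '%s': %d x %d px, %d-bit RGB>\n",
              x$image_id, d[1], d[2], x$bit_depth))
  invisible(x)
}

#' @export
dim.bee_image <- function(x) dim(x$pixels)

#' Write an image losslessly
#'
#' Writes a `bee_image` to PNG (8-bit) or TIFF (8- or 16-bit). Round-trips
#' through these formats are pixel-exact.
#'
#' @param img A `bee_image`.
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "bee_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- img$pixels / (2^img$bit_depth - 1)
  if (ext == "png") {
    if (img$bit_depth != 8L) {
      stop("PNG output supports 8-bit only; use TIFF for 16-bit", call. = FALSE)
    }
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = img$bit_depth)
  } else {
    stop("unsupported output format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Construct a rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the ROI covers columns
#' `[x0, x1)` and rows `[y0, y1)`. The x-axis is the abdomen's long axis
#' (anterior to posterior), so the extracted profile has exactly `x1 - x0`
#' entries.
#'
#' @param image_id Identifier matching the image the ROI belongs to.
#' @param x0,y0,x1,y1 Integer pixel bounds, `0 <= x0 < x1`, `0 <= y0 < y1`.
#' @return An `roi_rect` object.
#' @export
roi_rect <- function(image_id, x0, y0, x1, y1) {
  co <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(is.na(co)) || any(co != trunc(co))) {
    stop("ROI coordinates must be integers", call. = FALSE)
  }
  co <- stats::setNames(as.integer(co), names(co))
  if (co["x0"] < 0L || co["y0"] < 0L) {
    stop("ROI coordinates must be non-negative", call. = FALSE)
  }
  if (co["x0"] >= co["x1"]) stop("ROI requires x0 < x1", call. = FALSE)
  if (co["y0"] >= co["y1"]) stop("ROI requires y0 < y1", call. = FALSE)
  structure(list(image_id = as.character(image_id),
                 x0 = co[["x0"]], y0 = co[["y0"]],
                 x1 = co[["x1"]], y1 = co[["y1"]]),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect '%s': [%d,%d) x [%d,%d)>\n",
              x$image_id, x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

#' Crop a region of interest out of an image
#'
#' @param img A `bee_image`.
#' @param roi An `roi_rect` whose `image_id` matches `img` and whose bounds
#'   lie within the image.
#' @return A new `bee_image` of dimensions `(y1-y0) x (x1-x0)`; pixels are
#'   copied, not aliased.
#' @export
crop_roi <- function(img, roi) {
  stopifnot(inherits(img, "bee_image"), inherits(roi, "roi_rect"))
  if (!identical(roi$image_id, img$image_id)) {
    stop("ROI image_id '", roi$image_id, "' does not match image '",
         img$image_id, "'", call. = FALSE)
  }
  d <- dim(img$pixels)
  if (roi$x1 > d[2] || roi$y1 > d[1]) {
    stop("ROI out of bounds for image '", img$image_id, "' (",
         d[1], " x ", d[2], " px)", call. = FALSE)
  }
  sub <- img$pixels[(roi$y0 + 1L):roi$y1, (roi$x0 + 1L):roi$x1, , drop = FALSE]
  new_bee_image(sub, img$bit_depth, img$image_id)
}

#' Read a table of ROIs from CSV
#'
#' The CSV must have columns `image_id,x0,y0,x1,y1` with 0-based half-open
#' pixel coordinates. Exactly one ROI per image is allowed: the protocol uses
#' a single left-half-abdomen rectangle per specimen, so duplicate
#' `image_id` rows are an error.
#'
#' @param path Path to the CSV file.
#' @return A named list of `roi_rect` objects (names = image ids); empty list
#'   for a header-only file.
#' @export
read_roi_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("image_id", "x0", "y0", "x1", "y1")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("ROI table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(structure(list(), names = character()))
  if (anyDuplicated(tab$image_id)) {
    dup <- unique(tab$image_id[duplicated(tab$image_id)])
    stop("multiple ROI rows for image(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rois <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    rois[[i]] <- tryCatch(
      roi_rect(tab$image_id[i], tab$x0[i], tab$y0[i], tab$x1[i], tab$y1[i]),
      error = function(e) {
        stop("invalid ROI in row ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }
  names(rois) <- tab$image_id
  rois
}
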