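#' Grayscale image container
#'
#' A `gray_image` is a plain numeric matrix of finite intensities addressed as
#' `(row, col)` with 0-based coordinates and pixel centers at integer
#' positions, optionally carrying a physical pixel spacing. All geometry in
#' the package is expressed in pixels; spacing is only used to report scores
#' in millimeters alongside the pixel value when it is known.
#'
#' @param pixels numeric matrix, at least 2 x 2, all values finite.
#' @param spacing optional numeric `c(row_mm, col_mm)`, strictly positive.
#'
#' @return A `gray_image` object (numeric matrix with class and attributes).
#' @export
#' @examples
#' img <- gray_image(matrix(0, 16, 16))
#' dim(img)
gray_image <- function(pixels, spacing = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_pms("`pixels` must be a numeric matrix", "image")
  }
  if (nrow(pixels) < 2 || ncol(pixels) < 2) {
    stop_pms("image must be at least 2 x 2 pixels", "image")
  }
  if (!all(is.finite(pixels))) {
    stop_pms("image intensities must all be finite", "image")
  }
  if (!is.null(spacing)) {
    if (length(spacing) != 2L || !all(is.finite(spacing)) || any(spacing <= 0)) {
      stop_pms("`spacing` must be two strictly positive numbers (row_mm, col_mm)", "image")
    }
    spacing <- as.numeric(spacing)
  }
  structure(unclass(pixels), spacing = spacing, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  sp <- attr(x, "spacing")
  cat(sprintf("<gray_image %d x %d px%s>\n", nrow(x), ncol(x),
              if (is.null(sp)) "" else sprintf(", spacing %.4g x %.4g mm", sp[1], sp[2])))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

image_spacing <- function(image) attr(image, "spacing")

#' Rectangular region of interest
#'
#' An `roi_box` selects the half-open pixel block
#' `[top, top + height) x [left, left + width)` of an image, in 0-based
#' coordinates. Boxes are deliberately rigid: within one study every box must
#' share a single `(height, width)` so that margin scores from different
#' regions are comparable.
#'
#' @param top,left 0-based row/column of the first included pixel.
#' @param height,width box extent in pixels, each at least 8.
#' @param label optional region label, `"tumor"` or `"healthy"`.
#'
#' @return An `roi_box` object.
#' @export
#' @examples
#' roi_box(10, 20, 40, 40, label = "tumor")
roi_box <- function(top, left, height, width, label = NA_character_) {
  vals <- c(top = top, left = left, height = height, width = width)
  if (!all(vapply(vals, is_scalar_number, logical(1))) || any(vals != round(vals))) {
    stop_pms("roi_box fields must be single integers", "roi")
  }
  if (top < 0 || left < 0) stop_pms("roi_box top/left must be non-negative", "roi")
  if (height < 8 || width < 8) stop_pms("roi_box must be at least 8 x 8 pixels", "roi")
  if (!is.na(label) && !label %in% c("tumor", "healthy")) {
    stop_pms("roi label must be 'tumor' or 'healthy'", "roi")
  }
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width),
                 label = label),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box %d x %d at (%d, %d)%s>\n", x$height, x$width, x$top, x$left,
              if (is.na(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' Parse an ROI given as "top,left,height,width"
#'
#' @param text character scalar such as `"10,20,40,40"`.
#' @param label optional region label passed to [roi_box()].
#' @return An [roi_box()].
#' @export
parse_roi <- function(text, label = NA_character_) {
  parts <- suppressWarnings(as.numeric(strsplit(trimws(text), ",")[[1]]))
  if (length(parts) != 4L || anyNA(parts)) {
    stop_pms(sprintf("cannot parse ROI '%s'; expected 'top,left,height,width'", text), "roi")
  }
  roi_box(parts[1], parts[2], parts[3], parts[4], label = label)
}

format_roi <- function(roi) {
  paste(roi$top, roi$left, roi$height, roi$width, sep = ",")
}

validate_roi_in_image <- function(roi, image) {
  nr <- nrow(image); nc <- ncol(image)
  if (roi$top + roi$height > nr) {
    stop_pms(sprintf("ROI bottom edge %d exceeds image height %d",
                     roi$top + roi$height, nr), "roi")
  }
  if (roi$left + roi$width > nc) {
    stop_pms(sprintf("ROI right edge %d exceeds image width %d",
                     roi$left + roi$width, nc), "roi")
  }
  invisible(roi)
}

#' Crop an image to a region of interest
#'
#' Pixel `(r, c)` of the crop equals pixel `(top + r, left + c)` of the
#' source; pixel spacing is propagated.
#'
#' @param image a [gray_image()].
#' @param roi an [roi_box()] lying entirely inside `image`.
#' @return A [gray_image()] of shape `(height, width)`.
#' @export
#' @examples
#' img <- gray_image(outer(0:63, 0:63, `+`))
#' crop(img, roi_box(10, 20, 40, 40))[1, 1]  # 30
crop <- function(image, roi) {
  stopifnot(inherits(image, "gray_image"), inherits(roi, "roi_box"))
  validate_roi_in_image(roi, image)
  px <- unclass(image)[roi$top + seq_len(roi$height), roi$left + seq_len(roi$width), drop = FALSE]
  gray_image(px, spacing = image_spacing(image))
}

#' Read a grayscale image from disk
#'
#' Supports 8/16-bit grayscale PNG and TIFF. PNG intensities are returned on
#' the 0..255 scale; TIFF is read at its stored integer values (16-bit TIFFs
#' written by [write_image()] round-trip exactly). Color images are rejected
#' rather than silently converted: CT-like data is single-channel and a
#' silent luminance conversion would hide mistakes.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return A [gray_image()]; spacing is absent for these formats.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop_pms(sprintf("image file not found: %s", path), "io")
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    stop_pms(sprintf("unsupported image format '.%s' (use PNG or TIFF): %s", ext, path), "io")
  )
  if (length(dim(px)) == 3L) {
    stop_pms(sprintf("color or multi-channel image rejected (single-channel grayscale required): %s",
                     path), "io")
  }
  gray_image(px)
}

#' Write a grayscale image to disk
#'
#' TIFF output is 16-bit (integer intensities in 0..65535 round-trip
#' exactly); PNG output is 8-bit (intensities clamped to 0..255).
#'
#' @param image a [gray_image()].
#' @param path destination ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  ext <- tolower(tools::file_ext(path))
  px <- unclass(image)
  if (ext == "png") {
    png::writePNG(pmin(pmax(px, 0), 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(px, 0), 65535) / 65535, path, bits.per.sample = 16L)
  } else {
    stop_pms(sprintf("unsupported image format '.%s' (use PNG or TIFF): %s", ext, path), "io")
  }
  invisible(path)
}

#' Load and validate a paired-ROI manifest
#'
#' The manifest is a CSV with columns `patient_id`, `image_path`,
#' `roi_tumor`, `roi_healthy` (each ROI as `"top,left,height,width"`), and
#' optionally `true_rms_tumor`, `true_rms_healthy`, `seed` (carried through
#' when present, e.g. from the phantom generator). Image paths are resolved
#' relative to the manifest's directory. Every ROI is validated against its
#' image, and all boxes in one manifest must share one `(height, width)` —
#' the boxes are kept constant in size across images and patients.
#'
#' @param path path to the manifest CSV.
#' @return A tibble with one row per patient: `patient_id`, `image_path`
#'   (resolved), `roi_tumor`, `roi_healthy` (list-columns of [roi_box()]),
#'   plus any passthrough columns.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop_pms(sprintf("manifest not found: %s", path), "io")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(patient_id = "c", image_path = "c",
                                                roi_tumor = "c", roi_healthy = "c"))
  if (nrow(df) == 0L) stop_pms("manifest is empty", "manifest")
  need <- c("patient_id", "image_path", "roi_tumor", "roi_healthy")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_pms(paste0("manifest missing columns: ", paste(missing, collapse = ", ")), "manifest")
  }
  base <- dirname(normalizePath(path))
  df$image_path <- ifelse(grepl("^(/|[A-Za-z]:)", df$image_path),
                          df$image_path, file.path(base, df$image_path))
  rois_t <- purrr::map(df$roi_tumor, parse_roi, label = "tumor")
  rois_h <- purrr::map(df$roi_healthy, parse_roi, label = "healthy")

  sizes <- unique(do.call(rbind, purrr::map(c(rois_t, rois_h),
                                            function(r) c(r$height, r$width))))
  if (nrow(sizes) > 1L) {
    stop_pms(paste0("ROI boxes must be kept constant in size within a manifest; found ",
                    paste(apply(sizes, 1, paste, collapse = "x"), collapse = ", ")),
             "manifest")
  }
  for (i in seq_len(nrow(df))) {
    p <- df$image_path[i]
    if (!file.exists(p)) {
      stop_pms(sprintf("manifest row %d: image file not found: %s", i, p), "manifest")
    }
    img <- load_image(p)
    for (roi in list(rois_t[[i]], rois_h[[i]])) {
      tryCatch(validate_roi_in_image(roi, img), pmscore_error = function(e) {
        stop_pms(sprintf("manifest row %d (%s): %s", i, df$patient_id[i],
                         conditionMessage(e)), "manifest")
      })
    }
  }
  out <- tibble::as_tibble(df)
  out$roi_tumor <- rois_t
  out$roi_healthy <- rois_h
  out
}
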