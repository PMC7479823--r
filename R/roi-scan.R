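# RoiScan: one examination's 2D gray-level image plus binary lesion mask.

#' Construct a ROI scan
#'
#' @param image numeric matrix of gray levels (arbitrary units), indexed
#'   `[row, col]`, origin top-left, 0-based pixel coordinates in all
#'   derived geometry.
#' @param mask logical or 0/1 matrix, same shape; any nonzero pixel is
#'   foreground.
#' @param spacing mm per pixel as `(row, col)`; both > 0.
#' @param examination `"pre"` (baseline) or `"post"` (after cycle 1).
#' @return an object of class `roi_scan`.
#' @export
roi_scan <- function(image, mask, spacing = c(1, 1),
                     examination = c("pre", "post")) {
  examination <- match.arg(examination)
  if (!is.matrix(image) || !is.numeric(image))
    rader_abort("`image` must be a numeric matrix", "alignment")
  if (!is.matrix(mask))
    rader_abort("`mask` must be a matrix", "alignment")
  if (!all(dim(image) == dim(mask)))
    rader_abort(sprintf("image (%dx%d) and mask (%dx%d) shapes differ",
                        nrow(image), ncol(image), nrow(mask), ncol(mask)),
                "alignment")
  mask <- matrix(as.logical(mask != 0), nrow(mask), ncol(mask))
  if (!any(mask))
    rader_abort("mask has no foreground pixels (empty ROI)", "empty_roi")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    rader_abort("`spacing` must be two positive numbers (row, col)", "alignment")
  structure(list(image = image, mask = mask, spacing = spacing,
                 examination = examination),
            class = "roi_scan")
}

#' @export
print.roi_scan <- function(x, ...) {
  cat(sprintf("<roi_scan %s> %dx%d px, %d in ROI, spacing %.3g x %.3g mm\n",
              x$examination, nrow(x$image), ncol(x$image), sum(x$mask),
              x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' Read an image/mask pair into a ROI scan
#'
#' Formats are chosen by extension: `.nrrd`, `.nii`, `.pgm`. A 3D mask
#' (multi-slice delineation) is reduced to its largest-area slice with a
#' warning; the analysis is single-slice by design. Spacing is taken
#' from the image header (1 mm when the format carries none); the mask
#' must be grid-aligned with the image.
#'
#' @param image_path path to the gray-level image.
#' @param mask_path path to the mask; any nonzero value is foreground.
#' @param examination `"pre"` or `"post"`.
#' @return a [roi_scan()].
#' @export
read_roi_scan <- function(image_path, mask_path, examination = "pre") {
  img <- read_image_any(image_path)
  msk <- read_image_any(mask_path)
  reduce <- function(obj, other_areas = NULL) obj
  pick_slice <- function(arr) {
    areas <- apply(arr != 0, 3, sum)
    k <- which.max(areas)
    warning(sprintf("multi-slice input reduced to largest-area slice %d (%d px)",
                    k, areas[k]), call. = FALSE)
    arr[, , k]
  }
  if (length(dim(msk$data)) == 3L) {
    k_areas <- apply(msk$data != 0, 3, sum)
    k <- which.max(k_areas)
    warning(sprintf("multi-slice mask reduced to largest-area slice %d (%d px)",
                    k, k_areas[k]), call. = FALSE)
    msk$data <- msk$data[, , k]
    if (length(dim(img$data)) == 3L) img$data <- img$data[, , k]
  } else if (length(dim(img$data)) == 3L) {
    img$data <- pick_slice(img$data)
  }
  roi_scan(img$data, msk$data, spacing = img$spacing,
           examination = examination)
}

masked_values <- function(scan) scan$image[scan$mask]
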