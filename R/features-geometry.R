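# Shape features of the lesion mask (single-slice; "volume" names follow
# the field's convention for these 2D quantities, in mm^2).

#' Geometry features of a ROI mask
#'
#' * `volume` - foreground pixel count x pixel area (mm^2).
#' * `major_diameter`, `minor_diameter` - full axis lengths (mm) of the
#'   ellipse whose second central moments match the mask's; pixel extent
#'   enters via the standard +h^2/12 continuous correction, so a filled
#'   w x h rectangle recovers its closed-form moments exactly.
#' * `eccentricity` - `sqrt(1 - (minor/major)^2)`.
#' * `elongation` - `minor/major`.
#' * `orientation` - major-axis angle in degrees in (-90, 90], measured
#'   from the +column axis, counter-clockwise with rows pointing down.
#' * `bounding_box_volume` - axis-aligned bounding-box area (mm^2).
#' * `perimeter` - crack length of the mask boundary: total length of
#'   exposed pixel edges (mm); exact for axis-aligned rectangles.
#'
#' @param scan a [roi_scan()].
#' @return named numeric vector of 8 features.
#' @export
geometry_features <- function(scan) {
  idx <- which(scan$mask, arr.ind = TRUE)
  sr <- scan$spacing[1]; sc <- scan$spacing[2]
  y <- (idx[, 1] - 1) * sr   # physical row coordinate (mm)
  x <- (idx[, 2] - 1) * sc
  n <- nrow(idx)
  mx <- mean(x); my <- mean(y)
  # population covariance + pixel-extent correction
  cxx <- mean((x - mx)^2) + sc^2 / 12
  cyy <- mean((y - my)^2) + sr^2 / 12
  cxy <- mean((x - mx) * (y - my))
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  # orientation in the (x, -y) frame so positive angles are CCW on screen
  theta <- 0.5 * atan2(2 * -cxy, cxx - cyy) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  ratio <- if (major > 0) minor / major else 1
  bbox <- (diff(range(idx[, 1])) + 1) * sr * (diff(range(idx[, 2])) + 1) * sc
  c(volume = n * sr * sc,
    major_diameter = major,
    minor_diameter = minor,
    eccentricity = sqrt(max(1 - ratio^2, 0)),
    elongation = ratio,
    orientation = theta,
    bounding_box_volume = bbox,
    perimeter = mask_crack_perimeter(scan$mask, sr, sc))
}

# total length of foreground pixel edges not shared with another
# foreground pixel
mask_crack_perimeter <- function(mask, sr, sc) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  up    <- core & !pad[1:nr, 2:(nc + 1)]
  down  <- core & !pad[3:(nr + 2), 2:(nc + 1)]
  left  <- core & !pad[2:(nr + 1), 1:nc]
  right <- core & !pad[2:(nr + 1), 3:(nc + 2)]
  (sum(up) + sum(down)) * sc + (sum(left) + sum(right)) * sr
}
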