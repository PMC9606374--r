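#' In-fill the imager's logo block
#'
#' Replaces the pixels inside the given rectangle by the per-channel
#' median colour of a 2-pixel border ring around it, leaving all other
#' pixels unchanged. Median in-fill avoids introducing spurious texture
#' that a constant block or interpolation could create.
#'
#' @param rgb H x W x 3 array in [0, 255].
#' @param logoRect integer vector (x0, y0, w, h): 1-based top-left
#'   column and row, width and height. Zero area returns the image
#'   unchanged; \code{NULL} is treated as zero area.
#' @return the in-filled raster.
#' @export
removeLogo <- function(rgb, logoRect) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be H x W x 3")
  if (is.null(logoRect)) return(rgb)
  stopifnot(length(logoRect) == 4)
  x0 <- logoRect[1]; y0 <- logoRect[2]; w <- logoRect[3]; h <- logoRect[4]
  if (w == 0 || h == 0) return(rgb)
  if (x0 < 1 || y0 < 1 || x0 + w - 1 > d[2] || y0 + h - 1 > d[1])
    stop("logo rectangle lies outside the image bounds")
  rows <- y0:(y0 + h - 1); cols <- x0:(x0 + w - 1)
  ringRows <- max(1, y0 - 2):min(d[1], y0 + h + 1)
  ringCols <- max(1, x0 - 2):min(d[2], x0 + w + 1)
  inRect <- outer(ringRows %in% rows, ringCols %in% cols, "&")
  for (ch in 1:3) {
    ring <- rgb[ringRows, ringCols, ch][!inRect]
    if (length(ring)) rgb[rows, cols, ch] <- median(ring)
  }
  rgb
}

#' Convert a pseudo-colour raster to greyscale
#'
#' Two modes: \code{"luminance"} computes the Rec. 709 luminance
#' 0.2126 R + 0.7152 G + 0.0722 B rescaled to [0, 1];
#' \code{"colormap_inverse"} inverts a declared monotone pseudo-colour
#' map by nearest-neighbour palette lookup, recovering the latent grey
#' field up to 8-bit quantization (the preferred mode when the palette
#' is known, since it undoes the map's non-linearity exactly).
#'
#' @param rgb H x W x 3 array in [0, 255].
#' @param mode \code{"colormap_inverse"} or \code{"luminance"}.
#' @param colormap palette name for the inverse mode.
#' @return H x W numeric matrix in [0, 1].
#' @export
rgbToGrey <- function(rgb, mode = c("colormap_inverse", "luminance"),
                      colormap = "iron") {
  mode <- match.arg(mode)
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be H x W x 3")
  if (mode == "luminance") {
    (0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]) / 255
  } else {
    invertColormap(rgb, colormap)
  }
}

#' Min-max normalise a grey image
#'
#' Rescales to [0, 1] via (g - min) / (max - min); the output min is
#' exactly 0 and max exactly 1. A constant image returns all zeros with
#' a warning (its downstream GLCM then collapses to the constant-image
#' feature values).
#'
#' @param grey H x W numeric matrix.
#' @return normalised matrix.
#' @export
normaliseImage <- function(grey) {
  stopifnot(is.matrix(grey), all(is.finite(grey)))
  rng <- range(grey)
  if (rng[1] == rng[2]) {
    warning("constant image: normalisation returns all zeros")
    return(matrix(0, nrow(grey), ncol(grey)))
  }
  (grey - rng[1]) / (rng[2] - rng[1])
}

#' Segment the wound bed and enhance the mask
#'
#' Thresholds the grey image (Otsu's criterion by default, or a fixed
#' value), keeps pixels at or above the threshold, fills interior
#' holes, erodes with a disk structuring element, and retains the
#' largest connected component only. The result contains no interior
#' holes and exactly one component.
#'
#' @param grey H x W matrix in [0, 1].
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold threshold in [0, 1] when \code{method = "fixed"}.
#' @param erosionRadius disk radius in pixels (>= 0; default 2, small
#'   enough to preserve small wound beds).
#' @return H x W binary matrix (0/1).
#' @export
computeMask <- function(grey, method = c("otsu", "fixed"),
                        threshold = NULL, erosionRadius = 2L) {
  method <- match.arg(method)
  stopifnot(is.matrix(grey), erosionRadius >= 0)
  t <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(grey), range = c(0, 1))
  } else {
    if (is.null(threshold)) stop("fixed method requires a threshold")
    threshold
  }
  mask <- (grey >= t) + 0
  if (sum(mask) == 0)
    stop("empty mask after thresholding; lower the threshold")
  mask <- as.matrix(EBImage::fillHull(mask))
  if (erosionRadius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(erosionRadius) + 1L,
                                shape = "disc")
    mask <- as.matrix(EBImage::erode(mask, brush))
  }
  if (sum(mask) == 0)
    stop("mask empty after erosion; use a smaller erosionRadius ",
         "or a different threshold")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) + 0
}

#' Pair a grey image with its enhanced mask
#'
#' Background pixels are excluded from analysis rather than zero-filled,
#' so co-occurrence counting never pairs a wound pixel with a fabricated
#' background value.
#'
#' @param grey H x W matrix in [0, 1].
#' @param mask H x W binary matrix; must be non-empty.
#' @return a \code{\linkS4class{WoundBed}}.
#' @export
extractWoundBed <- function(grey, mask) {
  if (sum(mask) < 1) stop("mask is empty")
  new("WoundBed", grey = grey, mask = mask + 0)
}

#' Preprocessing configuration
#'
#' Bundles the stage parameters of the image-preparation chain: logo
#' in-fill rectangle, greyscale conversion mode, threshold rule and
#' morphology radius.
#'
#' @param logoRect rectangle passed to \code{\link{removeLogo}}, or
#'   \code{NULL} to skip in-fill.
#' @param greyMode,colormap see \code{\link{rgbToGrey}}.
#' @param maskMethod,threshold,erosionRadius see
#'   \code{\link{computeMask}}.
#' @return a named list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(logoRect = c(6L, 6L, 40L, 12L),
                             greyMode = "colormap_inverse",
                             colormap = "iron",
                             maskMethod = "otsu", threshold = NULL,
                             erosionRadius = 2L) {
  structure(list(logoRect = logoRect, greyMode = greyMode,
                 colormap = colormap, maskMethod = maskMethod,
                 threshold = threshold, erosionRadius = erosionRadius),
            class = "PreprocessConfig")
}

#' Run the full preprocessing chain on one image
#'
#' logo in-fill, greyscale conversion, min-max normalisation, mask
#' computation and wound-bed extraction.
#'
#' @param image a \code{\linkS4class{ThermalImage}}.
#' @param config a \code{\link{preprocessConfig}} list.
#' @return a \code{\linkS4class{WoundBed}}.
#' @export
preprocessImage <- function(image, config = preprocessConfig()) {
  rgb <- removeLogo(rgbRaster(image), config$logoRect)
  grey <- rgbToGrey(rgb, config$greyMode, config$colormap)
  grey <- normaliseImage(grey)
  mask <- computeMask(grey, config$maskMethod, config$threshold,
                      config$erosionRadius)
  extractWoundBed(grey, mask)
}

#' Write the four preprocessing stages as debug PNGs
#'
#' Saves raw, normalised, mask and masked images for visual QA.
#'
#' @param image a \code{\linkS4class{ThermalImage}}.
#' @param dir output directory.
#' @param config a \code{\link{preprocessConfig}} list.
#' @param prefix filename prefix.
#' @return the output paths, invisibly.
#' @export
writePreprocessStages <- function(image, dir,
                                  config = preprocessConfig(),
                                  prefix = "stage") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rgb <- removeLogo(rgbRaster(image), config$logoRect)
  grey <- normaliseImage(rgbToGrey(rgb, config$greyMode,
                                   config$colormap))
  mask <- computeMask(grey, config$maskMethod, config$threshold,
                      config$erosionRadius)
  masked <- grey * mask
  paths <- file.path(dir, paste0(prefix, "_",
    c("raw", "normalised", "mask", "masked"), ".png"))
  EBImage::writeImage(EBImage::Image(aperm(rgb, c(2, 1, 3)) / 255,
                                     colormode = "Color"), paths[1])
  EBImage::writeImage(EBImage::Image(t(grey)), paths[2])
  EBImage::writeImage(EBImage::Image(t(mask)), paths[3])
  EBImage::writeImage(EBImage::Image(t(masked)), paths[4])
  invisible(paths)
}
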