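#' Parameters of the synthetic thermal-wound generator
#'
#' The generator emulates the salient structure of home-visit thermal
#' wound photographs: a warm elliptical wound bed on a cooler,
#' heterogeneous background, rendered through a monotone pseudo-colour
#' map with a vendor-logo overlay. The wound interior carries an
#' additive random field (white noise smoothed by a Gaussian kernel,
#' mildly skewed towards hot spots, then rescaled), whose amplitude and
#' correlation length depend on the healing class: unhealed wounds get
#' a larger-amplitude, shorter-range field, so their wound-bed GLCM
#' contrast and cluster prominence exceed those of healed wounds by
#' construction, matching the direction observed clinically. The
#' hot-spot skew reproduces the asymmetric grey-tone distribution that
#' cluster shade and prominence respond to in inflamed wound beds.
#'
#' All grey quantities are on the normalised [0, 1] scale. The
#' wound-background offset (baseTempLevel - backgroundLevel = 0.45 at
#' defaults) is far above 3 x backgroundNoiseSd, so Otsu thresholding
#' succeeds by construction at defaults.
#'
#' @param width,height raster size in pixels (default 160 x 120).
#' @param woundAxes length-2 range of the ellipse semi-axes in pixels.
#' @param baseTempLevel grey level at the wound centre.
#' @param backgroundLevel mean grey level of the background.
#' @param woundEdgeDrop grey-level drop from wound centre to wound rim
#'   (the bed is warmest centrally and cools towards the margin). This
#'   fixed-scale profile anchors the wound-bed grey range, so the
#'   texture amplitude controls GLCM contrast even after per-bed
#'   quantization.
#' @param textureCorrLengthHealed,textureCorrLengthUnhealed Gaussian
#'   smoothing sigma (pixels) of the within-wound texture field.
#' @param textureAmpHealed,textureAmpUnhealed standard deviation (grey
#'   units) of the within-wound texture field; the unhealed amplitude
#'   must be at least the healed one (set both equal, e.g. to 0, for
#'   null-calibration cohorts with no class difference).
#' @param hotSpotSkew quadratic skew coefficient of the texture field
#'   (field + skew * (field^2 - 1), re-standardised): positive values
#'   produce sparse hot spots and an asymmetric, heavy upper tail of
#'   grey tones. Applied to both classes; its visible effect scales
#'   with the class texture amplitude.
#' @param backgroundGradientAmp peak-to-trough amplitude of the smooth
#'   ambient gradient across the frame.
#' @param backgroundNoiseSd SD of the independent background noise.
#' @param logoRect integer vector (x0, y0, w, h) of the vendor-logo
#'   block (1-based top-left column/row, width, height), or \code{NULL}.
#' @param colormapName pseudo-colour map used for rendering.
#' @return a validated list of class \code{"SyntheticParams"}.
#' @export
syntheticParams <- function(width = 160L, height = 120L,
                            woundAxes = c(22, 35),
                            baseTempLevel = 0.75,
                            backgroundLevel = 0.30,
                            woundEdgeDrop = 0.20,
                            textureCorrLengthHealed = 3,
                            textureCorrLengthUnhealed = 2,
                            textureAmpHealed = 0.03,
                            textureAmpUnhealed = 0.10,
                            hotSpotSkew = 0.6,
                            backgroundGradientAmp = 0.08,
                            backgroundNoiseSd = 0.02,
                            logoRect = c(6L, 6L, 40L, 12L),
                            colormapName = "iron") {
  p <- list(width = as.integer(width), height = as.integer(height),
            woundAxes = woundAxes, baseTempLevel = baseTempLevel,
            backgroundLevel = backgroundLevel,
            woundEdgeDrop = woundEdgeDrop,
            textureCorrLengthHealed = textureCorrLengthHealed,
            textureCorrLengthUnhealed = textureCorrLengthUnhealed,
            textureAmpHealed = textureAmpHealed,
            textureAmpUnhealed = textureAmpUnhealed,
            hotSpotSkew = hotSpotSkew,
            backgroundGradientAmp = backgroundGradientAmp,
            backgroundNoiseSd = backgroundNoiseSd,
            logoRect = logoRect, colormapName = colormapName)
  stopifnot(p$width > 0, p$height > 0, length(p$woundAxes) == 2,
            all(p$woundAxes > 0))
  amps <- c(p$textureAmpHealed, p$textureAmpUnhealed,
            p$backgroundGradientAmp, p$backgroundNoiseSd,
            p$woundEdgeDrop)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  cl <- c(p$textureCorrLengthHealed, p$textureCorrLengthUnhealed)
  if (any(cl <= 0) || any(cl >= min(p$width, p$height)))
    stop("correlation lengths must lie in (0, min(width, height))")
  if (p$textureAmpUnhealed < p$textureAmpHealed)
    stop("textureAmpUnhealed must be >= textureAmpHealed")
  class(p) <- "SyntheticParams"
  p
}

# Gaussian random field: white noise smoothed with sigma, rescaled to
# unit SD. sigma is the correlation length dial; amplitude applied by
# the caller.
.gaussianField <- function(height, width, sigma) {
  z <- matrix(rnorm(height * width), height, width)
  f <- EBImage::gblur(z, sigma = sigma)
  f <- as.matrix(f)
  (f - mean(f)) / sd(f)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic pseudo-colour thermal wound image
#'
#' Deterministic in (params, label, seed). The wound is a warm ellipse
#' of random size/orientation/position (drawn from the seed) carrying a
#' class-dependent Gaussian texture field; the background is a smooth
#' ambient gradient plus independent noise, strictly cooler on average
#' than the wound interior; the logo rectangle, when present, is
#' overwritten with a constant white block after pseudo-colour
#' rendering.
#'
#' @param params a \code{\link{syntheticParams}} list.
#' @param label \code{"healed"} or \code{"unhealed"}.
#' @param seed integer seed; the image is a pure function of
#'   (params, label, seed).
#' @param subjectId identifier stored in the result.
#' @return a \code{\linkS4class{ThermalImage}} with ground-truth mask.
#' @examples
#' img <- generateWoundImage(syntheticParams(), "unhealed", seed = 1)
#' img
#' @export
generateWoundImage <- function(params = syntheticParams(),
                               label = c("unhealed", "healed"),
                               seed = 1L, subjectId = "S1") {
  label <- match.arg(label)
  stopifnot(inherits(params, "SyntheticParams"))
  H <- params$height; W <- params$width
  margin <- ceiling(max(params$woundAxes)) + 3L
  if (2L * margin >= min(W, H))
    stop("wound ellipse does not fit inside the frame; ",
         "reduce woundAxes or enlarge the raster")
  .withSeed(seed, {
    a <- runif(1, params$woundAxes[1], params$woundAxes[2])
    b <- runif(1, params$woundAxes[1], params$woundAxes[2])
    phi <- runif(1, 0, pi)
    cx <- runif(1, margin, W - margin)
    cy <- runif(1, margin, H - margin)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    u <- (xx - cx) * cos(phi) + (yy - cy) * sin(phi)
    v <- -(xx - cx) * sin(phi) + (yy - cy) * cos(phi)
    rho2 <- (u / a)^2 + (v / b)^2        # 0 at centre, 1 at the rim
    mask <- rho2 <= 1
    gdir <- runif(1, 0, 2 * pi)
    grad <- params$backgroundGradientAmp *
      (cos(gdir) * (xx / W - 0.5) + sin(gdir) * (yy / H - 0.5))
    grey <- params$backgroundLevel + grad +
      matrix(rnorm(H * W, sd = params$backgroundNoiseSd), H, W)
    if (label == "unhealed") {
      amp <- params$textureAmpUnhealed
      corr <- params$textureCorrLengthUnhealed
    } else {
      amp <- params$textureAmpHealed
      corr <- params$textureCorrLengthHealed
    }
    field <- .gaussianField(H, W, corr)
    if (params$hotSpotSkew != 0) {
      field <- field + params$hotSpotSkew * (field^2 - 1)
      field <- (field - mean(field)) / sd(field)
    }
    grey[mask] <- params$baseTempLevel -
      params$woundEdgeDrop * rho2[mask] + amp * field[mask]
    grey <- pmin(pmax(grey, 0), 1)
    rgb <- applyColormap(grey, params$colormapName)
    if (!is.null(params$logoRect)) {
      r <- params$logoRect
      rows <- r[2]:(r[2] + r[4] - 1L)
      cols <- r[1]:(r[1] + r[3] - 1L)
      rgb[rows, cols, ] <- 255L
    }
    ThermalImage(rgb, trueMask = mask + 0, label = label,
                 subjectId = subjectId)
  })
}

#' Generate a labelled synthetic cohort
#'
#' Produces \code{nUnhealed + nHealed} images with unique subject
#' identifiers; each image's seed is derived deterministically from the
#' master seed, so two calls with identical arguments return identical
#' cohorts. The default 47:17 imbalance mirrors the clinical cohort
#' structure the generator emulates (47 unhealed and 17 healed ulcers).
#'
#' @param nUnhealed,nHealed class counts (>= 1).
#' @param params a \code{\link{syntheticParams}} list.
#' @param seed master seed.
#' @return list of \code{\linkS4class{ThermalImage}} objects, unhealed
#'   first.
#' @export
generateCohort <- function(nUnhealed = 47L, nHealed = 17L,
                           params = syntheticParams(), seed = 1L) {
  stopifnot(nUnhealed >= 1, nHealed >= 1)
  labels <- c(rep("unhealed", nUnhealed), rep("healed", nHealed))
  n <- length(labels)
  lapply(seq_len(n), function(i) {
    generateWoundImage(params, labels[i],
                       seed = deriveSeed(seed, i),
                       subjectId = sprintf("S%03d", i))
  })
}

#' Derive a per-item seed from a master seed
#'
#' Deterministic and collision-free for item indices below 10^4; the
#' result stays below 2^31.
#'
#' @param seed master seed (integer).
#' @param index item index (>= 1).
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 199999) * 10000 + index)
}

#' Write a cohort to PNG files plus a manifest CSV
#'
#' @param images list of \code{\linkS4class{ThermalImage}} objects.
#' @param dir output directory (created if needed).
#' @param seed the master seed to record in the manifest.
#' @return the manifest data frame (columns filename, subject_id,
#'   label, seed), invisibly; also written to \code{manifest.csv}.
#' @export
writeCohort <- function(images, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- sprintf("wound_%03d.png", seq_along(images))
  for (i in seq_along(images)) {
    arr <- aperm(rgbRaster(images[[i]]), c(2, 1, 3)) / 255
    img <- EBImage::Image(arr, colormode = "Color")
    EBImage::writeImage(img, file.path(dir, fn[i]))
  }
  manifest <- data.frame(
    filename = fn,
    subject_id = vapply(images, subjectId, character(1)),
    label = vapply(images, woundLabel, character(1)),
    seed = seed)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a thermal image from a raster file
#'
#' Reads PNG/TIFF/JPEG via EBImage and returns the package's raster
#' convention (rows = image rows, channel values in [0, 255]).
#'
#' @param path file path.
#' @param label,subjectId metadata to attach.
#' @return a \code{\linkS4class{ThermalImage}}.
#' @export
readThermalImage <- function(path, label = "unknown", subjectId = "") {
  img <- EBImage::readImage(path)
  arr <- EBImage::imageData(img)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  arr <- round(255 * aperm(arr[, , 1:3, drop = FALSE], c(2, 1, 3)))
  ThermalImage(arr, label = label, subjectId = subjectId)
}
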