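#' GLCM configuration
#'
#' @param nLevels grey-level quantization Ng (>= 2; default 16, which
#'   keeps the co-occurrence matrix well populated for small wound beds
#'   on a 160 x 120 raster).
#' @param theta angular offset in degrees: 0, 45, 90 or 135 (default
#'   90, the vertical neighbour).
#' @param d pixel distance (>= 1; default 1).
#' @param symmetric accumulate both the offset and its negation
#'   (default TRUE: direction-agnostic texture).
#' @return a named list of class \code{"GLCMConfig"}.
#' @export
glcmConfig <- function(nLevels = 16L, theta = 90L, d = 1L,
                       symmetric = TRUE) {
  stopifnot(nLevels >= 2, d >= 1, theta %in% c(0L, 45L, 90L, 135L))
  structure(list(nLevels = as.integer(nLevels),
                 theta = as.integer(theta), d = as.integer(d),
                 symmetric = isTRUE(symmetric)),
            class = "GLCMConfig")
}

#' Quantize wound-bed grey values to Ng levels
#'
#' Uniform binning of the eligible-pixel grey range into Ng equal-width
#' bins: level = 1 + floor(Ng (g - min) / (max - min)), clipped to Ng.
#' A constant eligible region maps every pixel to level 1 with a
#' warning.
#'
#' @param bed a \code{\linkS4class{WoundBed}}.
#' @param nLevels Ng.
#' @return H x W integer matrix of levels 1..Ng on eligible pixels and
#'   0 elsewhere.
#' @export
quantizeBed <- function(bed, nLevels = 16L) {
  stopifnot(is(bed, "WoundBed"), nLevels >= 2)
  mask <- maskValues(bed) == 1
  if (sum(mask) < 2) stop("need at least 2 eligible pixels to quantize")
  g <- greyValues(bed)
  rng <- range(g[mask])
  lev <- matrix(0L, nrow(g), ncol(g))
  if (rng[1] == rng[2]) {
    warning("constant wound bed: all pixels assigned level 1")
    lev[mask] <- 1L
  } else {
    q <- 1L + floor(nLevels * (g[mask] - rng[1]) / (rng[2] - rng[1]))
    lev[mask] <- pmin(as.integer(q), as.integer(nLevels))
  }
  lev
}

# (row, col) offset for an angle/distance, row 1 at the top
.glcmOffset <- function(theta, d) {
  switch(as.character(theta),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d))
}

#' Compute the grey-level co-occurrence matrix of a masked level image
#'
#' Counts ordered level pairs (levels[x], levels[x + offset]) over all
#' positions where both endpoints are mask-eligible; with
#' \code{symmetric = TRUE} the negated offset is accumulated as well.
#' Counts are normalised by the total pair count.
#'
#' @param levels H x W integer level matrix (0 = ineligible), as
#'   returned by \code{\link{quantizeBed}}.
#' @param mask H x W binary matrix of eligible pixels.
#' @param config a \code{\link{glcmConfig}} list.
#' @return a \code{\linkS4class{GLCM}}.
#' @export
computeGLCM <- function(levels, mask, config = glcmConfig()) {
  stopifnot(identical(dim(levels), dim(mask)))
  Ng <- config$nLevels
  off <- .glcmOffset(config$theta, config$d)
  H <- nrow(levels); W <- ncol(levels)
  dr <- off[1]; dc <- off[2]
  r1 <- max(1L, 1L - dr):min(H, H - dr)
  c1 <- max(1L, 1L - dc):min(W, W - dc)
  if (length(r1) < 1 || length(c1) < 1)
    stop("offset exceeds image extent")
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + dr, c1 + dc, drop = FALSE]
  ok <- (mask[r1, c1, drop = FALSE] == 1) &
    (mask[r1 + dr, c1 + dc, drop = FALSE] == 1)
  av <- a[ok]; bv <- b[ok]
  counts <- matrix(tabulate(av + (bv - 1L) * Ng, Ng * Ng), Ng, Ng)
  if (config$symmetric) counts <- counts + t(counts)
  n <- sum(counts)
  if (n == 0)
    stop("no eligible pixel pairs at this offset: degenerate mask")
  new("GLCM", p = counts / n, nPairs = n, config = unclass(config))
}

#' Names of the 19 GLCM texture features
#'
#' Energy, contrast, correlation, sum of squares (variance), sum
#' average, sum variance, entropy, sum entropy, difference entropy,
#' information measure of correlation, homogeneity, autocorrelation,
#' dissimilarity, cluster shade, cluster prominence, maximum
#' probability, inverse difference, inverse difference normalised, and
#' inverse difference moment normalised.
#'
#' @return character vector of length 19.
#' @export
featureNames <- function() {
  c("Eng", "Cont", "Corr", "sumSq", "sumAv", "sumVar", "Entr",
    "sumEnt", "diffEnt", "imCorr", "Hom", "aCorr", "dSim", "clSha",
    "clPro", "maxProb", "idHom", "idNorm", "idmNorm")
}

#' Compute the 19 texture features of a GLCM
#'
#' Levels are indexed 1..Ng (Haralick convention) and the natural
#' logarithm is used throughout, with 0 log 0 = 0. Sum variance is
#' taken about the sum average (the widely used corrected form).
#' Correlation and the information measure are reported as 0, with a
#' \code{"degenerate"} attribute, when the marginal SD or entropy
#' vanishes (single-level image).
#'
#' @param glcm a \code{\linkS4class{GLCM}} (or a bare normalised
#'   probability matrix).
#' @return named numeric vector of the 19 features
#'   (\code{\link{featureNames}}).
#' @examples
#' g <- new("GLCM", p = diag(2) / 2, nPairs = 4,
#'          config = unclass(glcmConfig(nLevels = 2)))
#' glcmFeatures(g)[c("Eng", "Corr", "sumAv")]
#' @export
glcmFeatures <- function(glcm) {
  p <- if (is(glcm, "GLCM")) glcmMatrix(glcm) else glcm
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)            # row index
  j <- matrix(seq_len(Ng), Ng, Ng, byrow = TRUE)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sigx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  # marginal distributions of i + j and |i - j|
  psum <- vapply(2:(2 * Ng), function(k) sum(p[i + j == k]), 0)
  pdiff <- vapply(0:(Ng - 1), function(k) sum(p[abs(i - j) == k]), 0)
  ksum <- 2:(2 * Ng); kdiff <- 0:(Ng - 1)
  degenerate <- FALSE

  eng <- sum(p^2)
  cont <- sum((i - j)^2 * p)
  acorr <- sum(i * j * p)
  corr <- if (sigx == 0 || sigy == 0) {
    degenerate <- TRUE; 0
  } else (acorr - mux * muy) / (sigx * sigy)
  sumsq <- sum((i - mux)^2 * p)
  sumav <- sum(ksum * psum)
  sumvar <- sum((ksum - sumav)^2 * psum)
  entr <- -sum(xlogx(p))
  sument <- -sum(xlogx(psum))
  diffent <- -sum(xlogx(pdiff))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p[p > 0] * log(pxy[p > 0]))
  imcorr <- if (max(hx, hy) == 0) {
    degenerate <- TRUE; 0
  } else (entr - hxy1) / max(hx, hy)
  hom <- sum(p / (1 + (i - j)^2))
  dsim <- sum(abs(i - j) * p)
  clsha <- sum((i + j - mux - muy)^3 * p)
  clpro <- sum((i + j - mux - muy)^4 * p)
  maxprob <- max(p)
  idhom <- sum(p / (1 + abs(i - j)))
  idnorm <- sum(p / (1 + abs(i - j) / Ng))
  idmnorm <- sum(p / (1 + (i - j)^2 / Ng^2))

  out <- c(Eng = eng, Cont = cont, Corr = corr, sumSq = sumsq,
           sumAv = sumav, sumVar = sumvar, Entr = entr,
           sumEnt = sument, diffEnt = diffent, imCorr = imcorr,
           Hom = hom, aCorr = acorr, dSim = dsim, clSha = clsha,
           clPro = clpro, maxProb = maxprob, idHom = idhom,
           idNorm = idnorm, idmNorm = idmnorm)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Extract the 19-feature vector from one thermal image
#'
#' Composes the full deterministic chain: logo in-fill, greyscale
#' conversion, normalisation, masking, wound-bed extraction,
#' quantization, co-occurrence counting and feature computation.
#'
#' @param image a \code{\linkS4class{ThermalImage}}.
#' @param preprocess a \code{\link{preprocessConfig}} list.
#' @param glcm a \code{\link{glcmConfig}} list.
#' @return named numeric feature vector with attributes
#'   \code{"maskPixels"} (eligible pixel count) and \code{"nPairs"}.
#' @export
extractFeatures <- function(image, preprocess = preprocessConfig(),
                            glcm = glcmConfig()) {
  bed <- preprocessImage(image, preprocess)
  lev <- quantizeBed(bed, glcm$nLevels)
  g <- computeGLCM(lev, maskValues(bed), glcm)
  f <- glcmFeatures(g)
  attr(f, "maskPixels") <- sum(maskValues(bed))
  attr(f, "nPairs") <- pairCount(g)
  f
}

#' Build a feature table from a cohort of images
#'
#' One row per image: metadata, the 19 features, and the GLCM
#' configuration for provenance.
#'
#' @param images list of \code{\linkS4class{ThermalImage}} objects.
#' @param preprocess a \code{\link{preprocessConfig}} list.
#' @param glcm a \code{\link{glcmConfig}} list.
#' @param filenames optional character vector recorded in the table.
#' @return data.frame with columns \code{filename}, \code{subject_id},
#'   \code{label}, the 19 features, \code{n_levels}, \code{theta},
#'   \code{d} and \code{mask_px}.
#' @export
extractFeatureTable <- function(images, preprocess = preprocessConfig(),
                                glcm = glcmConfig(),
                                filenames = NULL) {
  if (is.null(filenames))
    filenames <- sprintf("wound_%03d.png", seq_along(images))
  rows <- lapply(seq_along(images), function(k) {
    f <- extractFeatures(images[[k]], preprocess, glcm)
    cbind(data.frame(filename = filenames[k],
                     subject_id = subjectId(images[[k]]),
                     label = woundLabel(images[[k]])),
          as.data.frame(as.list(f)),
          data.frame(n_levels = glcm$nLevels, theta = glcm$theta,
                     d = glcm$d, mask_px = attr(f, "maskPixels")))
  })
  do.call(rbind, rows)
}

#' Extract the 19-feature matrix from a feature table
#'
#' @param table a feature table from \code{\link{extractFeatureTable}}.
#' @return numeric matrix with one row per image and the 19 feature
#'   columns.
#' @export
featureMatrix <- function(table) {
  fn <- featureNames()
  missing <- setdiff(fn, names(table))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  m <- as.matrix(table[, fn])
  if (anyNA(m)) stop("feature table contains missing values")
  m
}
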