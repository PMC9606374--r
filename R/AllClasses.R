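setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ThermalImage: a pseudo-colour thermal raster with metadata
#'
#' The raw observation unit of the pipeline: an RGB raster (nominally
#' 160 x 120 from a handheld imager) in which warmer surfaces map to
#' brighter pseudo-colours, together with the week-12 healing label and a
#' subject identifier. Synthetic images additionally carry the
#' ground-truth wound mask used to score segmentation.
#'
#' @slot rgb numeric H x W x 3 array with integer values in [0, 255].
#' @slot trueMask H x W matrix in {0, 1} (ground-truth wound region,
#'   synthetic images only) or \code{NULL}.
#' @slot label character; one of \code{"healed"}, \code{"unhealed"},
#'   \code{"unknown"}.
#' @slot subjectId character; opaque subject identifier.
#'
#' @exportClass ThermalImage
setClass("ThermalImage",
  representation(
    rgb = "array",
    trueMask = "matrixOrNULL",
    label = "character",
    subjectId = "character"
  ),
  prototype(trueMask = NULL, label = "unknown", subjectId = "")
)

setValidity("ThermalImage", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L)
    return("rgb must be an H x W x 3 array")
  if (anyNA(object@rgb) || min(object@rgb) < 0 || max(object@rgb) > 255)
    return("rgb channel values must lie in [0, 255]")
  if (!object@label %in% c("healed", "unhealed", "unknown"))
    return("label must be 'healed', 'unhealed' or 'unknown'")
  if (!is.null(object@trueMask)) {
    if (!identical(dim(object@trueMask), d[1:2]))
      return("trueMask dimensions must match the raster")
    if (!all(object@trueMask %in% c(0, 1)))
      return("trueMask must be binary")
    if (sum(object@trueMask) > 0) {
      lab <- EBImage::bwlabel(object@trueMask)
      if (max(lab) != 1L)
        return("trueMask must be a single connected region")
    }
  }
  TRUE
})

#' Construct a ThermalImage
#'
#' @param rgb H x W x 3 array of integer channel values in [0, 255].
#' @param trueMask optional H x W binary matrix (synthetic ground truth).
#' @param label healing label: \code{"healed"}, \code{"unhealed"} or
#'   \code{"unknown"}.
#' @param subjectId subject identifier.
#' @return A \code{\linkS4class{ThermalImage}}.
#' @export
ThermalImage <- function(rgb, trueMask = NULL, label = "unknown",
                         subjectId = "") {
  new("ThermalImage", rgb = rgb, trueMask = trueMask, label = label,
      subjectId = subjectId)
}

setMethod("show", "ThermalImage", function(object) {
  d <- dim(object@rgb)
  cat("ThermalImage", d[2], "x", d[1], "px,",
      "label:", object@label,
      if (nzchar(object@subjectId)) paste0("(", object@subjectId, ")"),
      if (!is.null(object@trueMask)) "[with ground-truth mask]", "\n")
})

#' WoundBed: normalised grey image restricted to wound pixels
#'
#' Pairs the normalised grey image with the enhanced binary mask.
#' Background pixels are excluded from analysis (not zero-filled):
#' co-occurrence counting skips any pixel pair with an endpoint outside
#' the mask, so no artificial high-contrast edge is created at the mask
#' boundary.
#'
#' @slot grey H x W numeric matrix in [0, 1].
#' @slot mask H x W matrix in {0, 1}; the analysis-eligible pixels.
#'
#' @exportClass WoundBed
setClass("WoundBed",
  representation(grey = "matrix", mask = "matrix"))

setValidity("WoundBed", function(object) {
  if (!identical(dim(object@grey), dim(object@mask)))
    return("grey and mask dimensions differ")
  if (anyNA(object@grey) || any(!is.finite(object@grey)))
    return("grey must be finite everywhere")
  if (min(object@grey) < 0 || max(object@grey) > 1)
    return("grey values must lie in [0, 1]")
  if (!all(object@mask %in% c(0, 1)))
    return("mask must be binary")
  if (sum(object@mask) < 1)
    return("mask must contain at least one pixel")
  TRUE
})

setMethod("show", "WoundBed", function(object) {
  cat("WoundBed:", sum(object@mask), "eligible pixels of",
      length(object@mask), "\n")
})

#' GLCM: normalised grey-level co-occurrence matrix
#'
#' The joint distribution p(i, j) of quantized grey levels of pixel
#' pairs at a fixed angular offset and distance, normalised to sum to 1.
#'
#' @slot p Ng x Ng numeric matrix of co-occurrence probabilities; levels
#'   indexed 1..Ng.
#' @slot nPairs number of pixel pairs that contributed counts.
#' @slot config the \code{\link{glcmConfig}} list used.
#'
#' @exportClass GLCM
setClass("GLCM",
  representation(p = "matrix", nPairs = "numeric", config = "list"))

setValidity("GLCM", function(object) {
  p <- object@p
  if (nrow(p) != ncol(p)) return("p must be square")
  if (min(p) < 0) return("p entries must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) return("p must sum to 1")
  if (isTRUE(object@config$symmetric) && any(p != t(p)))
    return("symmetric GLCM must equal its transpose")
  TRUE
})

setMethod("show", "GLCM", function(object) {
  cat("GLCM", nrow(object@p), "x", ncol(object@p),
      sprintf("(theta=%d, d=%d, %s), %d pairs\n",
              object@config$theta, object@config$d,
              if (isTRUE(object@config$symmetric)) "symmetric" else
                "directed",
              as.integer(object@nPairs)))
})

#' PCAModel: principal axes fitted on training features
#'
#' Stores the training-set column means (and optional scales), the
#' orthonormal principal axes with a fixed sign convention (the
#' largest-magnitude loading of each component is positive), and the
#' explained-variance ratios. Held-out data are projected with the
#' training-derived centre and axes only; the model is never re-fitted
#' on test rows.
#'
#' @slot center numeric vector of training column means.
#' @slot scale numeric vector of training column scales (all 1 when the
#'   model was fitted unstandardised).
#' @slot rotation p x k matrix of orthonormal principal axes (columns).
#' @slot varRatios explained-variance ratios, non-increasing.
#' @slot kSelected number of leading components retained by default.
#' @slot standardised logical; whether columns were scaled to unit SD.
#'
#' @exportClass PCAModel
setClass("PCAModel",
  representation(center = "numeric", scale = "numeric",
                 rotation = "matrix", varRatios = "numeric",
                 kSelected = "integer", standardised = "logical"))

setValidity("PCAModel", function(object) {
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(ncol(object@rotation)))) > 1e-8)
    return("rotation columns must be orthonormal")
  r <- object@varRatios
  if (any(r < -1e-12) || any(diff(r) > 1e-12))
    return("explained-variance ratios must be non-negative and non-increasing")
  if (sum(r) > 1 + 1e-12) return("ratios must sum to at most 1")
  if (object@kSelected < 1L || object@kSelected > ncol(object@rotation))
    return("kSelected out of range")
  TRUE
})

setMethod("show", "PCAModel", function(object) {
  cv <- cumsum(object@varRatios)
  cat("PCAModel:", nrow(object@rotation), "features,",
      ncol(object@rotation), "components;",
      sprintf("first %d explain %.2f%%\n", object@kSelected,
              100 * cv[object@kSelected]))
})

#' BNNModel: a 3-h-1 feedforward classifier with Gaussian weight prior
#'
#' A single-hidden-layer network taking the three leading principal
#' component scores, with tanh hidden units and one sigmoid output that
#' gives the probability that the wound is UNHEALED (the positive
#' class). Training minimises cross-entropy plus a weight-decay penalty
#' alpha * 0.5 * sum(w^2); alpha is re-estimated from the evidence
#' framework. The parameter count is 5h + 1.
#'
#' @slot w1 h x 3 input-to-hidden weight matrix.
#' @slot b1 hidden biases (length h).
#' @slot w2 hidden-to-output weights (length h).
#' @slot b2 output bias (length 1).
#' @slot h hidden-node count.
#' @slot alpha weight-decay hyperparameter (> 0).
#' @slot trained logical.
#'
#' @exportClass BNNModel
setClass("BNNModel",
  representation(w1 = "matrix", b1 = "numeric", w2 = "numeric",
                 b2 = "numeric", h = "integer", alpha = "numeric",
                 trained = "logical"))

setValidity("BNNModel", function(object) {
  h <- object@h
  if (h < 1L) return("h must be >= 1")
  if (!identical(dim(object@w1), c(as.integer(h), 3L)))
    return("w1 must be h x 3")
  if (length(object@b1) != h || length(object@w2) != h ||
      length(object@b2) != 1L)
    return("bias/weight lengths inconsistent with h")
  if (object@alpha <= 0) return("alpha must be positive")
  TRUE
})

setMethod("show", "BNNModel", function(object) {
  cat(sprintf("BNNModel 3-%d-1 (%d parameters), alpha = %.4g%s\n",
              object@h, 5L * object@h + 1L, object@alpha,
              if (object@trained) ", trained" else ", untrained"))
})

#' @describeIn ThermalImage-class accessor for the RGB raster.
#' @param object a \code{ThermalImage}.
#' @export
rgbRaster <- function(object) object@rgb

#' @describeIn ThermalImage-class accessor for the ground-truth mask.
#' @export
trueMask <- function(object) object@trueMask

#' @describeIn ThermalImage-class accessor for the healing label.
#' @export
woundLabel <- function(object) object@label

#' @describeIn ThermalImage-class accessor for the subject identifier.
#' @export
subjectId <- function(object) object@subjectId

#' @describeIn WoundBed-class accessor for the grey image.
#' @param object a \code{WoundBed}.
#' @export
greyValues <- function(object) object@grey

#' @describeIn WoundBed-class accessor for the binary mask.
#' @export
maskValues <- function(object) object@mask

#' @describeIn GLCM-class accessor for the probability matrix p(i, j).
#' @param object a \code{GLCM}.
#' @export
glcmMatrix <- function(object) object@p

#' @describeIn GLCM-class accessor for the contributing pair count.
#' @export
pairCount <- function(object) object@nPairs
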