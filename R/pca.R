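#' Fit principal axes on training-set features
#'
#' Covariance PCA on mean-centred (by default unstandardised) feature
#' columns. The raw texture features span several orders of magnitude
#' (cluster prominence is of order 10^2 while the normalised inverse
#' differences are of order 1), so unscaled PCA concentrates almost all
#' variance in very few components; a \code{standardise} flag is
#' available for unit-variance columns. Component signs are fixed by
#' forcing the largest-magnitude loading of each axis to be positive,
#' so repeated fits are bit-comparable.
#'
#' @param x n x p numeric matrix of training features (n >= 2).
#' @param standardise scale columns to unit SD before the fit.
#' @param kSelected number of leading components retained by default
#'   (capped at the available rank; default 3, the number fed to the
#'   classifier).
#' @return a \code{\linkS4class{PCAModel}}.
#' @export
fitPCA <- function(x, standardise = FALSE, kSelected = 3L) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA requires at least 2 rows")
  pr <- prcomp(x, center = TRUE, scale. = standardise)
  rot <- pr$rotation
  for (k in seq_len(ncol(rot))) {
    imax <- which.max(abs(rot[, k]))
    if (rot[imax, k] < 0) rot[, k] <- -rot[, k]
  }
  v <- pr$sdev^2
  ratios <- v / sum(v)
  sc <- if (identical(pr$scale, FALSE)) rep(1, ncol(x)) else pr$scale
  new("PCAModel", center = as.numeric(pr$center),
      scale = as.numeric(sc), rotation = unname(rot),
      varRatios = as.numeric(ratios),
      kSelected = as.integer(min(kSelected, ncol(rot))),
      standardised = isTRUE(standardise))
}

#' Cumulative explained variance of a PCA model
#'
#' @param model a \code{\linkS4class{PCAModel}}.
#' @return non-decreasing numeric vector in [0, 1]; the last entry is 1
#'   when all components are kept.
#' @export
cumulativeVariance <- function(model) {
  stopifnot(is(model, "PCAModel"))
  cumsum(model@varRatios)
}

#' Number of components needed to reach a variance threshold
#'
#' Smallest k whose cumulative explained variance reaches the
#' threshold. The default threshold 0.9999 reflects the regime where a
#' handful of components carries essentially all variance of the
#' unstandardised texture features.
#'
#' @param cumulative non-decreasing cumulative-variance sequence.
#' @param threshold fraction in (0, 1].
#' @return integer k; the full dimension, with a warning, when the
#'   threshold is numerically unreachable.
#' @examples
#' selectNComponents(c(0.9644, 0.9944, 0.9999, 1), 0.9999)  # 3
#' @export
selectNComponents <- function(cumulative, threshold = 0.9999) {
  stopifnot(threshold > 0, threshold <= 1)
  k <- which(cumulative >= threshold - 1e-12)[1]
  if (is.na(k)) {
    warning("variance threshold unreachable; keeping all components")
    k <- length(cumulative)
  }
  as.integer(k)
}

#' Project feature vectors onto training-derived principal axes
#'
#' Centres (and scales, if the model was standardised) with the
#' training statistics and multiplies by the leading-k axes. The model
#' is never re-fitted: held-out data influence nothing but their own
#' scores.
#'
#' @param model a \code{\linkS4class{PCAModel}}.
#' @param x m x p matrix of feature vectors.
#' @param k number of leading components (default the model's
#'   \code{kSelected}).
#' @return m x k score matrix.
#' @export
projectScores <- function(model, x, k = model@kSelected) {
  stopifnot(is(model, "PCAModel"), k >= 1, k <= ncol(model@rotation))
  x <- as.matrix(x)
  if (ncol(x) != nrow(model@rotation))
    stop("feature dimension does not match the model")
  xc <- sweep(x, 2, model@center)
  if (model@standardised) xc <- sweep(xc, 2, model@scale, "/")
  xc %*% model@rotation[, seq_len(k), drop = FALSE]
}

#' Serialise a PCA model to JSON
#'
#' @param model a \code{\linkS4class{PCAModel}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePCAModel <- function(model, path) {
  obj <- list(center = model@center, scale = model@scale,
              rotation = model@rotation, varRatios = model@varRatios,
              kSelected = model@kSelected,
              standardised = model@standardised)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a PCA model from JSON
#'
#' @param path file written by \code{\link{writePCAModel}}.
#' @return a \code{\linkS4class{PCAModel}}.
#' @export
readPCAModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PCAModel", center = obj$center, scale = obj$scale,
      rotation = as.matrix(obj$rotation), varRatios = obj$varRatios,
      kSelected = as.integer(obj$kSelected),
      standardised = isTRUE(obj$standardised))
}
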