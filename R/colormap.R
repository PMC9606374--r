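#' Pseudo-colour maps for thermal rasters
#'
#' The package ships a procedurally defined "iron" map (black - red -
#' yellow - white, the hot-iron palette common on handheld thermal
#' imagers) built from piecewise-linear R, G, B ramps. Its luminance
#' 0.2126 R + 0.7152 G + 0.0722 B is strictly increasing in the grey
#' input, so the map can be inverted stably by nearest-neighbour lookup.
#'
#' @param name colormap identifier; currently only \code{"iron"}.
#' @return a 256 x 3 integer matrix of R, G, B values in [0, 255],
#'   row k being the colour for grey level (k - 1)/255.
#' @export
colormapLUT <- function(name = "iron") {
  if (!identical(name, "iron"))
    stop("unknown colormap: ", name)
  x <- seq(0, 1, length.out = 256)
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  r <- clamp01(x / 0.375)
  g <- clamp01((x - 0.375) / 0.375)
  b <- clamp01((x - 0.75) / 0.25)
  lut <- round(255 * cbind(r, g, b))
  dimnames(lut) <- NULL
  storage.mode(lut) <- "integer"
  lut
}

#' Map a grey field through a pseudo-colour map
#'
#' @param grey H x W numeric matrix in [0, 1].
#' @param name colormap identifier (see \code{\link{colormapLUT}}).
#' @return H x W x 3 integer array of channel values in [0, 255].
#' @examples
#' rgb <- applyColormap(matrix(0.5, 4, 4))
#' dim(rgb)
#' @export
applyColormap <- function(grey, name = "iron") {
  stopifnot(is.matrix(grey))
  if (anyNA(grey) || min(grey) < 0 || max(grey) > 1)
    stop("grey values must lie in [0, 1]")
  lut <- colormapLUT(name)
  idx <- pmin(pmax(as.integer(round(grey * 255)), 0L), 255L) + 1L
  out <- array(0L, c(dim(grey), 3L))
  for (ch in 1:3) out[, , ch] <- lut[idx, ch]
  out
}

#' Invert a pseudo-colour map by nearest-neighbour lookup
#'
#' Recovers the grey level whose palette colour is closest (Euclidean in
#' RGB) to each pixel. Exact round-trips hold up to the 8-bit
#' quantization of the palette.
#'
#' @param rgb H x W x 3 array of channel values in [0, 255].
#' @param name colormap identifier.
#' @return H x W numeric matrix in [0, 1].
#' @export
invertColormap <- function(rgb, name = "iron") {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be H x W x 3")
  lut <- colormapLUT(name)
  px <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
              as.vector(rgb[, , 3]))
  # squared distances via |p|^2 + |l|^2 - 2 p.l; argmin over 256 rows
  cross <- px %*% t(lut)
  d2 <- outer(rowSums(px^2), rep(1, nrow(lut))) +
    outer(rep(1, nrow(px)), rowSums(lut^2)) - 2 * cross
  idx <- max.col(-d2, ties.method = "first")
  matrix((idx - 1) / 255, d[1], d[2])
}
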