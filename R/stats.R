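# Exact null distribution of the rank sum of the first sample, as a
# dynamic programme over the (possibly tied, mid-ranked) pooled ranks.
# Returns support (rank sums, scaled by 2 to stay integer) and counts.
.rankSumDistribution <- function(ranks2, nx) {
  n <- length(ranks2)
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(nx)])
  ways <- matrix(0, nx + 1L, smax + 1L)
  ways[1L, 1L] <- 1
  kmax <- 0L
  for (r in ranks2) {
    upto <- min(kmax, nx - 1L)
    for (k in upto:0L) {
      src <- ways[k + 1L, ]
      idx <- which(src > 0)
      if (length(idx))
        ways[k + 2L, idx + r] <- ways[k + 2L, idx + r] + src[idx]
    }
    kmax <- min(kmax + 1L, nx)
  }
  counts <- ways[nx + 1L, ]
  support <- which(counts > 0) - 1L
  list(s = support, count = counts[support + 1L])
}

#' Mann-Whitney U test
#'
#' Two-sided test of stochastic equality between two samples. The
#' \code{"exact"} mode enumerates the permutation null distribution of
#' the rank sum (valid with ties, using mid-ranks) and is limited to
#' combined samples of 20; \code{"normal_approx"} uses the
#' tie-corrected Gaussian approximation with continuity correction.
#' \code{"auto"} picks exact when n <= 20.
#'
#' @param x,y numeric samples (x is conventionally the unhealed group).
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal_approx"}.
#' @return list with \code{U} (the Mann-Whitney statistic for x),
#'   \code{p.value}, \code{mode} used, and \code{degenerate} (TRUE when
#'   all values are tied across both samples, in which case p = 1).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p.value  # 0.1
#' @export
mannWhitneyU <- function(x, y, mode = c("auto", "exact",
                                        "normal_approx")) {
  mode <- match.arg(mode)
  nx <- length(x); ny <- length(y); n <- nx + ny
  stopifnot(nx >= 1, ny >= 1)
  if (mode == "auto") mode <- if (n <= 20) "exact" else "normal_approx"
  if (mode == "exact" && n > 20)
    stop("exact mode requires a combined sample size of at most 20")
  r <- rank(c(x, y))
  rs <- sum(r[seq_len(nx)])
  U <- rs - nx * (nx + 1) / 2
  if (length(unique(c(x, y))) == 1L)
    return(list(U = U, p.value = 1, mode = mode, degenerate = TRUE))
  if (mode == "exact") {
    dist <- .rankSumDistribution(as.integer(round(2 * r)), nx)
    total <- sum(dist$count)
    sObs <- as.integer(round(2 * rs))
    lower <- sum(dist$count[dist$s <= sObs]) / total
    upper <- sum(dist$count[dist$s >= sObs]) / total
    p <- min(1, 2 * min(lower, upper))
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0)
      return(list(U = U, p.value = 1, mode = mode, degenerate = TRUE))
    z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(U = U, p.value = p, mode = mode, degenerate = FALSE)
}

#' Effect size between two samples
#'
#' \code{"cohens_d"}: difference of means over the pooled (n - 1)
#' standard deviation. \code{"rank_biserial"}: 2U/(nx ny) - 1, the
#' rank-based companion of the Mann-Whitney test. Both are positive
#' when group x (conventionally the unhealed wounds) exceeds group y.
#'
#' @param x,y numeric samples; \code{cohens_d} requires at least 2
#'   values per sample.
#' @param method \code{"cohens_d"} or \code{"rank_biserial"}.
#' @return a signed scalar.
#' @export
effectSize <- function(x, y, method = c("cohens_d", "rank_biserial")) {
  method <- match.arg(method)
  nx <- length(x); ny <- length(y)
  if (method == "cohens_d") {
    stopifnot(nx >= 2, ny >= 2)
    sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
    if (sp == 0) stop("zero pooled SD: degenerate input")
    (mean(x) - mean(y)) / sp
  } else {
    r <- rank(c(x, y))
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    2 * U / (nx * ny) - 1
  }
}

#' Rank texture features by between-class significance
#'
#' Runs one two-sided Mann-Whitney U test per feature (unhealed vs
#' healed) and orders features by ascending p-value; both Cohen's d and
#' the rank-biserial correlation are reported (positive = unhealed
#' higher). No multiple-testing correction is applied: a raw 0.05 rule
#' flags significance, and \code{n_tests} is recorded so users can
#' apply their own correction.
#'
#' With \code{onePerSubject = TRUE}, only the first image per subject
#' (by subject identifier, then table order — a deterministic, declared
#' rule) is retained before testing.
#'
#' @param table a feature table (see \code{\link{extractFeatureTable}})
#'   with a \code{label} column.
#' @param onePerSubject retain a single image per subject first.
#' @param mode test mode passed to \code{\link{mannWhitneyU}}.
#' @return data.frame ordered by ascending p-value with columns
#'   \code{feature}, \code{U}, \code{p_value}, \code{cohens_d},
#'   \code{rank_biserial}, \code{significant}; attribute
#'   \code{"n_tests"} carries the number of tests.
#' @export
rankFeatures <- function(table, onePerSubject = FALSE, mode = "auto") {
  if (onePerSubject) {
    ord <- order(table$subject_id, seq_len(nrow(table)))
    table <- table[ord, ]
    table <- table[!duplicated(table$subject_id), ]
  }
  x <- table[table$label == "unhealed", , drop = FALSE]
  y <- table[table$label == "healed", , drop = FALSE]
  if (nrow(x) == 0 || nrow(y) == 0)
    stop("both healing groups must be non-empty")
  fn <- featureNames()
  res <- lapply(fn, function(f) {
    mw <- mannWhitneyU(x[[f]], y[[f]], mode)
    data.frame(feature = f, U = mw$U, p_value = mw$p.value,
               cohens_d = effectSize(x[[f]], y[[f]], "cohens_d"),
               rank_biserial = effectSize(x[[f]], y[[f]],
                                          "rank_biserial"),
               significant = mw$p.value < 0.05)
  })
  res <- do.call(rbind, res)
  res <- res[order(res$p_value, seq_len(nrow(res))), ]
  rownames(res) <- NULL
  attr(res, "n_tests") <- length(fn)
  res
}

#' Boxplot of one feature by healing group
#'
#' Draws group boxplots with the individual values overlaid, the usual
#' presentation for small-cohort feature comparisons.
#'
#' @param table a feature table with a \code{label} column.
#' @param feature feature name to plot.
#' @param file optional PNG path; when given the plot is written there.
#' @return \code{file}, invisibly.
#' @export
plotFeatureBoxplot <- function(table, feature, file = NULL) {
  if (!is.null(file)) {
    png(file, width = 480, height = 480)
    on.exit(dev.off())
  }
  v <- table[[feature]]
  g <- factor(table$label, levels = c("unhealed", "healed"))
  boxplot(v ~ g, xlab = "", ylab = feature, outline = FALSE,
          ylim = range(v))
  stripchart(v ~ g, vertical = TRUE, method = "jitter", add = TRUE,
             pch = 1)
  invisible(file)
}
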