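#' Repeated-holdout split specification
#'
#' @param trainFraction fraction of rows used for training (default
#'   0.70).
#' @param nRepetitions number of random divisions (default 20).
#' @param stratified preserve class proportions in each split (default
#'   TRUE; with 17 healed wounds of 64, unstratified draws can leave a
#'   test side with almost no healed cases).
#' @param masterSeed seed from which the per-repetition split seeds are
#'   derived.
#' @return a named list of class \code{"SplitSpec"}.
#' @export
splitSpec <- function(trainFraction = 0.70, nRepetitions = 20L,
                      stratified = TRUE, masterSeed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1, nRepetitions >= 1)
  structure(list(trainFraction = trainFraction,
                 nRepetitions = as.integer(nRepetitions),
                 stratified = isTRUE(stratified),
                 masterSeed = as.integer(masterSeed)),
            class = "SplitSpec")
}

#' Split a feature table into train and test rows
#'
#' Stratified draws take, per class, a test set of size
#' floor(n_class * (1 - trainFraction)) — with 47/17 rows at 0.70 this
#' gives a 45-row training set and a 19-row test set (14 unhealed, 5
#' healed). Unstratified draws sample the test rows from the pooled
#' table and re-draw (deterministically) if a class goes missing from
#' either side. Deterministic in (spec, repIndex).
#'
#' @param table a feature table with a \code{label} column.
#' @param spec a \code{\link{splitSpec}} list.
#' @param repIndex repetition index (>= 1).
#' @return list with integer row indices \code{train} and \code{test};
#'   disjoint, jointly covering all rows.
#' @export
splitData <- function(table, spec = splitSpec(), repIndex = 1L) {
  labs <- table$label
  if (length(unique(labs)) < 2)
    stop("both classes must be present before splitting")
  n <- nrow(table)
  .withSeed(deriveSeed(spec$masterSeed, 5000L + repIndex), {
    if (spec$stratified) {
      test <- integer(0)
      for (cl in sort(unique(labs))) {
        idx <- which(labs == cl)
        nTest <- floor(length(idx) * (1 - spec$trainFraction))
        test <- c(test, sort(sample(idx, nTest)))
      }
      test <- sort(test)
    } else {
      nTest <- floor(n * (1 - spec$trainFraction))
      for (attempt in 1:100) {
        test <- sort(sample(n, nTest))
        ok <- length(unique(labs[test])) == 2 &&
          length(unique(labs[-test])) == 2
        if (ok) break
      }
      if (!ok) stop("could not draw a split containing both classes")
    }
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Confusion counts with unhealed as the positive class
#'
#' @param truth,predicted equal-length label vectors over
#'   \code{"healed"}/\code{"unhealed"}.
#' @return named vector (TP, FN, TN, FP): TP counts unhealed wounds
#'   predicted unhealed, TN healed predicted healed.
#' @export
confusionCounts <- function(truth, predicted) {
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  ok <- c("healed", "unhealed")
  if (!all(truth %in% ok) || !all(predicted %in% ok))
    stop("labels must be 'healed' or 'unhealed'")
  c(TP = sum(truth == "unhealed" & predicted == "unhealed"),
    FN = sum(truth == "unhealed" & predicted == "healed"),
    TN = sum(truth == "healed" & predicted == "healed"),
    FP = sum(truth == "healed" & predicted == "unhealed"))
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity is the correct detection rate of unhealed wounds,
#' TP / (TP + FN); specificity the rate for healed wounds,
#' TN / (TN + FP).
#'
#' @param counts vector from \code{\link{confusionCounts}}.
#' @return named vector (sensitivity, specificity).
#' @export
sensitivitySpecificity <- function(counts) {
  if (counts["TP"] + counts["FN"] == 0 ||
      counts["TN"] + counts["FP"] == 0)
    stop("a class is empty; sensitivity/specificity undefined")
  c(sensitivity = unname(counts["TP"] / (counts["TP"] + counts["FN"])),
    specificity = unname(counts["TN"] / (counts["TN"] + counts["FP"])))
}

#' ROC curve over the unique score thresholds
#'
#' Sweeps the decision threshold over the unique predicted
#' probabilities plus a sentinel above the maximum, labelling a case
#' positive (unhealed) when its probability is at or above the
#' threshold; the curve runs from (0, 0) to (1, 1).
#'
#' @param probabilities predicted probabilities of the positive class.
#' @param truth label vector over \code{"healed"}/\code{"unhealed"}.
#' @return data.frame with columns \code{threshold}, \code{fpr},
#'   \code{tpr}, ordered from (0, 0) to (1, 1).
#' @export
rocCurve <- function(probabilities, truth) {
  pos <- truth == "unhealed"
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  th <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  pts <- t(vapply(th, function(t) {
    pred <- probabilities >= t
    c(fpr = sum(pred & !pos) / nNeg, tpr = sum(pred & pos) / nPos)
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Area under a ROC curve (trapezoid rule)
#'
#' Equals the Mann-Whitney concordance probability of the underlying
#' scores (ties counted half).
#'
#' @param points data.frame from \code{\link{rocCurve}}.
#' @return AUC in [0, 1].
#' @export
aucTrapezoid <- function(points) {
  o <- order(points$fpr, points$tpr)
  x <- points$fpr[o]; y <- points$tpr[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Run the repeated 70/30 evaluation experiment
#'
#' Per repetition: split the feature table; fit PCA on the training
#' rows only; project both sides to the leading three components;
#' select and train the classifier (width by maximum evidence) on the
#' training scores; evaluate sensitivity and specificity on both
#' sides. Aggregates the mean and SD over successful repetitions,
#' identifies the best repetition (maximal test sensitivity,
#' tie-broken by test specificity), and reports the training-set ROC
#' and AUC of that best model. Test rows influence nothing but their
#' own scores and predictions.
#'
#' @param table a feature table (see \code{\link{extractFeatureTable}}).
#' @param spec a \code{\link{splitSpec}} list.
#' @param config a named list of pipeline settings; see
#'   \code{\link{pipelineConfig}}.
#' @return list of class \code{"EvaluationReport"}: \code{perRepetition}
#'   data.frame (repetition, selected h, train/test sensitivity and
#'   specificity, threshold), \code{summary} (mean and SD for each
#'   rate), \code{best} (repetition index and its rates), \code{roc}
#'   and \code{auc} for the best repetition's training set, and the
#'   full \code{config} echo.
#' @export
runExperiment <- function(table, spec = splitSpec(),
                          config = pipelineConfig()) {
  labs <- table$label
  feats <- featureMatrix(table)
  reps <- list(); failures <- integer(0)
  models <- vector("list", spec$nRepetitions)
  splits <- vector("list", spec$nRepetitions)
  for (r in seq_len(spec$nRepetitions)) {
    res <- tryCatch({
      sp <- splitData(table, spec, r)
      pca <- fitPCA(feats[sp$train, , drop = FALSE],
                    standardise = config$standardise,
                    kSelected = config$k)
      sTrain <- projectScores(pca, feats[sp$train, , drop = FALSE])
      sTest <- projectScores(pca, feats[sp$test, , drop = FALSE])
      tTrain <- as.numeric(labs[sp$train] == "unhealed")
      sel <- selectArchitecture(sTrain, tTrain,
                                hRange = config$hRange,
                                restarts = config$restarts,
                                seed = deriveSeed(spec$masterSeed, r),
                                alpha0 = config$alpha0,
                                maxOuter = config$maxOuter,
                                maxit = config$maxit)
      predTrain <- predictBNN(sel$model, sTrain, config$threshold)
      predTest <- predictBNN(sel$model, sTest, config$threshold)
      ssTrain <- sensitivitySpecificity(
        confusionCounts(labs[sp$train], predTrain$label))
      ssTest <- sensitivitySpecificity(
        confusionCounts(labs[sp$test], predTest$label))
      list(row = data.frame(
             repetition = r, h = sel$h,
             trainSensitivity = ssTrain["sensitivity"],
             trainSpecificity = ssTrain["specificity"],
             testSensitivity = ssTest["sensitivity"],
             testSpecificity = ssTest["specificity"],
             threshold = config$threshold, row.names = NULL),
           model = sel$model, pca = pca, split = sp)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("repetition ", r, " failed: ", conditionMessage(res))
      failures <- c(failures, r)
    } else {
      reps[[length(reps) + 1L]] <- res$row
      models[[r]] <- list(model = res$model, pca = res$pca)
      splits[[r]] <- res$split
    }
  }
  if (!length(reps)) stop("every repetition failed")
  per <- do.call(rbind, reps)
  cols <- c("trainSensitivity", "trainSpecificity",
            "testSensitivity", "testSpecificity")
  summ <- data.frame(metric = cols,
                     mean = vapply(cols, function(c) mean(per[[c]]), 0),
                     sd = vapply(cols, function(c) sd(per[[c]]), 0),
                     row.names = NULL)
  bestIdx <- order(-per$testSensitivity, -per$testSpecificity)[1]
  bestRep <- per$repetition[bestIdx]
  bm <- models[[bestRep]]
  sp <- splits[[bestRep]]
  sTrain <- projectScores(bm$pca, feats[sp$train, , drop = FALSE])
  probs <- bnnForward(bm$model, sTrain)
  roc <- rocCurve(probs, labs[sp$train])
  structure(list(perRepetition = per, summary = summ,
                 best = per[bestIdx, ], bestModel = bm$model,
                 bestPCA = bm$pca, roc = roc,
                 auc = aucTrapezoid(roc), failures = failures,
                 config = config, spec = unclass(spec)),
            class = "EvaluationReport")
}

#' Pipeline configuration for the evaluation experiment
#'
#' @param k number of principal components fed to the classifier
#'   (default 3).
#' @param hRange candidate hidden-layer widths (default 1..9).
#' @param restarts random restarts per width (default 3 in the
#'   20-repetition harness; \code{\link{selectArchitecture}} alone
#'   defaults to 5).
#' @param alpha0 initial weight decay.
#' @param threshold decision threshold on the unhealed probability.
#' @param standardise standardise features before PCA (default FALSE).
#' @param maxOuter,maxit training caps, see \code{\link{trainBNN}}.
#' @return a named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(k = 3L, hRange = 1:9, restarts = 3L,
                           alpha0 = 0.1, threshold = 0.5,
                           standardise = FALSE, maxOuter = 20L,
                           maxit = 500L) {
  structure(list(k = as.integer(k), hRange = hRange,
                 restarts = as.integer(restarts), alpha0 = alpha0,
                 threshold = threshold,
                 standardise = isTRUE(standardise),
                 maxOuter = as.integer(maxOuter),
                 maxit = as.integer(maxit)),
            class = "PipelineConfig")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("Repeated-holdout evaluation:",
      nrow(x$perRepetition), "successful repetitions\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %.2f%% (SD %.2f)\n", s$metric[i],
                100 * s$mean[i], 100 * s$sd[i]))
  cat(sprintf("  best repetition %d: test %.2f%% / %.2f%% (h = %d)\n",
              x$best$repetition, 100 * x$best$testSensitivity,
              100 * x$best$testSpecificity, x$best$h))
  cat(sprintf("  training-set AUC of best model: %.3f\n", x$auc))
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' Writes the per-repetition table, summary statistics, best-repetition
#' rates, training ROC/AUC of the best model, and the full resolved
#' configuration.
#'
#' @param report an \code{"EvaluationReport"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  obj <- list(perRepetition = report$perRepetition,
              summary = report$summary, best = report$best,
              auc = report$auc, roc = report$roc,
              failures = report$failures,
              config = unclass(report$config), spec = report$spec)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
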