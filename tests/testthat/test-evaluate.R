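test_that("stratified 70/30 splits have the documented per-class sizes", {
  tab <- data.frame(label = rep(c("unhealed", "healed"), c(47, 17)))
  sp <- splitData(tab, splitSpec(masterSeed = 3), 1)
  expect_length(sp$train, 45)
  expect_length(sp$test, 19)
  expect_equal(sum(tab$label[sp$test] == "unhealed"), 14)
  expect_equal(sum(tab$label[sp$test] == "healed"), 5)
  # disjoint and covering
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:64)
  # deterministic per repetition index
  expect_identical(sp, splitData(tab, splitSpec(masterSeed = 3), 1))
  sp2 <- splitData(tab, splitSpec(masterSeed = 3), 2)
  expect_false(identical(sp$test, sp2$test))
  oneClass <- data.frame(label = rep("unhealed", 10))
  expect_error(splitData(oneClass, splitSpec(), 1), "both classes")
})

test_that("unstratified splits still contain both classes on both sides", {
  tab <- data.frame(label = rep(c("unhealed", "healed"), c(47, 17)))
  spec <- splitSpec(stratified = FALSE, masterSeed = 11)
  for (r in 1:10) {
    sp <- splitData(tab, spec, r)
    expect_length(unique(tab$label[sp$train]), 2)
    expect_length(unique(tab$label[sp$test]), 2)
  }
})

test_that("confusion counts and rates match the hand-worked example", {
  truth <- rep(c("unhealed", "healed"), c(14, 5))
  pred <- c(rep("unhealed", 11), rep("healed", 3),
            rep("healed", 3), rep("unhealed", 2))
  cc <- confusionCounts(truth, pred)
  expect_equal(unname(cc), c(11, 3, 3, 2))
  ss <- sensitivitySpecificity(cc)
  expect_equal(unname(ss["sensitivity"]), 11 / 14)
  expect_equal(unname(ss["specificity"]), 0.6)
  perfect <- confusionCounts(truth, truth)
  expect_equal(unname(perfect[c("FN", "FP")]), c(0, 0))
  allPos <- sensitivitySpecificity(
    confusionCounts(truth, rep("unhealed", 19)))
  expect_equal(unname(allPos), c(1, 0))
  expect_error(confusionCounts(character(0), character(0)), "empty")
  expect_error(confusionCounts(truth, rep("maybe", 19)), "labels")
})

test_that("ROC curves span (0,0) to (1,1) and AUC equals concordance", {
  roc <- rocCurve(c(0.9, 0.8, 0.3, 0.2),
                  rep(c("unhealed", "healed"), each = 2))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect separation
  expect_equal(aucTrapezoid(roc), 1)
  set.seed(81)
  for (rep in 1:20) {
    prob <- round(runif(40), 2)     # force ties
    truth <- sample(rep(c("unhealed", "healed"), c(25, 15)))
    auc <- aucTrapezoid(rocCurve(prob, truth))
    expect_equal(auc, concordanceAUC(prob, truth), tolerance = 1e-12)
    # reversing the scores mirrors the AUC
    aucRev <- aucTrapezoid(rocCurve(1 - prob, truth))
    expect_equal(aucRev, 1 - auc, tolerance = 1e-12)
    # monotone after sorting by threshold
    roc <- rocCurve(prob, truth)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  }
  expect_error(rocCurve(runif(4), rep("unhealed", 4)), "both classes")
})

test_that("AUC agrees with pROC on random scores", {
  set.seed(82)
  prob <- runif(60)
  truth <- sample(rep(c("unhealed", "healed"), c(40, 20)))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = prob,
    levels = c("healed", "unhealed"), direction = "<", quiet = TRUE)))
  expect_equal(aucTrapezoid(rocCurve(prob, truth)), ref,
               tolerance = 1e-12)
  # label-independent scores sit near the diagonal
  expect_lt(abs(aucTrapezoid(rocCurve(runif(500),
    sample(rep(c("unhealed", "healed"), 250)))) - 0.5), 0.1)
})

test_that("a single-repetition experiment reports that repetition as best", {
  tab <- smallCohortTable()
  rep1 <- runExperiment(tab, splitSpec(nRepetitions = 1, masterSeed = 4),
                        pipelineConfig(hRange = 1:2, restarts = 1))
  expect_equal(nrow(rep1$perRepetition), 1)
  expect_equal(rep1$best$repetition, 1)
  expect_true(all(rep1$perRepetition$testSensitivity >= 0 &
                    rep1$perRepetition$testSensitivity <= 1))
  expect_gte(rep1$auc, 0)
  expect_lte(rep1$auc, 1)
})

test_that("perturbing held-out rows leaves the trained model bit-identical", {
  tab <- smallCohortTable()
  spec <- splitSpec(nRepetitions = 1, masterSeed = 4)
  cfg <- pipelineConfig(hRange = 1:2, restarts = 1)
  sp <- splitData(tab, spec, 1)
  a <- runExperiment(tab, spec, cfg)
  mutated <- tab
  mutated[sp$test, featureNames()] <-
    mutated[sp$test, featureNames()] * 3 + 1
  b <- runExperiment(mutated, spec, cfg)
  expect_identical(thermaheal:::.packParams(a$bestModel),
                   thermaheal:::.packParams(b$bestModel))
  expect_identical(a$bestPCA@rotation, b$bestPCA@rotation)
})

test_that("experiment reports are serialisable and self-describing", {
  tab <- smallCohortTable()
  rep1 <- runExperiment(tab, splitSpec(nRepetitions = 2, masterSeed = 6),
                        pipelineConfig(hRange = 1:2, restarts = 1))
  expect_equal(rep1$summary$metric,
               c("trainSensitivity", "trainSpecificity",
                 "testSensitivity", "testSpecificity"))
  f <- withr::local_tempfile(fileext = ".json")
  writeEvaluationReport(rep1, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$auc, rep1$auc)
  expect_equal(back$config$restarts, 1)
  expect_length(back$perRepetition$repetition, 2)
})
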