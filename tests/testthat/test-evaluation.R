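test_that("one-vs-rest relabeling merges the rest classes in ascending order", {
  study <- generateStudy(sensorSimConfig(nPerClass = 10L, seed = 5L))
  dt <- buildDecisionTable(study, "M1", "wooden")
  b7 <- relabelOneVsRest(dt, "7")
  expect_equal(sum(classLabelsOf(b7) == "7"), 10L)
  expect_equal(sum(classLabelsOf(b7) == "156"), 30L)
  b1 <- relabelOneVsRest(dt, "1")
  expect_setequal(unique(classLabelsOf(b1)), c("1", "567"))
  ## idempotence on an already binary table
  expect_identical(classLabelsOf(relabelOneVsRest(b7, "7")),
                   classLabelsOf(b7))
  expect_error(relabelOneVsRest(b7, "5"), "not present")
})

test_that("split plans are stratified, disjoint, covering and reproducible", {
  study <- generateStudy(sensorSimConfig(nPerClass = 10L, seed = 5L))
  dt <- buildDecisionTable(study, "M1", "wooden")
  plan <- makeSplitPlan(dt, seed = 9L)
  expect_length(plan@splits, 25L)   # 5 groups x 5 per group
  labs <- classLabelsOf(dt)
  for (sp in plan@splits) {
    expect_length(sp$test, 20L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), seq_len(40L))
    expect_equal(unname(table(labs[sp$test])), rep(5L, 4L),
                 ignore_attr = TRUE)
  }
  expect_identical(makeSplitPlan(dt, seed = 9L)@splits, plan@splits)
  expect_false(identical(makeSplitPlan(dt, seed = 10L)@splits, plan@splits))

  ## degenerate fractions are rejected
  expect_error(makeSplitPlan(dt, testFraction = 0.01), "empty test")
  tiny <- makeTable(matrix(rnorm(18), 6L), c("5", "5", "7"))
  expect_error(makeSplitPlan(tiny, testFraction = 0.5), ">= 2 rows")
})

test_that("metrics match a hand confusion-matrix oracle", {
  m <- metricsFromPredictions(c("7", "7", "156", "156"),
                              c("7", "156", "156", "156"))
  expect_equal(m$acc_7, 0.5)
  expect_equal(m$acc_156, 1)
  expect_equal(m$acc_balanced, 0.75)
  expect_equal(m$tpr_7, 1)
  expect_equal(m$tpr_156, 2 / 3)
  expect_equal(m$acc_global, 0.75)
  expect_equal(m$cov_global, 1)

  perfect <- metricsFromPredictions(c("1", "5", "6", "7"),
                                    c("1", "5", "6", "7"))
  expect_true(all(unlist(perfect[setdiff(names(perfect), "n_splits")]) == 1))

  ## tpr of a never-predicted class is 0 by convention
  m2 <- metricsFromPredictions(c("7", "156"), c("156", "156"))
  expect_equal(m2$tpr_7, 0)

  expect_error(metricsFromPredictions(c("7", "7"), "7"), "equal length")

  ## balanced accuracy is the unweighted mean of per-class accuracies
  set.seed(42)
  classes <- c("1", "5", "6", "7")
  for (i in 1:20) {
    truth <- sample(classes, 30L, replace = TRUE)
    pred <- sample(classes, 30L, replace = TRUE)
    if (length(unique(truth)) < 4L) next
    m <- metricsFromPredictions(truth, pred)
    expect_lt(abs(m$acc_balanced -
                    mean(c(m$acc_1, m$acc_5, m$acc_6, m$acc_7))), 1e-12)
  }
})

test_that("MCCV averages per-split records and handles degenerate classifiers", {
  study <- generateStudy(fastConfig())
  dt <- relabelOneVsRest(buildDecisionTable(study, "M1", "wooden"), "7")
  one <- makeSplitPlan(dt, nGroups = 1L, nPerGroup = 1L, seed = 4L)
  rec <- runMCCV(dt, one, "euclidean.1nn")
  sp <- one@splits[[1L]]
  direct <- metricsFromPredictions(
    classLabelsOf(dt)[sp$test],
    predictTable(dt[, sp$train], dt[, sp$test], "euclidean.1nn"))
  for (cl in c("acc_global", "acc_balanced", "tpr_7", "tpr_156"))
    expect_equal(rec[[cl]], direct[[cl]])
  expect_equal(rec$n_splits, 1L)

  ## a constant prediction on a balanced binary table scores 0.5 balanced
  constPred <- rep("156", 10L)
  truth <- rep(c("7", "156"), 5L)
  expect_equal(metricsFromPredictions(truth, constPred)$acc_balanced, 0.5)

  ## averaging identity over several splits
  plan <- makeSplitPlan(dt, nGroups = 2L, nPerGroup = 3L, seed = 4L)
  rec6 <- runMCCV(dt, plan, "manhattan.811", keepSplits = TRUE)
  per <- attr(rec6, "per_split")
  expect_equal(nrow(per), 6L)
  expect_equal(rec6$acc_balanced, mean(per$acc_balanced))
  expect_equal(rec6$cov_global, 1)
})

test_that("separation monotonicity and the binary-task advantage hold", {
  accAt <- function(sep) {
    study <- generateStudy(sensorSimConfig(separation = sep, nPerClass = 5L,
                                           seed = 31L))
    dt <- buildDecisionTable(study, "M1", "wooden")
    plan <- makeSplitPlan(dt, seed = 17L)
    runMCCV(dt, plan, "euclidean.1nn", keepSplits = TRUE)
  }
  recs <- lapply(c(0.05, 0.4, 1.5), accAt)
  acc <- vapply(recs, function(r) r$acc_balanced, numeric(1L))
  se <- vapply(recs, function(r) {
    p <- attr(r, "per_split")$acc_balanced
    stats::sd(p) / sqrt(length(p))
  }, numeric(1L))
  ## non-decreasing in class separation, within one standard error
  expect_gte(acc[2L], acc[1L] - se[1L])
  expect_gte(acc[3L], acc[2L] - se[2L])

  ## 1-NN class-7 predictions are invariant under rest-label merging: the
  ## nearest training row does not move when classes 1, 5, 6 are renamed,
  ## so the 7-vs-rest tpr_7 equals the 4-class tpr_7 exactly (same splits)
  study <- generateStudy(sensorSimConfig(separation = 0.05, nPerClass = 5L,
                                         seed = 31L))
  dt <- buildDecisionTable(study, "M1", "wooden")
  planA <- makeSplitPlan(dt, seed = 17L)
  for (nm in c("euclidean.1nn", "manhattan.1nn")) {
    multi <- runMCCV(dt, planA, nm)
    bin <- runMCCV(relabelOneVsRest(dt, "7"), planA, nm)
    expect_equal(bin$tpr_7, multi$tpr_7)
    ## both sit strictly inside (0, 1) in this overlap regime, so the
    ## equality is informative
    expect_gt(bin$tpr_7, 0)
    expect_lt(bin$tpr_7, 1)
  }

  ## vote-pooling classifiers are NOT invariant: merging the rest classes
  ## pools their votes, which changes (and here depresses) class-7 calls
  m811 <- runMCCV(dt, planA, "euclidean.811")
  b811 <- runMCCV(relabelOneVsRest(dt, "7"), planA, "euclidean.811")
  expect_false(isTRUE(all.equal(b811$tpr_7, m811$tpr_7)))
})
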