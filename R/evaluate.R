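## MCCV evaluation harness: stratified random train/test splits shared by
## all classifiers, per-class accuracy / balanced accuracy / true positive
## rate, and one-vs-rest relabeling.

#' Relabel a decision table for a one-vs-rest variant
#'
#' Rows of the positive class keep their label; all remaining rows receive a
#' single merged rest-label formed by concatenating the other labels in
#' ascending order (e.g. positive 7 on a {1,5,6,7} table yields classes
#' {"7", "156"}). Relabeling an already binary table with its positive class
#' is the identity.
#'
#' @param table a [DecisionTable-class].
#' @param positive label of the positive class; must be present.
#' @return A relabeled [DecisionTable-class].
#' @examples
#' study <- generateStudy(sensorSimConfig(nPerClass = 3, seed = 1))
#' dt <- buildDecisionTable(study, "M1", "wooden")
#' table(classLabelsOf(relabelOneVsRest(dt, "7")))
#' @export
relabelOneVsRest <- function(table, positive) {
  stopifnot(is(table, "DecisionTable"))
  positive <- as.character(positive)
  labs <- classLabelsOf(table)
  if (!positive %in% labs)
    stop(sprintf("positive class '%s' not present (classes: %s)", positive,
                 paste(orderLabels(unique(labs)), collapse = ", ")))
  rest <- setdiff(orderLabels(unique(labs)), positive)
  merged <- paste(rest, collapse = "")
  newLabs <- ifelse(labs == positive, positive, merged)
  out <- table
  SummarizedExperiment::colData(out)$class <- newLabs
  out
}

#' Draw a stratified Monte Carlo cross-validation split plan
#'
#' Generates `nGroups * nPerGroup` independent stratified random splits
#' (default 5 x 5 = 25, the 5xMCCV5 design): per split, each class
#' contributes `round(testFraction * n_class)` rows to the test part and the
#' remainder to training. The plan is reproducible from `seed` and is meant
#' to be reused for every classifier so all techniques see identical
#' subsets.
#'
#' @param table a [DecisionTable-class]; every class needs at least 2 rows.
#' @param nGroups,nPerGroup factorization of the number of splits.
#' @param testFraction fraction of each class assigned to test, in (0, 1).
#' @param seed integer seed.
#' @return A [SplitPlan-class].
#' @examples
#' study <- generateStudy(sensorSimConfig(nPerClass = 4, seed = 1))
#' makeSplitPlan(buildDecisionTable(study, "M1", "wooden"), seed = 7)
#' @export
makeSplitPlan <- function(table, nGroups = 5L, nPerGroup = 5L,
                          testFraction = 0.5, seed = 1L) {
  stopifnot(is(table, "DecisionTable"), testFraction > 0, testFraction < 1)
  labs <- classLabelsOf(table)
  counts <- table(labs)
  if (any(counts < 2L))
    stop(sprintf("every class needs >= 2 rows to stratify (smallest: %s with %d)",
                 names(counts)[which.min(counts)], min(counts)))
  nTest <- round(testFraction * counts)
  if (any(nTest < 1L) || any(nTest >= counts)) {
    bad <- names(counts)[which(nTest < 1L | nTest >= counts)[1L]]
    stop(sprintf(
      "testFraction %g leaves class '%s' with an empty test or train part",
      testFraction, bad))
  }
  nSplits <- as.integer(nGroups) * as.integer(nPerGroup)
  classes <- orderLabels(unique(labs))
  idxByClass <- lapply(classes, function(cl) which(labs == cl))
  names(idxByClass) <- classes
  splits <- withSeed(as.integer(seed), lapply(seq_len(nSplits), function(i) {
    test <- unlist(lapply(classes, function(cl) {
      sample(idxByClass[[cl]], nTest[[cl]])
    }), use.names = FALSE)
    test <- sort(test)
    list(train = setdiff(seq_along(labs), test), test = test)
  }))
  new("SplitPlan", splits = splits, nGroups = as.integer(nGroups),
      nPerGroup = as.integer(nPerGroup), testFraction = testFraction,
      seed = as.integer(seed))
}

#' Compute evaluation metrics from truth/prediction pairs
#'
#' Per class c: accuracy `acc_c` is the fraction of class-c objects
#' classified as c; the true positive rate `tpr_c` is the fraction of
#' objects *predicted* as c that truly are c (the precision analogue; 0 when
#' nothing is predicted c). `acc_global` is the overall fraction correct,
#' `acc_balanced` the unweighted mean of the per-class accuracies, and
#' `cov_global` the fraction of objects receiving any prediction (always 1
#' for the classifiers implemented here).
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes class set defining the per-class columns; defaults to the
#'   classes present in `truth`, in label order.
#' @return A one-row data.frame with columns `acc_global`, `cov_global`,
#'   `acc_<class>` per class, `acc_balanced`, `tpr_<class>` per class and
#'   `n_splits` (= 1).
#' @examples
#' metricsFromPredictions(c("7", "7", "156", "156"),
#'                        c("7", "156", "156", "156"))
#' @export
metricsFromPredictions <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted) || length(truth) == 0L)
    stop("truth and predicted must be non-empty vectors of equal length")
  if (is.null(classes)) classes <- orderLabels(unique(truth))
  accC <- vapply(classes, function(cl) {
    n <- sum(truth == cl)
    if (n == 0L) NA_real_ else sum(truth == cl & predicted == cl) / n
  }, numeric(1L))
  tprC <- vapply(classes, function(cl) {
    n <- sum(predicted == cl)
    if (n == 0L) 0 else sum(truth == cl & predicted == cl) / n
  }, numeric(1L))
  out <- data.frame(
    acc_global = mean(truth == predicted),
    cov_global = mean(!is.na(predicted)))
  for (cl in classes) out[[paste0("acc_", cl)]] <- accC[[cl]]
  out$acc_balanced <- mean(accC, na.rm = TRUE)
  for (cl in classes) out[[paste0("tpr_", cl)]] <- tprC[[cl]]
  out$n_splits <- 1L
  out
}

#' Run Monte Carlo cross-validation of one classifier
#'
#' For every split of the plan, classifies the test rows using the train
#' rows (no fitting: all ten classifiers are lazy) and computes a metrics
#' record; the per-split records are averaged arithmetically (macro over
#' splits).
#'
#' @param table a [DecisionTable-class].
#' @param plan a [SplitPlan-class] valid for `table`.
#' @param spec a [ClassifierSpec-class] or canonical name.
#' @param keepSplits attach the per-split records as attribute
#'   `"per_split"`?
#' @return A one-row data.frame as in [metricsFromPredictions()], with
#'   `n_splits` the number of splits averaged.
#' @examples
#' study <- generateStudy(sensorSimConfig(nPerClass = 4, seed = 1))
#' dt <- relabelOneVsRest(buildDecisionTable(study, "M1", "wooden"), "7")
#' plan <- makeSplitPlan(dt, nGroups = 2, nPerGroup = 2, seed = 3)
#' runMCCV(dt, plan, "euclidean.1nn")
#' @export
runMCCV <- function(table, plan, spec, keepSplits = FALSE) {
  stopifnot(is(table, "DecisionTable"), is(plan, "SplitPlan"))
  if (is.character(spec)) spec <- classifierSpec(spec)
  labs <- classLabelsOf(table)
  feats <- featureMatrix(table)
  classes <- orderLabels(unique(labs))
  recs <- lapply(plan@splits, function(sp) {
    pred <- predictCore(feats[, sp$train, drop = FALSE], labs[sp$train],
                        feats[, sp$test, drop = FALSE], spec)
    metricsFromPredictions(labs[sp$test], pred, classes = classes)
  })
  all <- do.call(rbind, recs)
  avg <- as.data.frame(t(colMeans(all)))
  avg$n_splits <- length(recs)
  if (keepSplits) attr(avg, "per_split") <- all
  avg
}
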