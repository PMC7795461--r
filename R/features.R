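## Feature extraction: one six-descriptor vector per recording, taken at a
## fixed reference second of the exposure phase (270 s by default, after
## signal stabilization), optionally baseline-differential corrected by
## subtracting the object's own regeneration-phase (ambient air) level.

#' Extract the six-descriptor feature vector of one recording
#'
#' The descriptor of sensor s is the exposure reading at the reference
#' second `tRef` (optionally the mean over a centered window of
#' `smoothWindow` seconds). With `baselineCorrect = TRUE` the ambient-air
#' reference level of the same object's 600-s regeneration phase is
#' subtracted per sensor: its arithmetic mean by default
#' (`baselineStat = "mean"`), or the final reading (`"last"`).
#'
#' @param recording a [SensorRecording-class].
#' @param tRef reference second into the exposure phase (1-based, 1..600).
#' @param baselineCorrect subtract the regeneration-phase reference level?
#' @param baselineStat how the 600 regeneration readings are aggregated.
#' @param smoothWindow odd window length in seconds centered on `tRef`
#'   (clipped at the phase ends); 1 = the single reference reading.
#' @return Named numeric vector of length 6 (sensor order).
#' @examples
#' m <- generateMeasurement(sensorSimConfig(seed = 1), "7", "M1", "wooden", 3)
#' extractFeatures(m, baselineCorrect = TRUE)
#' @export
extractFeatures <- function(recording, tRef = 270L, baselineCorrect = FALSE,
                            baselineStat = c("mean", "last"),
                            smoothWindow = 1L) {
  stopifnot(is(recording, "SensorRecording"))
  tRef <- as.integer(tRef)
  if (tRef < 1L || tRef > PHASE_LENGTH)
    stop(sprintf("tRef must lie in 1..%d", PHASE_LENGTH))
  baselineStat <- match.arg(baselineStat)
  smoothWindow <- as.integer(smoothWindow)
  if (smoothWindow < 1L || smoothWindow %% 2L == 0L)
    stop("smoothWindow must be a positive odd integer")

  if (smoothWindow == 1L) {
    feat <- recording@exposure[tRef, ]
  } else {
    h <- (smoothWindow - 1L) %/% 2L
    win <- max(1L, tRef - h):min(PHASE_LENGTH, tRef + h)
    feat <- colMeans(recording@exposure[win, , drop = FALSE])
  }
  if (baselineCorrect) {
    ref <- switch(baselineStat,
                  mean = colMeans(recording@regeneration),
                  last = recording@regeneration[PHASE_LENGTH, ])
    feat <- feat - ref
  }
  stats::setNames(as.numeric(feat), sensorNames())
}

#' Build a decision table from a study
#'
#' Filters the study to one device x insert run (either may be `NULL` to
#' pool), extracts one feature vector per object and assembles them into a
#' [DecisionTable-class] (a `SummarizedExperiment` with the 6 x N descriptor
#' matrix as the `"features"` assay and object metadata in `colData`). The
#' (device, insert, baselineCorrect) triple reproduces the study's eight
#' test options, see [optionCatalogue()].
#'
#' @param study a [SensorStudy-class].
#' @param device,insert filters; `NULL` keeps all.
#' @param baselineCorrect apply baseline differential correction?
#' @param tRef,baselineStat,smoothWindow passed to [extractFeatures()].
#' @return A [DecisionTable-class].
#' @examples
#' study <- generateStudy(sensorSimConfig(nPerClass = 3, seed = 1))
#' buildDecisionTable(study, "M1", "wooden", baselineCorrect = FALSE)
#' @export
buildDecisionTable <- function(study, device = NULL, insert = NULL,
                               baselineCorrect = FALSE, tRef = 270L,
                               baselineStat = "mean", smoothWindow = 1L) {
  sub <- filterStudy(study, device = device, insert = insert)
  if (length(sub) == 0L)
    stop(sprintf("no measurements for device=%s, insert=%s",
                 paste(device %||% "any", collapse = "/"),
                 paste(insert %||% "any", collapse = "/")))
  feats <- vapply(sub, extractFeatures, numeric(N_SENSORS), tRef = tRef,
                  baselineCorrect = baselineCorrect,
                  baselineStat = baselineStat, smoothWindow = smoothWindow)
  rownames(feats) <- sensorNames()
  cd <- S4Vectors::DataFrame(
    object_id = vapply(sub, function(r) r@objectId, ""),
    class = vapply(sub, function(r) r@classLabel, ""),
    device = vapply(sub, function(r) r@device, ""),
    insert = vapply(sub, function(r) r@insert, ""))
  colnames(feats) <- cd$object_id
  rownames(cd) <- cd$object_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feats), colData = cd,
    metadata = list(tRef = as.integer(tRef), baselineStat = baselineStat,
                    smoothWindow = as.integer(smoothWindow)))
  new("DecisionTable", se, baselineCorrected = isTRUE(baselineCorrect))
}

#' Build the decision table of a named test option
#'
#' Convenience wrapper resolving an option key ("I".."VIII") through
#' [optionCatalogue()] and calling [buildDecisionTable()].
#'
#' @param study a [SensorStudy-class].
#' @param option one of "I".."VIII".
#' @param ... passed to [buildDecisionTable()].
#' @return A [DecisionTable-class].
#' @export
buildOptionTable <- function(study, option, ...) {
  cat_ <- optionCatalogue()
  row <- cat_[cat_$option == option, ]
  if (nrow(row) != 1L)
    stop(sprintf("unknown option '%s' (valid: %s)", option,
                 paste(cat_$option, collapse = ", ")))
  buildDecisionTable(study, device = row$device, insert = row$insert,
                     baselineCorrect = row$baseline_correct, ...)
}

#' Export a decision table as CSV
#'
#' Header: `object_id,class,device,insert,TGS823,...,TGS2603`.
#'
#' @param table a [DecisionTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(table, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(table))
  out <- cbind(cd[c("object_id", "class", "device", "insert")],
               as.data.frame(t(featureMatrix(table))))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
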