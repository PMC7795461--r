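#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata
#' @importClassesFrom S4Vectors SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## SensorSimConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic e-nose study generator
#'
#' Holds every parameter of the synthetic six-sensor recording model: the
#' class-dependent plateau amplitudes, device-specific additive baselines,
#' chamber-insert odour shifts, exponential rise/decay time constants, the
#' per-second Gaussian noise level, the number of objects per class and the
#' master seed. Objects are created with [sensorSimConfig()].
#'
#' The exposure-phase model for sensor s at second t (1..600) is
#' \deqn{baseline[device,s] + shift[insert,s] + A[class,s](1 - e^{-t/\tau_r})
#'   + \epsilon_{t,s},}
#' and the regeneration phase decays back towards the device baseline as
#' \deqn{baseline[device,s] + A[class,s] e^{-t/\tau_d} + \epsilon_{t,s},}
#' with \eqn{\epsilon \sim N(0, \sigma^2)} i.i.d. per second and sensor.
#' Class 1 is the empty test chamber, so its amplitude row is identically
#' zero. The rise constant must satisfy \eqn{e^{-270/\tau_r} < 0.01} so the
#' signal has stabilized at the 270-s reference second.
#'
#' @slot amplitude 4 x 6 matrix of plateau rises (sensor units), rows
#'   named "1","5","6","7"; row "1" is all zero.
#' @slot baseline 2 x 6 matrix of device offsets, rows "M1","M2".
#' @slot insertShift 2 x 6 matrix of insert odour contributions, rows
#'   "wooden","polystyrene" (applied during exposure only).
#' @slot tauRise,tauDecay exponential time constants in seconds.
#' @slot noiseSd standard deviation of the per-second Gaussian noise.
#' @slot nPerClass objects generated per class for each device x insert run.
#' @slot separation scalar recorded for provenance: the factor by which the
#'   base inter-class amplitude differences (classes 5,6,7) were scaled.
#' @slot seed master seed from which all per-object seeds are derived.
#'
#' @seealso [sensorSimConfig()], [generateStudy()]
#' @export
setClass("SensorSimConfig",
  representation(
    amplitude = "matrix",
    baseline = "matrix",
    insertShift = "matrix",
    tauRise = "numeric",
    tauDecay = "numeric",
    noiseSd = "numeric",
    nPerClass = "integer",
    separation = "numeric",
    seed = "integer"
  )
)

setValidity("SensorSimConfig", function(object) {
  msg <- character()
  if (!identical(dim(object@amplitude), c(4L, 6L)) ||
      !identical(rownames(object@amplitude), classLevels()))
    msg <- c(msg, "amplitude must be a 4 x 6 matrix with rows 1,5,6,7")
  else if (any(object@amplitude["1", ] != 0))
    msg <- c(msg, "class-1 (empty chamber) amplitude row must be zero")
  if (any(object@amplitude < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (!identical(dim(object@baseline), c(2L, 6L)) ||
      !identical(rownames(object@baseline), deviceLevels()))
    msg <- c(msg, "baseline must be a 2 x 6 matrix with rows M1,M2")
  if (!identical(dim(object@insertShift), c(2L, 6L)) ||
      !identical(rownames(object@insertShift), insertLevels()))
    msg <- c(msg, "insertShift must be a 2 x 6 matrix with rows wooden,polystyrene")
  if (object@tauRise <= 0 || object@tauDecay <= 0)
    msg <- c(msg, "tauRise and tauDecay must be positive")
  if (exp(-270 / object@tauRise) >= 0.01)
    msg <- c(msg, "tauRise too slow: exp(-270/tauRise) must be < 0.01 so the signal is stabilized at the reference second")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nPerClass < 1L) msg <- c(msg, "nPerClass must be >= 1")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SensorRecording / SensorStudy
## ---------------------------------------------------------------------------

#' A single e-nose measurement of one object
#'
#' One object's full measurement: a 600-s exposure phase (air sampled above
#' the object in the test chamber) followed by a 600-s regeneration phase
#' (filtered ambient air), both recorded once per second on each of the six
#' TGS sensors, plus the object metadata.
#'
#' @slot objectId unique identifier.
#' @slot classLabel one of "1","5","6","7" (empty chamber, young workers,
#'   old workers, workers from laying-worker colonies).
#' @slot device "M1" or "M2".
#' @slot insert "wooden" or "polystyrene".
#' @slot exposure,regeneration 600 x 6 numeric matrices, columns in
#'   [sensorNames()] order, one row per second (1-based).
#'
#' @seealso [generateMeasurement()], [readDeviceCSV()]
#' @export
setClass("SensorRecording",
  representation(
    objectId = "character",
    classLabel = "character",
    device = "character",
    insert = "character",
    exposure = "matrix",
    regeneration = "matrix"
  )
)

setValidity("SensorRecording", function(object) {
  msg <- character()
  okMat <- function(m) {
    identical(dim(m), c(PHASE_LENGTH, N_SENSORS)) &&
      identical(colnames(m), sensorNames()) && all(is.finite(m))
  }
  if (length(object@objectId) != 1L) msg <- c(msg, "objectId must be a single string")
  if (!object@classLabel %in% classLevels())
    msg <- c(msg, sprintf("unknown class label '%s' (valid: %s)",
                          object@classLabel, paste(classLevels(), collapse = ", ")))
  if (!object@device %in% deviceLevels())
    msg <- c(msg, sprintf("unknown device '%s' (valid: %s)",
                          object@device, paste(deviceLevels(), collapse = ", ")))
  if (!object@insert %in% insertLevels())
    msg <- c(msg, sprintf("unknown insert '%s' (valid: %s)",
                          object@insert, paste(insertLevels(), collapse = ", ")))
  if (!okMat(object@exposure))
    msg <- c(msg, "exposure must be a finite 600 x 6 matrix with TGS column names")
  if (!okMat(object@regeneration))
    msg <- c(msg, "regeneration must be a finite 600 x 6 matrix with TGS column names")
  if (length(msg)) msg else TRUE
})

#' A collection of sensor recordings
#'
#' A [S4Vectors::SimpleList] of [SensorRecording-class] objects, typically one
#' full study (all devices, inserts, classes and replicates).
#'
#' @seealso [generateStudy()], [readDeviceCSV()]
#' @export
setClass("SensorStudy", contains = "SimpleList",
         prototype = prototype(elementType = "SensorRecording"))

#' @rdname SensorStudy-class
#' @param recordings a list of [SensorRecording-class] objects.
#' @return A `SensorStudy`.
#' @export
SensorStudy <- function(recordings = list()) {
  ans <- S4Vectors::SimpleList(recordings)
  ans <- new("SensorStudy", ans)
  ans@elementType <- "SensorRecording"
  ok <- vapply(recordings, is, TRUE, class2 = "SensorRecording")
  if (!all(ok)) stop("all elements must be SensorRecording objects")
  names(ans) <- vapply(recordings, function(r) r@objectId, "")
  ans
}

## ---------------------------------------------------------------------------
## DecisionTable
## ---------------------------------------------------------------------------

#' Decision table of six-descriptor feature vectors
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one column
#' per measured object: the `"features"` assay is the 6 (sensors) x N
#' (objects) matrix of descriptors, and `colData` carries `object_id`,
#' `class`, `device` and `insert`. Conditional attributes are numeric; the
#' decision (class) is categorical. The per-attribute extrema over the rows
#' currently in the table are available via [attrRanges()].
#'
#' @slot baselineCorrected whether descriptors are baseline-differential
#'   corrected (exposure reading minus the mean regeneration level).
#'
#' @seealso [buildDecisionTable()], [attrRanges()], [classLabelsOf()]
#' @export
setClass("DecisionTable", contains = "SummarizedExperiment",
         representation(baselineCorrected = "logical"))

setValidity("DecisionTable", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must contain a 'features' assay")
  else {
    a <- SummarizedExperiment::assay(object, "features")
    if (nrow(a) != N_SENSORS || !identical(rownames(a), sensorNames()))
      msg <- c(msg, "'features' assay must have the six TGS sensors as rows")
    if (ncol(a) > 0 && !all(is.finite(a)))
      msg <- c(msg, "all descriptor values must be finite")
  }
  need <- c("object_id", "class", "device", "insert")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, sprintf("colData must contain: %s", paste(need, collapse = ", ")))
  if (length(object@baselineCorrected) != 1L)
    msg <- c(msg, "baselineCorrected must be a single logical")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ClassSignature
## ---------------------------------------------------------------------------

#' Per-class scent signature
#'
#' The radar-chart signature of each decision class: per sensor attribute,
#' all rows of a decision table are min-max normalized into [a, b], averaged
#' within each class, and the class means are squared. With a >= 0 every
#' signature value lies in [a^2, b^2].
#'
#' @slot values nClass x 6 matrix (rows: classes in label order; columns:
#'   sensors), unitless.
#' @slot a,b normalization interval endpoints.
#'
#' @seealso [classSignature()], [minmaxNormalize()]
#' @export
setClass("ClassSignature",
  representation(values = "matrix", a = "numeric", b = "numeric"))

setValidity("ClassSignature", function(object) {
  msg <- character()
  if (!identical(colnames(object@values), sensorNames()))
    msg <- c(msg, "signature columns must be the six TGS sensors")
  if (length(object@a) != 1L || length(object@b) != 1L || object@b <= object@a)
    msg <- c(msg, "normalization interval must satisfy b > a")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ClassifierSpec
## ---------------------------------------------------------------------------

#' Specification of one of the ten classifiers
#'
#' The ten classifiers are 1-nearest-neighbour (`1nn`) and inverse-distance
#' weighted voting (`811`) under each of four metrics (canberra, euclidean,
#' manhattan, maxmin-normalized euclidean), plus two epsilon-indiscernibility
#' Naive Bayes variants (`nb`: sum of per-attribute class indiscernibility
#' ratios; `nb2`: the same sum weighted by the class prior). Create specs by
#' canonical name with [classifierSpec()]; the full list is
#' [classifierNames()].
#'
#' @slot name canonical name, e.g. "euclidean.1nn" or "eps=0.01.nb2".
#' @slot family one of "1nn", "811", "nb", "nb2".
#' @slot metric one of "canberra", "euclidean", "manhattan", "maxmin"
#'   (ignored by nb/nb2).
#' @slot eps indiscernibility window half-width as a fraction of each
#'   attribute's training range (nb/nb2 only).
#' @slot delta additive regularizer of the 811 vote weight 1/(d + delta).
#'
#' @export
setClass("ClassifierSpec",
  representation(name = "character", family = "character",
                 metric = "character", eps = "numeric", delta = "numeric"))

setValidity("ClassifierSpec", function(object) {
  msg <- character()
  if (!object@family %in% c("1nn", "811", "nb", "nb2"))
    msg <- c(msg, "family must be one of 1nn, 811, nb, nb2")
  if (object@family %in% c("1nn", "811") &&
      !object@metric %in% c("canberra", "euclidean", "manhattan", "maxmin"))
    msg <- c(msg, "metric must be one of canberra, euclidean, manhattan, maxmin")
  if (object@family %in% c("nb", "nb2") &&
      (object@eps <= 0 || object@eps > 1))
    msg <- c(msg, "eps must lie in (0, 1]")
  if (object@delta <= 0) msg <- c(msg, "delta must be > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SplitPlan
## ---------------------------------------------------------------------------

#' Monte Carlo cross-validation split plan
#'
#' A fixed list of stratified random train/test partitions of a decision
#' table, reused across all classifiers so that every technique is evaluated
#' on identical subsets. The default 5 groups x 5 splits gives the 25
#' repetitions of the 5xMCCV5 design.
#'
#' @slot splits list of `list(train = <idx>, test = <idx>)` integer index
#'   pairs; within each split, train and test are disjoint and cover the
#'   table.
#' @slot nGroups,nPerGroup the factorization of the number of splits.
#' @slot testFraction fraction of each class assigned to the test part.
#' @slot seed the seed the plan was drawn from.
#'
#' @seealso [makeSplitPlan()], [runMCCV()]
#' @export
setClass("SplitPlan",
  representation(splits = "list", nGroups = "integer", nPerGroup = "integer",
                 testFraction = "numeric", seed = "integer"))
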