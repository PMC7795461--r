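#' Accessors for decision tables and signatures
#'
#' `featureMatrix()` returns the 6 x N descriptor matrix of a
#' [DecisionTable-class]; `classLabelsOf()` its per-object decision labels;
#' `attrRanges()` the per-attribute minima and maxima over the rows of the
#' table; `isBaselineCorrected()` whether baseline differential correction
#' was applied; `signatureValues()` the numeric matrix of a
#' [ClassSignature-class].
#'
#' @param x a `DecisionTable` (or `ClassSignature` for `signatureValues`).
#' @return `featureMatrix`: numeric matrix (sensors x objects);
#'   `classLabelsOf`: character vector; `attrRanges`: list with numeric
#'   components `min` and `max` (length 6, named by sensor);
#'   `isBaselineCorrected`: logical; `signatureValues`: numeric matrix
#'   (classes x sensors).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("classLabelsOf", function(x) standardGeneric("classLabelsOf"))

#' @rdname accessors
#' @export
setGeneric("attrRanges", function(x) standardGeneric("attrRanges"))

#' @rdname accessors
#' @export
setGeneric("isBaselineCorrected",
           function(x) standardGeneric("isBaselineCorrected"))

#' @rdname accessors
#' @export
setGeneric("signatureValues", function(x) standardGeneric("signatureValues"))

#' @rdname accessors
#' @export
setMethod("featureMatrix", "DecisionTable", function(x) {
  SummarizedExperiment::assay(x, "features")
})

#' @rdname accessors
#' @export
setMethod("classLabelsOf", "DecisionTable", function(x) {
  as.character(SummarizedExperiment::colData(x)$class)
})

#' @rdname accessors
#' @export
setMethod("attrRanges", "DecisionTable", function(x) {
  a <- featureMatrix(x)
  list(min = apply(a, 1L, min), max = apply(a, 1L, max))
})

#' @rdname accessors
#' @export
setMethod("isBaselineCorrected", "DecisionTable",
          function(x) x@baselineCorrected)

#' @rdname accessors
#' @export
setMethod("signatureValues", "ClassSignature", function(x) x@values)

setMethod("show", "SensorRecording", function(object) {
  cat(sprintf(
    "SensorRecording '%s' | class %s | device %s | %s insert\n",
    object@objectId, object@classLabel, object@device, object@insert))
  cat(sprintf("  exposure / regeneration: %d s x %d sensors each\n",
              nrow(object@exposure), ncol(object@exposure)))
})

setMethod("show", "SensorStudy", function(object) {
  cl <- table(vapply(object, function(r) r@classLabel, ""))
  cat(sprintf("SensorStudy with %d recordings (classes: %s)\n",
              length(object),
              paste(sprintf("%s=%d", names(cl), cl), collapse = ", ")))
})

setMethod("show", "SensorSimConfig", function(object) {
  cat("SensorSimConfig\n")
  cat(sprintf("  tauRise = %g s, tauDecay = %g s, noiseSd = %g\n",
              object@tauRise, object@tauDecay, object@noiseSd))
  cat(sprintf("  nPerClass = %d, separation = %g, seed = %d\n",
              object@nPerClass, object@separation, object@seed))
  cat("  max amplitude per class:",
      paste(sprintf("%s=%g", rownames(object@amplitude),
                    apply(object@amplitude, 1L, max)), collapse = ", "), "\n")
})

setMethod("show", "DecisionTable", function(object) {
  cat(sprintf(
    "DecisionTable: %d objects x %d sensor attributes%s\n",
    ncol(object), nrow(object),
    if (object@baselineCorrected) " (baseline corrected)" else ""))
  cl <- table(classLabelsOf(object))
  cat("  classes:", paste(sprintf("%s=%d", names(cl), cl), collapse = ", "), "\n")
})

setMethod("show", "ClassSignature", function(object) {
  cat(sprintf("ClassSignature on [%g, %g] for classes: %s\n",
              object@a, object@b,
              paste(rownames(object@values), collapse = ", ")))
  print(round(object@values, 4))
})

setMethod("show", "ClassifierSpec", function(object) {
  cat(sprintf("ClassifierSpec '%s' (family %s%s)\n", object@name,
              object@family,
              if (object@family %in% c("1nn", "811"))
                paste0(", metric ", object@metric)
              else sprintf(", eps = %g", object@eps)))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf(
    "SplitPlan: %d splits (%d groups x %d), test fraction %g, seed %d\n",
    length(object@splits), object@nGroups, object@nPerGroup,
    object@testFraction, object@seed))
})
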