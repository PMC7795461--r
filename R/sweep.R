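## Option x variant x classifier sweep: the full evaluation grid over the
## eight device/insert/baseline-correction options, the all-classes and four
## one-vs-rest variants, and the ten classifiers, with best-classifier
## summaries.

VARIANT_KEYS <- c("all", "1vsall", "5vsall", "6vsall", "7vsall")

#' Evaluation variant keys
#'
#' `"all"` keeps the four classes; `"<c>vsall"` relabels class c against the
#' merged rest (e.g. `"7vsall"` gives classes {"7", "156"}).
#'
#' @return Character vector of the five variant keys.
#' @export
variantKeys <- function() VARIANT_KEYS

applyVariant <- function(table, variant) {
  if (identical(variant, "all")) return(table)
  m <- regmatches(variant, regexec("^([1567])vsall$", variant))[[1L]]
  if (length(m) != 2L)
    stop(sprintf("unknown variant '%s' (valid: %s)", variant,
                 paste(VARIANT_KEYS, collapse = ", ")))
  relabelOneVsRest(table, m[2L])
}

#' Run the option x variant x classifier sweep
#'
#' For each requested option (see [optionCatalogue()]) the decision table is
#' built from the study; for each variant it is (possibly) relabeled
#' one-vs-rest; a single stratified split plan is drawn per (device, insert,
#' variant) — deliberately independent of the baseline-correction flag, so
#' each corrected option reuses the plan of its uncorrected twin and the
#' correction effect is evaluated on paired subsets — and every classifier
#' is run over the same plan.
#'
#' @param study a [SensorStudy-class] containing the devices/inserts the
#'   requested options need.
#' @param options subset of "I".."VIII".
#' @param variants subset of [variantKeys()].
#' @param specs classifier names or [ClassifierSpec-class] objects (default
#'   all ten).
#' @param nGroups,nPerGroup,testFraction split-plan parameters (default the
#'   25-split 5xMCCV5 design with a 50/50 split).
#' @param seed master seed; per-cell plan seeds are derived from it.
#' @param tRef feature reference second.
#' @return A long-format data.frame keyed by (`option`, `variant`,
#'   `classifier`) with the metric columns of [metricsFromPredictions()];
#'   columns not applicable to a variant (other class sets) are `NA`.
#' @examples
#' study <- generateStudy(sensorSimConfig(nPerClass = 4, seed = 1))
#' res <- runOptionSweep(study, options = "I", variants = "7vsall",
#'                       specs = c("euclidean.1nn", "canberra.1nn"),
#'                       nGroups = 2, nPerGroup = 2, seed = 5)
#' res[, c("option", "variant", "classifier", "acc_balanced", "tpr_7")]
#' @export
runOptionSweep <- function(study, options = optionCatalogue()$option,
                           variants = variantKeys(),
                           specs = classifierNames(),
                           nGroups = 5L, nPerGroup = 5L, testFraction = 0.5,
                           seed = 1L, tRef = 270L) {
  cat_ <- optionCatalogue()
  bad <- setdiff(options, cat_$option)
  if (length(bad))
    stop(sprintf("unknown option '%s' (valid: %s)", bad[1L],
                 paste(cat_$option, collapse = ", ")))
  bad <- setdiff(variants, VARIANT_KEYS)
  if (length(bad))
    stop(sprintf("unknown variant '%s' (valid: %s)", bad[1L],
                 paste(VARIANT_KEYS, collapse = ", ")))
  specs <- lapply(specs, function(s)
    if (is.character(s)) classifierSpec(s) else s)
  if (length(specs) == 0L) return(data.frame())

  out <- list()
  for (opt in options) {
    row <- cat_[cat_$option == opt, ]
    dt0 <- buildDecisionTable(study, device = row$device, insert = row$insert,
                              baselineCorrect = row$baseline_correct,
                              tRef = tRef)
    for (variant in variants) {
      dt <- applyVariant(dt0, variant)
      ## plan seed excludes the baseline flag: corrected twins share splits
      planSeed <- hashSeed(seed, row$device, row$insert, variant)
      plan <- makeSplitPlan(dt, nGroups = nGroups, nPerGroup = nPerGroup,
                            testFraction = testFraction, seed = planSeed)
      for (spec in specs) {
        rec <- runMCCV(dt, plan, spec)
        rec <- cbind(data.frame(option = opt, variant = variant,
                                classifier = spec@name,
                                stringsAsFactors = FALSE), rec)
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  rbindFill(out)
}

#' Best classifier per sweep cell
#'
#' For one metric column, reduces a sweep result to the best classifier and
#' its value per (option, variant) cell — the shape of the best-classifier
#' summary tables. Ties list every co-best classifier.
#'
#' @param results a data.frame from [runOptionSweep()].
#' @param metric a metric column name, e.g. `"acc_balanced"` or `"tpr_7"`.
#' @return A data.frame with columns `option`, `variant`, `classifier`
#'   (comma-separated on ties) and `value`.
#' @export
sweepBest <- function(results, metric = "acc_balanced") {
  if (!metric %in% names(results))
    stop(sprintf("metric '%s' not found in results", metric))
  cells <- unique(results[c("option", "variant")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$option == cells$option[i] &
                     results$variant == cells$variant[i], ]
    v <- sub[[metric]]
    if (all(is.na(v))) return(NULL)
    best <- which(v == max(v, na.rm = TRUE))
    data.frame(option = cells$option[i], variant = cells$variant[i],
               classifier = paste(sub$classifier[best], collapse = ", "),
               value = max(v, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  rbindFill(rows)
}

#' Spread of a metric across classifiers
#'
#' The best-minus-worst range of a metric column within each
#' (option, variant) cell — the "largest discrepancy between the best and
#' the worst classifier" summary.
#'
#' @inheritParams sweepBest
#' @return A data.frame with columns `option`, `variant`, `min`, `max`,
#'   `spread`.
#' @export
sweepSpread <- function(results, metric = "tpr_7") {
  if (!metric %in% names(results))
    stop(sprintf("metric '%s' not found in results", metric))
  cells <- unique(results[c("option", "variant")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    v <- results[results$option == cells$option[i] &
                   results$variant == cells$variant[i], metric]
    if (all(is.na(v))) return(NULL)
    data.frame(option = cells$option[i], variant = cells$variant[i],
               min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
               spread = max(v, na.rm = TRUE) - min(v, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  rbindFill(rows)
}

#' Write sweep results as CSV
#'
#' @param results a data.frame from [runOptionSweep()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResultsCSV <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
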