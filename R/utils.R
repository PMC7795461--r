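## Shared constants and small helpers.

#' Sensor, class, device and insert vocabularies
#'
#' The six Figaro TGS metal-oxide sensors of the array, in the fixed column
#' order used throughout the package, and the valid class / device / insert
#' labels.
#'
#' @return A character vector.
#' @examples
#' sensorNames()
#' @export
sensorNames <- function() {
  c("TGS823", "TGS826", "TGS832", "TGS2600", "TGS2602", "TGS2603")
}

#' @rdname sensorNames
#' @export
classLevels <- function() c("1", "5", "6", "7")

#' @rdname sensorNames
#' @export
deviceLevels <- function() c("M1", "M2")

#' @rdname sensorNames
#' @export
insertLevels <- function() c("wooden", "polystyrene")

## seconds per measurement phase
PHASE_LENGTH <- 600L

## number of sensors
N_SENSORS <- 6L

#' Test-option catalogue
#'
#' The eight evaluation options combine device (M1/M2), chamber insert
#' (wooden/polystyrene) and whether baseline differential correction is
#' applied: I-IV are uncorrected, V-VIII are their baseline-corrected twins.
#'
#' @return A data.frame with columns `option`, `device`, `insert`,
#'   `baseline_correct`.
#' @examples
#' optionCatalogue()
#' @export
optionCatalogue <- function() {
  data.frame(
    option = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
    device = rep(c("M1", "M1", "M2", "M2"), 2),
    insert = rep(c("wooden", "polystyrene"), 4),
    baseline_correct = rep(c(FALSE, TRUE), each = 4),
    stringsAsFactors = FALSE
  )
}

## Deterministic label ordering used by every tie-break: labels that parse as
## numbers ascend numerically (so merged rest-labels such as "156" sort after
## the single digits); anything non-numeric sorts after those, alphabetically.
orderLabels <- function(labels) {
  labels <- unique(as.character(labels))
  num <- suppressWarnings(as.numeric(labels))
  c(labels[!is.na(num)][order(num[!is.na(num)])], sort(labels[is.na(num)]))
}

## djb2-style string hash folded into [0, 2^31 - 2]; used to derive per-object
## and per-plan seeds from a run seed plus identifying strings, so that every
## random draw is reproducible without relying on global RNG state ordering.
hashSeed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "|")
  h <- 5381
  for (b in utf8ToInt(key)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

## Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
## state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## rbind data.frames whose column sets differ (missing columns filled NA),
## preserving first-seen column order.
rbindFill <- function(dfs) {
  dfs <- dfs[vapply(dfs, function(d) !is.null(d) && nrow(d) > 0, TRUE)]
  if (length(dfs) == 0L) return(data.frame())
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  })
  do.call(rbind, c(dfs, list(make.row.names = FALSE)))
}
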