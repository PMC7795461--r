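## CSV dialect of the recorder: one file per device x insert run, one row per
## second and phase, header
##   object_id,class,device,insert,phase,second,TGS823,...,TGS2603
## with seconds 1..600 per phase and readings serialized to 6 decimals.

csvHeader <- function() {
  c("object_id", "class", "device", "insert", "phase", "second", sensorNames())
}

#' Write recordings to a device CSV
#'
#' Serializes a set of recordings (typically one device x insert run) into
#' the recorder's CSV dialect: 1200 rows per object (600 exposure seconds
#' followed by 600 regeneration seconds), readings with 6 decimal places.
#'
#' @param study a [SensorStudy-class] (or list of recordings).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readDeviceCSV()], [writeStudyCSV()]
#' @export
writeDeviceCSV <- function(study, path) {
  rows <- lapply(study, function(r) {
    meta <- data.frame(
      object_id = r@objectId, class = r@classLabel, device = r@device,
      insert = r@insert,
      phase = rep(c("exposure", "regeneration"), each = PHASE_LENGTH),
      second = rep(seq_len(PHASE_LENGTH), 2L),
      stringsAsFactors = FALSE)
    vals <- rbind(r@exposure, r@regeneration)
    cbind(meta, as.data.frame(apply(vals, 2L, sprintf, fmt = "%.6f")))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a full study as one CSV per device/insert run
#'
#' @param study a [SensorStudy-class].
#' @param dir output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
writeStudyCSV <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (device in deviceLevels()) {
    for (insert in insertLevels()) {
      sub <- filterStudy(study, device = device, insert = insert)
      if (length(sub) == 0L) next
      p <- file.path(dir, sprintf("signals_%s_%s.csv", device, insert))
      writeDeviceCSV(sub, p)
      paths[sprintf("%s_%s", device, insert)] <- p
    }
  }
  invisible(paths)
}

#' Read a device CSV back into recordings
#'
#' Parses a file in the recorder's CSV dialect and reassembles complete
#' recordings. Each object must have exactly 600 exposure and 600
#' regeneration seconds (any order on disk; rows are sorted by second);
#' missing or duplicated seconds, unknown phases and non-numeric readings
#' raise errors naming the object and line.
#'
#' @param path CSV file path.
#' @return A [SensorStudy-class]; empty if the file holds only the header.
#' @seealso [writeDeviceCSV()]
#' @export
readDeviceCSV <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  if (!identical(names(raw), csvHeader()))
    stop(sprintf("%s: malformed header (expected %s)", path,
                 paste(csvHeader(), collapse = ",")))
  if (nrow(raw) == 0L) return(SensorStudy())

  line <- seq_len(nrow(raw)) + 1L   # 1 header line
  badPhase <- !(raw$phase %in% c("exposure", "regeneration"))
  if (any(badPhase)) {
    i <- which(badPhase)[1L]
    stop(sprintf("%s line %d (object %s): unknown phase '%s'",
                 path, line[i], raw$object_id[i], raw$phase[i]))
  }
  vals <- suppressWarnings(
    vapply(sensorNames(), function(s) as.numeric(raw[[s]]),
           numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, 1L, N_SENSORS,
                                      dimnames = list(NULL, sensorNames()))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]
    stop(sprintf("%s line %d (object %s): non-numeric reading in column %s",
                 path, line[i], raw$object_id[i], sensorNames()[bad[1L, 2L]]))
  }
  sec <- suppressWarnings(as.integer(raw$second))
  if (anyNA(sec)) {
    i <- which(is.na(sec))[1L]
    stop(sprintf("%s line %d (object %s): non-integer second '%s'",
                 path, line[i], raw$object_id[i], raw$second[i]))
  }

  recs <- list()
  for (oid in unique(raw$object_id)) {
    sel <- raw$object_id == oid
    meta <- raw[which(sel)[1L], c("class", "device", "insert")]
    mats <- list()
    for (ph in c("exposure", "regeneration")) {
      rs <- which(sel & raw$phase == ph)
      got <- sort(sec[rs])
      if (!identical(got, seq_len(PHASE_LENGTH))) {
        missing <- setdiff(seq_len(PHASE_LENGTH), sec[rs])
        stop(sprintf(
          "%s (object %s): %s phase has %d rows, expected 600%s",
          path, oid, ph, length(rs),
          if (length(missing)) sprintf(" (first missing second: %d)",
                                       missing[1L]) else " (duplicated seconds)"))
      }
      ord <- rs[order(sec[rs])]
      m <- vals[ord, , drop = FALSE]
      colnames(m) <- sensorNames()
      mats[[ph]] <- m
    }
    recs[[oid]] <- new("SensorRecording", objectId = oid,
                       classLabel = meta$class, device = meta$device,
                       insert = meta$insert, exposure = mats$exposure,
                       regeneration = mats$regeneration)
  }
  SensorStudy(unname(recs))
}

#' Read a directory of device CSVs
#'
#' @param dir directory containing `signals_<device>_<insert>.csv` files.
#' @return A single merged [SensorStudy-class].
#' @export
readStudyCSV <- function(dir) {
  files <- list.files(dir, pattern = "^signals_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0L)
    stop(sprintf("no signals_*.csv files found in %s", dir))
  recs <- unlist(lapply(files, function(f) as.list(readDeviceCSV(f))),
                 recursive = FALSE)
  SensorStudy(recs)
}
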