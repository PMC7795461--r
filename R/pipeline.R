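## End-to-end pipeline glue: a serializable run configuration, a simulate
## command writing the four signal CSVs, and an evaluate command producing
## the sweep results, best-classifier summaries and class signatures.

#' Default run configuration
#'
#' A nested list fully describing a pipeline run; serializable to YAML with
#' [writeRunConfig()] and restored with [readRunConfig()]. Every artifact a
#' command writes is regenerable from the copied configuration alone.
#'
#' @param seed global seed.
#' @return A nested list with components `generator` (separation,
#'   n_per_class, tau_rise, tau_decay, noise_sd or NULL for the 1\%-of-max
#'   default), `features` (t_ref, baseline_stat), `evaluation` (options,
#'   variants, classifiers, n_groups, n_per_group, test_fraction) and
#'   `seed`.
#' @examples
#' str(defaultRunConfig())
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    generator = list(separation = 1, n_per_class = 10L, tau_rise = 40,
                     tau_decay = 40, noise_sd = NULL),
    features = list(t_ref = 270L, baseline_stat = "mean"),
    evaluation = list(options = optionCatalogue()$option,
                      variants = variantKeys(),
                      classifiers = classifierNames(),
                      n_groups = 5L, n_per_group = 5L, test_fraction = 0.5),
    seed = as.integer(seed)
  )
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @param config a run configuration list.
#' @return `readRunConfig`: the configuration list (missing fields filled
#'   from [defaultRunConfig()]); `writeRunConfig`: `path`, invisibly.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  for (sec in c("generator", "features", "evaluation"))
    for (k in names(def[[sec]]))
      if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- def[[sec]][[k]]
  if (is.null(cfg$seed)) cfg$seed <- def$seed
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

configToSimConfig <- function(config) {
  g <- config$generator
  sensorSimConfig(separation = g$separation, nPerClass = g$n_per_class,
                  seed = config$seed, tauRise = g$tau_rise,
                  tauDecay = g$tau_decay, noiseSd = g$noise_sd)
}

stageLog <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Simulate a study and write the signal CSVs
#'
#' Generates the synthetic study defined by the configuration and writes
#' one signal CSV per device x insert run (four files for a full study), a
#' `manifest.csv` listing per-file object counts, and a copy of the
#' configuration as `run_config.yaml`.
#'
#' @param config a run configuration list (see [defaultRunConfig()]).
#' @param outDir writable output directory (created if missing).
#' @return Named vector of signal CSV paths, invisibly.
#' @export
cmdSimulate <- function(config = defaultRunConfig(), outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  t0 <- Sys.time()
  simCfg <- configToSimConfig(config)
  study <- generateStudy(simCfg)
  stageLog("generated %d recordings in %.1f s", length(study),
           as.numeric(Sys.time() - t0, units = "secs"))
  paths <- writeStudyCSV(study, outDir)
  manifest <- data.frame(
    file = basename(paths),
    run = names(paths),
    n_objects = vapply(names(paths), function(k) {
      parts <- strsplit(k, "_")[[1L]]
      length(filterStudy(study, device = parts[1L], insert = parts[2L]))
    }, integer(1L)))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  writeRunConfig(config, file.path(outDir, "run_config.yaml"))
  stageLog("wrote %d signal CSVs + manifest to %s", length(paths), outDir)
  invisible(paths)
}

#' Evaluate a study: sweep, summaries and signatures
#'
#' Reads the signal CSVs from `signalDir` if present, otherwise generates
#' the study on the fly from the configuration. Runs the option x variant x
#' classifier sweep and writes `results.csv` (long format),
#' `best_<metric>.csv` best-classifier summaries for balanced accuracy and
#' the per-class true positive rates, and one class-signature CSV per
#' requested option. The configuration is copied to `run_config.yaml`.
#'
#' @param config a run configuration list.
#' @param outDir writable output directory (created if missing).
#' @param signalDir directory with `signals_*.csv`; `NULL` (default) means
#'   simulate in memory.
#' @return The sweep results data.frame, invisibly.
#' @export
cmdEvaluate <- function(config = defaultRunConfig(), outDir,
                        signalDir = NULL) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  ev <- config$evaluation
  ## validate classifier names up front so the error lists the valid ten
  specs <- lapply(ev$classifiers, classifierSpec)

  t0 <- Sys.time()
  if (!is.null(signalDir) &&
      length(list.files(signalDir, pattern = "^signals_.*\\.csv$"))) {
    study <- readStudyCSV(signalDir)
    stageLog("read %d recordings from %s", length(study), signalDir)
  } else {
    study <- generateStudy(configToSimConfig(config))
    stageLog("generated %d recordings", length(study))
  }

  results <- runOptionSweep(study, options = ev$options,
                            variants = ev$variants, specs = specs,
                            nGroups = ev$n_groups, nPerGroup = ev$n_per_group,
                            testFraction = ev$test_fraction,
                            seed = config$seed, tRef = config$features$t_ref)
  writeResultsCSV(results, file.path(outDir, "results.csv"))
  stageLog("sweep of %d cells done in %.1f s", nrow(results),
           as.numeric(Sys.time() - t0, units = "secs"))

  for (metric in c("acc_balanced",
                   grep("^tpr_", names(results), value = TRUE))) {
    best <- sweepBest(results, metric)
    utils::write.csv(best, file.path(outDir, sprintf("best_%s.csv", metric)),
                     row.names = FALSE, quote = FALSE)
  }
  for (opt in ev$options) {
    sig <- classSignature(buildOptionTable(study, opt,
                                           tRef = config$features$t_ref))
    writeSignatureCSV(sig, file.path(outDir,
                                     sprintf("signature_option_%s.csv", opt)))
  }
  writeRunConfig(config, file.path(outDir, "run_config.yaml"))
  stageLog("summaries and signatures written to %s", outDir)
  invisible(results)
}

#' Reference evaluation results from the original measurement campaign
#'
#' Loads the benchmark metric tables distributed with the package: the
#' published average MCCV results (25 splits, 7-vs-rest variant) of the ten
#' classifiers on the original, non-public device recordings, for the M1
#' device options (wooden/polystyrene chamber, with and without baseline
#' correction). Useful as a qualitative reference and for arithmetic
#' consistency checks; the synthetic pipeline does not reproduce these
#' numbers point-wise.
#'
#' @param option one of "I", "II", "V", "VI".
#' @return A data.frame with columns `classifier`, `acc_global`,
#'   `cov_global`, `acc_156`, `acc_7`, `acc_balanced`, `tpr_156`, `tpr_7`.
#' @examples
#' head(referenceResults("I"))
#' @export
referenceResults <- function(option = c("I", "II", "V", "VI")) {
  option <- match.arg(option)
  path <- system.file("extdata",
                      sprintf("reference_results_option_%s.csv", option),
                      package = "beeNose", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
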