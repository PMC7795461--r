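## Synthetic e-nose study generator.
##
## The generator emulates the measurement protocol of the bee study: each
## object is sampled for 600 s of exposure followed by 600 s of regeneration,
## once per second on six TGS sensors, on two devices (M1, M2) and with two
## chamber inserts (wooden, polystyrene). Class-dependent plateaus rise
## exponentially and stabilize well before the 270-s reference second.

defaultAmplitude <- function() {
  ## base plateau rises (sensor units) for the three bee classes; the empty
  ## chamber (class 1) contributes nothing above baseline + insert shift
  amp <- rbind(
    "1" = rep(0, 6),
    "5" = c(60, 45, 20, 70, 55, 40),    # young workers
    "6" = c(75, 60, 25, 85, 80, 65),    # old workers
    "7" = c(90, 80, 35, 95, 105, 95)    # workers from laying-worker colonies
  )
  colnames(amp) <- sensorNames()
  amp
}

defaultBaseline <- function() {
  ## twin prototype devices differ by small constant offsets
  b <- rbind(
    M1 = c(200, 180, 220, 150, 160, 170),
    M2 = c(210, 170, 230, 145, 175, 165)
  )
  colnames(b) <- sensorNames()
  b
}

defaultInsertShift <- function() {
  ## wood is the odour-noisier material; polystyrene is nearly neutral
  s <- rbind(
    wooden = c(8, 6, 4, 10, 12, 9),
    polystyrene = c(2, 1, 1, 3, 3, 2)
  )
  colnames(s) <- sensorNames()
  s
}

#' Create a synthetic-study generator configuration
#'
#' Builds a [SensorSimConfig-class]. The default amplitude, baseline and
#' insert-shift matrices define the study conditions; `separation` rescales
#' the inter-class amplitude differences of the three bee classes (5, 6, 7)
#' about their mean amplitude profile, so that `separation > 1` yields
#' near-separable classes and small values yield strongly overlapping ones.
#' The empty-chamber class 1 always has zero amplitude. The default noise
#' level is 1\% of the largest (post-separation) amplitude.
#'
#' @param separation scalar >= 0; factor applied to inter-class amplitude
#'   differences among classes 5, 6, 7.
#' @param nPerClass objects per class for each device x insert run.
#' @param seed master seed; all per-object seeds derive from it.
#' @param tauRise,tauDecay exponential rise/decay time constants (s). The
#'   rise constant must satisfy `exp(-270/tauRise) < 0.01`.
#' @param noiseSd per-second Gaussian noise SD; default `0.01 * max(amplitude)`.
#' @param amplitude,baseline,insertShift optional replacement matrices (see
#'   [SensorSimConfig-class] for shapes). `separation` is applied to
#'   `amplitude` after substitution.
#' @return A `SensorSimConfig`.
#' @examples
#' cfg <- sensorSimConfig(seed = 1)
#' cfg
#' @export
sensorSimConfig <- function(separation = 1, nPerClass = 10L, seed = 1L,
                            tauRise = 40, tauDecay = 40, noiseSd = NULL,
                            amplitude = defaultAmplitude(),
                            baseline = defaultBaseline(),
                            insertShift = defaultInsertShift()) {
  stopifnot(is.numeric(separation), length(separation) == 1L, separation >= 0)
  amp <- amplitude
  bee <- c("5", "6", "7")
  center <- colMeans(amp[bee, , drop = FALSE])
  for (cl in bee)
    amp[cl, ] <- center + separation * (amp[cl, ] - center)
  amp[amp < 0] <- 0
  if (is.null(noiseSd)) noiseSd <- 0.01 * max(amp)
  new("SensorSimConfig",
      amplitude = amp, baseline = baseline, insertShift = insertShift,
      tauRise = tauRise, tauDecay = tauDecay, noiseSd = noiseSd,
      nPerClass = as.integer(nPerClass), separation = separation,
      seed = as.integer(seed))
}

#' Generate one synthetic measurement
#'
#' Simulates a single object's exposure and regeneration phases under the
#' model described in [SensorSimConfig-class]. Identical arguments (including
#' `objectSeed`) reproduce bit-identical matrices; the caller's RNG state is
#' left untouched.
#'
#' @param config a [SensorSimConfig-class].
#' @param classLabel one of "1","5","6","7".
#' @param device "M1" or "M2".
#' @param insert "wooden" or "polystyrene".
#' @param objectSeed integer seed for this object's noise draws.
#' @param objectId identifier; autogenerated from the labels if omitted.
#' @return A [SensorRecording-class].
#' @examples
#' cfg <- sensorSimConfig(seed = 1)
#' m <- generateMeasurement(cfg, "7", "M1", "wooden", objectSeed = 42)
#' m
#' @export
generateMeasurement <- function(config, classLabel, device, insert,
                                objectSeed, objectId = NULL) {
  stopifnot(is(config, "SensorSimConfig"))
  classLabel <- as.character(classLabel)
  if (!classLabel %in% classLevels())
    stop(sprintf("unknown class label '%s' (valid: %s)", classLabel,
                 paste(classLevels(), collapse = ", ")))
  if (!device %in% deviceLevels())
    stop(sprintf("unknown device '%s' (valid: %s)", device,
                 paste(deviceLevels(), collapse = ", ")))
  if (!insert %in% insertLevels())
    stop(sprintf("unknown insert '%s' (valid: %s)", insert,
                 paste(insertLevels(), collapse = ", ")))
  if (is.null(objectId))
    objectId <- sprintf("%s_%s_c%s_s%d", device, insert, classLabel,
                        as.integer(objectSeed) %% 100000L)

  tt <- seq_len(PHASE_LENGTH)
  amp <- config@amplitude[classLabel, ]
  base <- config@baseline[device, ]
  shift <- config@insertShift[insert, ]

  rise <- 1 - exp(-tt / config@tauRise)       # 600-vector
  decay <- exp(-tt / config@tauDecay)

  expo <- outer(rep(1, PHASE_LENGTH), base + shift) + outer(rise, amp)
  regen <- outer(rep(1, PHASE_LENGTH), base) + outer(decay, amp)
  if (config@noiseSd > 0) {
    eps <- withSeed(as.integer(objectSeed),
                    stats::rnorm(2L * PHASE_LENGTH * N_SENSORS,
                                 sd = config@noiseSd))
    expo <- expo + matrix(eps[seq_len(PHASE_LENGTH * N_SENSORS)],
                          PHASE_LENGTH, N_SENSORS)
    regen <- regen + matrix(eps[-seq_len(PHASE_LENGTH * N_SENSORS)],
                            PHASE_LENGTH, N_SENSORS)
  }
  colnames(expo) <- colnames(regen) <- sensorNames()
  new("SensorRecording", objectId = objectId, classLabel = classLabel,
      device = device, insert = insert, exposure = expo, regeneration = regen)
}

#' Generate a full synthetic study
#'
#' For every device x insert combination, generates `nPerClass` objects of
#' each class in {1, 5, 6, 7}. Per-object seeds are derived by hashing the
#' master seed with the device, insert, class and replicate index, so the
#' study is reproducible element-wise and independent of generation order.
#'
#' @param config a [SensorSimConfig-class].
#' @return A [SensorStudy-class] with
#'   `4 * nPerClass * 2 devices * 2 inserts` recordings.
#' @examples
#' study <- generateStudy(sensorSimConfig(nPerClass = 2, seed = 1))
#' length(study)
#' @export
generateStudy <- function(config) {
  stopifnot(is(config, "SensorSimConfig"))
  recs <- list()
  for (device in deviceLevels()) {
    for (insert in insertLevels()) {
      for (cl in classLevels()) {
        for (rep_i in seq_len(config@nPerClass)) {
          seed_i <- hashSeed(config@seed, device, insert, cl, rep_i)
          oid <- sprintf("%s_%s_c%s_%02d", device, insert, cl, rep_i)
          recs[[oid]] <- generateMeasurement(config, cl, device, insert,
                                             objectSeed = seed_i,
                                             objectId = oid)
        }
      }
    }
  }
  SensorStudy(unname(recs))
}

#' Subset a study by metadata
#'
#' @param study a [SensorStudy-class].
#' @param device,insert,classLabel optional filters; `NULL` keeps all.
#' @return A `SensorStudy`.
#' @export
filterStudy <- function(study, device = NULL, insert = NULL,
                        classLabel = NULL) {
  keep <- vapply(study, function(r) {
    (is.null(device) || r@device %in% device) &&
      (is.null(insert) || r@insert %in% insert) &&
      (is.null(classLabel) || r@classLabel %in% classLabel)
  }, TRUE)
  SensorStudy(as.list(study)[keep])
}
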