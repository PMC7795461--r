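## Shared fixtures: small generator configs and hand-built tables/recordings.

## fast study: 3 objects per class, everything else at defaults
fastConfig <- function(...) sensorSimConfig(nPerClass = 3L, seed = 11L, ...)

## a DecisionTable built directly from a 6 x n feature matrix and labels
makeTable <- function(feats, labs, baselineCorrected = FALSE,
                      device = "M1", insert = "wooden") {
  feats <- as.matrix(feats)
  rownames(feats) <- sensorNames()
  colnames(feats) <- sprintf("o%02d", seq_len(ncol(feats)))
  cd <- S4Vectors::DataFrame(object_id = colnames(feats),
                             class = as.character(labs),
                             device = device, insert = insert)
  rownames(cd) <- colnames(feats)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feats), colData = cd)
  methods::new("DecisionTable", se, baselineCorrected = baselineCorrected)
}

## a random table: class-dependent means plus noise, labels cycled
randomTable <- function(n = 12L, classes = c("1", "5", "6", "7"), seed = 1L,
                        spreadSd = 1) {
  labs <- rep_len(classes, n)
  set.seed(seed)
  centers <- matrix(rnorm(6L * length(classes), sd = 3), 6L)
  feats <- centers[, match(labs, classes)] + matrix(rnorm(6L * n, sd = spreadSd), 6L)
  makeTable(feats, labs)
}

## a recording with constant exposure / regeneration levels per sensor
makeConstantRecording <- function(expoVal, regenVal, classLabel = "5",
                                  device = "M1", insert = "wooden") {
  expo <- matrix(rep(expoVal, each = 600L), 600L, 6L,
                 dimnames = list(NULL, sensorNames()))
  regen <- matrix(rep(regenVal, each = 600L), 600L, 6L,
                  dimnames = list(NULL, sensorNames()))
  methods::new("SensorRecording", objectId = "const", classLabel = classLabel,
               device = device, insert = insert,
               exposure = expo, regeneration = regen)
}

## discrete mean of exp(-t/tau) over t = 1..600 (the regeneration phase)
decayMean <- function(tau, n = 600L) {
  exp(-1 / tau) * (1 - exp(-n / tau)) / (1 - exp(-1 / tau)) / n
}

## scalar distance oracle, written independently of featureDistance()
oracleDistance <- function(metric, x, y, attrMin = NULL, attrMax = NULL) {
  s <- 0
  for (i in seq_along(x)) {
    s <- s + switch(metric,
      euclidean = (x[i] - y[i])^2,
      manhattan = abs(x[i] - y[i]),
      canberra = if (abs(x[i]) + abs(y[i]) == 0) 0
                 else abs(x[i] - y[i]) / (abs(x[i]) + abs(y[i])),
      maxmin = {
        r <- attrMax[i] - attrMin[i]
        xi <- if (r == 0) 0 else (x[i] - attrMin[i]) / r
        yi <- if (r == 0) 0 else (y[i] - attrMin[i]) / r
        (xi - yi)^2
      })
  }
  unname(if (metric %in% c("euclidean", "maxmin")) sqrt(s) else s)
}

## deterministic label order used by tie-break assertions
labelOrder <- function(labs) labs[order(as.numeric(labs))]

`%||%` <- function(a, b) if (is.null(a)) b else a
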