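test_that("feature extraction follows the reference-second and baseline rules", {
  ## constant signal in both phases: correction subtracts it away
  r <- makeConstantRecording(rep(4, 6), rep(4, 6))
  expect_equal(unname(extractFeatures(r, baselineCorrect = TRUE)), rep(0, 6))

  ## constant-baseline arithmetic: exposure 5, regeneration 2 -> 3
  r2 <- makeConstantRecording(rep(5, 6), rep(2, 6))
  expect_equal(unname(extractFeatures(r2, baselineCorrect = TRUE)), rep(3, 6))
  expect_equal(unname(extractFeatures(r2, baselineCorrect = FALSE)), rep(5, 6))

  ## noiseless synthetic object: closed-form oracle from generator equations
  cfg <- fastConfig(noiseSd = 0)
  m <- generateMeasurement(cfg, "6", "M2", "polystyrene", objectSeed = 1)
  amp <- cfg@amplitude["6", ]
  oracle <- amp * (1 - exp(-270 / cfg@tauRise)) -
    amp * decayMean(cfg@tauDecay) + cfg@insertShift["polystyrene", ]
  expect_equal(extractFeatures(m, baselineCorrect = TRUE), oracle,
               tolerance = 1e-12)

  ## "last reading" alternative for the ambient reference
  lastRef <- m@exposure[270, ] - m@regeneration[600, ]
  expect_equal(unname(extractFeatures(m, baselineCorrect = TRUE,
                                      baselineStat = "last")),
               unname(lastRef))

  ## tRef bounds
  expect_error(extractFeatures(m, tRef = 0), "tRef")
  expect_error(extractFeatures(m, tRef = 601), "tRef")
})

test_that("extraction is local to the reference second and regeneration phase", {
  cfg <- fastConfig(noiseSd = 0)
  m <- generateMeasurement(cfg, "7", "M1", "wooden", objectSeed = 1)
  f0 <- extractFeatures(m, baselineCorrect = TRUE)
  pert <- m
  pert@exposure[-270L, ] <- pert@exposure[-270L, ] + 100
  expect_equal(extractFeatures(pert, baselineCorrect = TRUE), f0)
  ## but the regeneration phase does enter the corrected descriptor
  pert@regeneration <- pert@regeneration + 1
  expect_equal(unname(extractFeatures(pert, baselineCorrect = TRUE)),
               unname(f0) - 1)
})

test_that("decision tables reproduce the option structure", {
  study <- generateStudy(fastConfig())
  dt <- buildDecisionTable(study, "M1", "wooden", baselineCorrect = FALSE)
  expect_s4_class(dt, "DecisionTable")
  expect_equal(ncol(dt), 12L)   # 4 classes x 3
  expect_false(isBaselineCorrected(dt))
  expect_identical(rownames(featureMatrix(dt)), sensorNames())
  rng <- attrRanges(dt)
  expect_true(all(rng$min <= rng$max))

  ## option keys resolve to device/insert/correction triples
  dtV <- buildOptionTable(study, "V")
  expect_true(isBaselineCorrected(dtV))
  expect_true(all(SummarizedExperiment::colData(dtV)$device == "M1"))
  expect_true(all(SummarizedExperiment::colData(dtV)$insert == "wooden"))
  dtVIII <- buildOptionTable(study, "VIII")
  expect_true(all(SummarizedExperiment::colData(dtVIII)$insert == "polystyrene"))
  expect_error(buildOptionTable(study, "IX"), "unknown option")

  ## empty selection errors; single object gives degenerate extrema
  expect_error(buildDecisionTable(SensorStudy(), "M1", "wooden"),
               "no measurements")
  one <- SensorStudy(list(study[[1L]]))
  d1 <- buildDecisionTable(one, "M1", "wooden")
  r1 <- attrRanges(d1)
  expect_equal(r1$min, r1$max)

  ## feature CSV export
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCSV(dt, path)
  got <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(got),
                   c("object_id", "class", "device", "insert", sensorNames()))
  expect_equal(nrow(got), 12L)
})

test_that("baseline correction removes device offsets in the noiseless limit", {
  cfg <- fastConfig(noiseSd = 0)
  study <- generateStudy(cfg)
  meanAbsDiff <- function(correct) {
    a <- featureMatrix(buildDecisionTable(study, "M1", "wooden",
                                          baselineCorrect = correct))
    b <- featureMatrix(buildDecisionTable(study, "M2", "wooden",
                                          baselineCorrect = correct))
    mean(abs(a - b))
  }
  expect_lt(meanAbsDiff(TRUE), meanAbsDiff(FALSE))
  ## with zero noise the corrected tables agree across devices exactly
  expect_lt(meanAbsDiff(TRUE), 1e-9)
})
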