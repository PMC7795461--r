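test_that("distances satisfy the stated formulas and edge conventions", {
  x6 <- rep(0, 6); y6 <- rep(1, 6)
  for (metric in c("canberra", "euclidean", "manhattan")) {
    expect_equal(featureDistance(metric, c(1, 2, 3), c(1, 2, 3)), 0)
  }
  expect_equal(featureDistance("canberra", c(1, 3), c(3, 1)), 1)
  expect_equal(featureDistance("manhattan", x6, y6), 6)
  expect_equal(featureDistance("euclidean", x6, y6), sqrt(6))
  ## canberra 0/0 terms contribute 0
  expect_equal(featureDistance("canberra", c(0, 1), c(0, 3)), 0.5)
  ## maxmin: training extrema scale coordinates; constant attributes map to 0
  expect_equal(featureDistance("maxmin", c(0, 5), c(10, 5),
                               attrMin = c(0, 5), attrMax = c(10, 5)), 1)
  expect_equal(featureDistance("maxmin", c(0, 4), c(10, 9),
                               attrMin = c(0, 5), attrMax = c(10, 5)), 1)
  ## values outside the training range are not clipped
  expect_equal(featureDistance("maxmin", c(-10, 0), c(10, 0),
                               attrMin = c(0, 0), attrMax = c(10, 1)), 2)
  expect_equal(featureDistance("maxmin", c(1, 2, 3), c(1, 2, 3),
                               attrMin = rep(0, 3), attrMax = rep(4, 3)), 0)
  expect_error(featureDistance("maxmin", 1, 2), "attrMin")
  expect_error(featureDistance("chebyshev", 1, 2), "unknown metric")
})

test_that("the ten canonical names parse and bad names list the valid set", {
  expect_length(classifierNames(), 10L)
  for (nm in classifierNames()) {
    spec <- classifierSpec(nm)
    expect_identical(spec@name, nm)
  }
  sp <- classifierSpec("eps = 0.01.nb2")   # caption-style spacing
  expect_identical(sp@name, "eps=0.01.nb2")
  expect_identical(sp@family, "nb2")
  expect_equal(sp@eps, 0.01)
  expect_error(classifierSpec("cosine.1nn"), "euclidean.811")
  expect_error(classifierSpec("euclidean.3nn"), "valid names")
})

test_that("1-NN matches an exhaustive-scan oracle under all four metrics", {
  ## forced cases first
  one <- makeTable(matrix(rnorm(6), 6L, 1L), "6")
  expect_identical(classify1NN(one, rnorm(6), "euclidean"), "6")
  tab <- randomTable(16L, seed = 21L)
  expect_identical(classify1NN(tab, featureMatrix(tab)[, 3L], "manhattan"),
                   classLabelsOf(tab)[3L])

  for (seed in 1:5) {
    tab <- randomTable(14L, seed = seed)
    feats <- featureMatrix(tab)
    labs <- classLabelsOf(tab)
    rng <- attrRanges(tab)
    for (metric in c("canberra", "euclidean", "manhattan", "maxmin")) {
      for (q in 1:8) {
        x <- rnorm(6L, sd = 4)
        d <- vapply(seq_len(ncol(feats)), function(j)
          oracleDistance(metric, x, feats[, j], rng$min, rng$max), numeric(1L))
        want <- labelOrder(labs[d == min(d)])[1L]
        expect_identical(classify1NN(tab, x, metric), want)
      }
    }
  }
})

test_that("811 weighted voting matches a vote-tally oracle", {
  ## unanimous training set
  uni <- makeTable(matrix(rnorm(24), 6L, 4L), rep("5", 4L))
  expect_identical(classify811(uni, rnorm(6), "euclidean"), "5")

  ## query on a training row with tiny delta: that row's weight dominates
  tab <- randomTable(12L, seed = 33L)
  x <- featureMatrix(tab)[, 7L]
  expect_identical(classify811(tab, x, "euclidean", delta = 1e-10),
                   classLabelsOf(tab)[7L])
  expect_identical(classify811(tab, x, "canberra", delta = 1e-10),
                   classify1NN(tab, x, "canberra"))

  ## hand-enumerated vote tally on random tables
  for (seed in 1:5) {
    tab <- randomTable(12L, seed = seed + 100L)
    feats <- featureMatrix(tab)
    labs <- classLabelsOf(tab)
    rng <- attrRanges(tab)
    delta <- 1e-10
    for (metric in c("euclidean", "manhattan", "canberra", "maxmin")) {
      for (q in 1:5) {
        x <- rnorm(6L, sd = 4)
        votes <- list()
        for (j in seq_along(labs)) {
          w <- 1 / (oracleDistance(metric, x, feats[, j], rng$min, rng$max) +
                      delta)
          votes[[labs[j]]] <- (votes[[labs[j]]] %||% 0) + w
        }
        vv <- unlist(votes)
        want <- labelOrder(names(vv)[vv == max(vv)])[1L]
        expect_identical(classify811(tab, x, metric, delta), want)
      }
    }
  }
})

test_that("epsilon-indiscernibility NB matches a loop-based oracle", {
  ## saturated ratios: x inside every window of class 7, outside all others
  feats <- cbind(matrix(0, 6L, 3L), matrix(100, 6L, 3L))
  tab <- makeTable(feats, c(rep("5", 3L), rep("7", 3L)))
  expect_identical(classifyNB(tab, rep(100, 6L), eps = 0.01, "nb"), "7")

  ## zero-range attribute degenerates to exact equality
  featsC <- rbind(matrix(c(0, 0, 10, 10), 1L), matrix(5, 5L, 4L))
  tabC <- makeTable(featsC, c("5", "5", "7", "7"))
  ## query matches the constant rows everywhere but attribute 1 decides
  expect_identical(classifyNB(tabC, c(10, rep(5, 5L)), eps = 0.5, "nb"), "7")
  expect_identical(classifyNB(tabC, c(0, rep(5, 5L)), eps = 0.5, "nb"), "5")

  ## literal reimplementation of the scoring formula on random tables
  for (seed in 1:6) {
    tab <- randomTable(12L, seed = seed + 200L)
    feats <- featureMatrix(tab)
    labs <- classLabelsOf(tab)
    rng <- attrRanges(tab)
    eps <- 0.25
    for (q in 1:5) {
      x <- feats[, sample(ncol(feats), 1L)] + rnorm(6L)
      classes <- labelOrder(unique(labs))
      scoreNB <- scoreNB2 <- setNames(numeric(length(classes)), classes)
      for (cl in classes) {
        rows <- which(labs == cl)
        s <- 0
        for (i in 1:6) {
          hits <- 0
          for (j in rows)
            if (abs(feats[i, j] - x[i]) <= eps * (rng$max[i] - rng$min[i]))
              hits <- hits + 1
          s <- s + hits / length(rows)
        }
        scoreNB[cl] <- s
        scoreNB2[cl] <- (length(rows) / length(labs)) * s
      }
      wantNB <- labelOrder(names(scoreNB)[scoreNB == max(scoreNB)])[1L]
      wantNB2 <- labelOrder(names(scoreNB2)[scoreNB2 == max(scoreNB2)])[1L]
      expect_identical(classifyNB(tab, x, eps, "nb"), wantNB)
      expect_identical(classifyNB(tab, x, eps, "nb2"), wantNB2)
    }
  }
})

test_that("classifiers are total, permutation-invariant and match knn1", {
  tab <- randomTable(20L, seed = 77L)
  test <- randomTable(15L, seed = 78L)
  perm <- sample(ncol(tab))
  shuffled <- makeTable(featureMatrix(tab)[, perm], classLabelsOf(tab)[perm])
  for (nm in classifierNames()) {
    pred <- predictTable(tab, test, nm)
    ## coverage is total: every query receives a valid label
    expect_length(pred, ncol(test))
    expect_true(all(pred %in% classLabelsOf(tab)))
    ## training-row order does not matter
    expect_identical(predictTable(shuffled, test, nm), pred)
  }

  ## off-the-shelf 1-NN agreement (euclidean), ties essentially impossible
  ## with continuous features
  skip_if_not_installed("class")
  agree <- 0L; total <- 0L
  for (seed in 1:4) {
    tr <- randomTable(16L, seed = seed + 300L)
    te <- randomTable(25L, seed = seed + 400L)
    mine <- predictTable(tr, te, "euclidean.1nn")
    ref <- as.character(class::knn1(t(featureMatrix(tr)),
                                    t(featureMatrix(te)),
                                    factor(classLabelsOf(tr))))
    agree <- agree + sum(mine == ref)
    total <- total + length(mine)
  }
  expect_gte(agree / total, 0.99)
})
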