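## The ten classifiers: 1-NN and inverse-distance weighted voting ("811")
## under four distance schemes, plus two epsilon-indiscernibility Naive
## Bayes variants. All are lazy (no fitting beyond the training table), all
## are total (every query receives a label), and all ties are broken by
## ascending class-label order so results are fully deterministic.

CANONICAL_CLASSIFIERS <- c(
  "canberra.1nn", "canberra.811", "eps=0.01.nb", "eps=0.01.nb2",
  "euclidean.1nn", "euclidean.811", "manhattan.1nn", "manhattan.811",
  "maxminnormalized.1nn", "maxminnormalized.811")

#' The ten canonical classifier names
#'
#' In the conventional order m1..m10: `canberra.1nn`, `canberra.811`,
#' `eps=0.01.nb`, `eps=0.01.nb2`, `euclidean.1nn`, `euclidean.811`,
#' `manhattan.1nn`, `manhattan.811`, `maxminnormalized.1nn`,
#' `maxminnormalized.811`.
#'
#' @return Character vector of length 10.
#' @export
classifierNames <- function() CANONICAL_CLASSIFIERS

#' Create a classifier specification
#'
#' Parses a canonical classifier name (see [classifierNames()]; whitespace
#' around `=` is tolerated, so `"eps = 0.01.nb"` works too) into a
#' [ClassifierSpec-class]. Alternatively the components can be given
#' directly via `family`/`metric`/`eps`.
#'
#' @param name canonical name, or `NULL` when components are supplied.
#' @param family one of "1nn", "811", "nb", "nb2".
#' @param metric one of "canberra", "euclidean", "manhattan", "maxmin"
#'   (`"maxminnormalized"` is accepted as an alias); ignored for nb/nb2.
#' @param eps indiscernibility window fraction in (0, 1] (nb/nb2 only).
#' @param delta vote regularizer of the 811 rule.
#' @return A [ClassifierSpec-class].
#' @examples
#' classifierSpec("euclidean.1nn")
#' classifierSpec("eps = 0.01.nb2")
#' @export
classifierSpec <- function(name = NULL, family = NULL, metric = NULL,
                           eps = 0.01, delta = 1e-10) {
  if (!is.null(name)) {
    key <- gsub(" ", "", name)
    if (grepl("^eps=", key)) {
      m <- regmatches(key, regexec("^eps=([0-9.eE+-]+)\\.(nb2?)$", key))[[1L]]
      if (length(m) != 3L)
        stop(badClassifierMsg(name))
      eps <- as.numeric(m[2L])
      family <- m[3L]
      metric <- "euclidean"   # unused by nb/nb2
    } else {
      m <- regmatches(key, regexec("^([a-z]+)\\.(1nn|811)$", key))[[1L]]
      if (length(m) != 3L)
        stop(badClassifierMsg(name))
      metric <- m[2L]
      family <- m[3L]
    }
    canonical <- if (family %in% c("nb", "nb2"))
      sprintf("eps=%g.%s", eps, family)
    else sprintf("%s.%s",
                 if (metric == "maxmin") "maxminnormalized" else metric, family)
  } else {
    if (is.null(family)) stop("either 'name' or 'family' must be given")
    if (is.null(metric)) metric <- "euclidean"
    canonical <- if (family %in% c("nb", "nb2"))
      sprintf("eps=%g.%s", eps, family)
    else sprintf("%s.%s",
                 if (metric == "maxmin") "maxminnormalized" else metric, family)
  }
  if (identical(metric, "maxminnormalized")) metric <- "maxmin"
  if (!metric %in% c("canberra", "euclidean", "manhattan", "maxmin"))
    stop(badClassifierMsg(name %||% metric))
  new("ClassifierSpec", name = canonical, family = family, metric = metric,
      eps = eps, delta = delta)
}

badClassifierMsg <- function(name) {
  sprintf("unknown classifier '%s'; valid names are: %s", name,
          paste(CANONICAL_CLASSIFIERS, collapse = ", "))
}

#' Distance between two feature vectors
#'
#' The four distance schemes of the kNN/811 classifiers:
#' \itemize{
#'   \item euclidean: \eqn{\sqrt{\sum_i (x_i - y_i)^2}}
#'   \item manhattan: \eqn{\sum_i |x_i - y_i|}
#'   \item canberra: \eqn{\sum_i |x_i - y_i| / (|x_i| + |y_i|)}, with 0/0
#'     terms contributing 0
#'   \item maxmin: euclidean after mapping each coordinate through
#'     \eqn{(v - min_i)/(max_i - min_i)} using the training-table extrema;
#'     a constant attribute (zero range) maps to 0 and values outside
#'     `[min, max]` are not clipped.
#' }
#'
#' @param metric one of "canberra", "euclidean", "manhattan", "maxmin".
#' @param x,y numeric vectors of equal length.
#' @param attrMin,attrMax per-attribute training extrema (maxmin only).
#' @return A single non-negative number.
#' @examples
#' featureDistance("canberra", c(1, 3), c(3, 1))   # 1
#' @export
featureDistance <- function(metric, x, y, attrMin = NULL, attrMax = NULL) {
  stopifnot(length(x) == length(y))
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    canberra = {
      num <- abs(x - y)
      den <- abs(x) + abs(y)
      sum(ifelse(den == 0, 0, num / den))
    },
    maxmin = {
      if (is.null(attrMin) || is.null(attrMax))
        stop("maxmin metric requires attrMin/attrMax from the training table")
      rng <- attrMax - attrMin
      xs <- ifelse(rng == 0, 0, (x - attrMin) / rng)
      ys <- ifelse(rng == 0, 0, (y - attrMin) / rng)
      sqrt(sum((xs - ys)^2))
    },
    stop(sprintf("unknown metric '%s'", metric))
  )
}

## Vectorized distances from query x to every column of the training matrix.
distancesToTrain <- function(metric, train, x, attrMin, attrMax) {
  d <- train - x      # 6 x n, column recycling of x
  switch(metric,
    euclidean = sqrt(colSums(d^2)),
    manhattan = colSums(abs(d)),
    canberra = {
      den <- abs(train) + abs(x)
      term <- abs(d) / den
      term[den == 0] <- 0
      colSums(term)
    },
    maxmin = {
      rng <- attrMax - attrMin
      sc <- ifelse(rng == 0, 0, 1 / rng)
      sqrt(colSums((d * sc)^2))
    },
    stop(sprintf("unknown metric '%s'", metric))
  )
}

## First label in deterministic label order among candidates.
breakTie <- function(labels) orderLabels(labels)[1L]

## Plain-matrix prediction kernel shared by the exported classifiers and the
## MCCV harness: trainFeats/testFeats are 6 x n matrices, trainLabs a
## character vector. Per-query work never touches S4 containers.
predictCore <- function(trainFeats, trainLabs, testFeats, spec) {
  attrMin <- apply(trainFeats, 1L, min)
  attrMax <- apply(trainFeats, 1L, max)
  classes <- orderLabels(unique(trainLabs))
  labIdx <- match(trainLabs, classes)

  if (spec@family %in% c("1nn", "811")) {
    one <- function(x) {
      d <- distancesToTrain(spec@metric, trainFeats, x, attrMin, attrMax)
      if (spec@family == "1nn") {
        classes[min(labIdx[d == min(d)])]
      } else {
        w <- 1 / (d + spec@delta)
        votes <- vapply(seq_along(classes),
                        function(k) sum(w[labIdx == k]), numeric(1L))
        classes[which.max(votes)]   # first max = smallest label on ties
      }
    }
  } else {
    win <- spec@eps * (attrMax - attrMin)
    colsByClass <- lapply(seq_along(classes), function(k) labIdx == k)
    prior <- vapply(colsByClass, mean, numeric(1L))
    one <- function(x) {
      hit <- abs(trainFeats - x) <= win
      scores <- vapply(seq_along(classes), function(k) {
        sum(rowMeans(hit[, colsByClass[[k]], drop = FALSE]))
      }, numeric(1L))
      if (spec@family == "nb2") scores <- prior * scores
      classes[which.max(scores)]
    }
  }
  stats::setNames(
    vapply(seq_len(ncol(testFeats)), function(j) one(testFeats[, j]), ""),
    colnames(testFeats))
}

#' Classify one query vector
#'
#' `classify1NN` returns the label of the training row nearest to the query;
#' `classify811` lets every training row vote for its own class with weight
#' `1/(distance + delta)` and returns the class with the largest vote sum;
#' `classifyNB` scores each class by the sum over attributes of its
#' indiscernibility ratio (fraction of the class's rows whose attribute
#' value lies within `eps * range` of the query; a zero-range attribute
#' degenerates to exact equality), with the `nb2` variant additionally
#' weighting the sum by the class prior. All ties are broken by ascending
#' class-label order.
#'
#' @param train a [DecisionTable-class] (non-empty).
#' @param x numeric query vector of length 6.
#' @param metric distance scheme, see [featureDistance()].
#' @param delta positive vote regularizer.
#' @param eps indiscernibility window fraction in (0, 1].
#' @param variant "nb" or "nb2".
#' @return A single class label (character).
#' @name pointClassifiers
#' @examples
#' study <- generateStudy(sensorSimConfig(nPerClass = 3, seed = 1))
#' dt <- buildDecisionTable(study, "M1", "wooden")
#' classify1NN(dt, featureMatrix(dt)[, 1], "euclidean")
NULL

#' @rdname pointClassifiers
#' @export
classify1NN <- function(train, x, metric) {
  stopifnot(is(train, "DecisionTable"), ncol(train) > 0L)
  rng <- attrRanges(train)
  d <- distancesToTrain(metric, featureMatrix(train), x, rng$min, rng$max)
  breakTie(classLabelsOf(train)[d == min(d)])
}

#' @rdname pointClassifiers
#' @export
classify811 <- function(train, x, metric, delta = 1e-10) {
  stopifnot(is(train, "DecisionTable"), ncol(train) > 0L, delta > 0)
  rng <- attrRanges(train)
  d <- distancesToTrain(metric, featureMatrix(train), x, rng$min, rng$max)
  w <- 1 / (d + delta)
  votes <- tapply(w, classLabelsOf(train), sum)
  breakTie(names(votes)[votes == max(votes)])
}

#' @rdname pointClassifiers
#' @export
classifyNB <- function(train, x, eps = 0.01, variant = c("nb", "nb2")) {
  stopifnot(is(train, "DecisionTable"), ncol(train) > 0L, eps > 0, eps <= 1)
  variant <- match.arg(variant)
  feats <- featureMatrix(train)
  labs <- classLabelsOf(train)
  rng <- attrRanges(train)
  win <- eps * (rng$max - rng$min)          # per-attribute window width
  hit <- abs(feats - x) <= win              # 6 x n logical
  classes <- orderLabels(unique(labs))
  n <- length(labs)
  scores <- vapply(classes, function(cl) {
    sel <- labs == cl
    ratio <- rowMeans(hit[, sel, drop = FALSE])
    s <- sum(ratio)
    if (variant == "nb2") s <- (sum(sel) / n) * s
    s
  }, numeric(1L))
  breakTie(classes[scores == max(scores)])
}

#' Classify every column of a test table
#'
#' Applies one classifier, specified by a [ClassifierSpec-class] (or a
#' canonical name), to each object of `test` using `train` as the reference
#' table. Coverage is total: every query receives a label.
#'
#' @param train,test [DecisionTable-class] objects.
#' @param spec a [ClassifierSpec-class] or a canonical classifier name.
#' @return Character vector of predicted labels, named by object id.
#' @examples
#' study <- generateStudy(sensorSimConfig(nPerClass = 3, seed = 1))
#' dt <- buildDecisionTable(study, "M1", "wooden")
#' predictTable(dt, dt, "euclidean.1nn")
#' @export
predictTable <- function(train, test, spec) {
  if (is.character(spec)) spec <- classifierSpec(spec)
  stopifnot(is(spec, "ClassifierSpec"))
  predictCore(featureMatrix(train), classLabelsOf(train),
              featureMatrix(test), spec)
}
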