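## Per-class "scent signature": min-max normalize each sensor attribute over
## all objects of a decision table, average within class, and square the
## class means. The squared profiles are what the radar charts display.

#' Min-max normalize a vector into an interval
#'
#' Maps `values` linearly onto `[a, b]`:
#' `x -> (x - min) * (b - a) / (max - min) + a`, so the minimum of the input
#' maps to `a` and the maximum to `b`. When all values are equal the range
#' is degenerate and every output is set to `a` (documented convention).
#'
#' @param values non-empty numeric vector.
#' @param a,b interval endpoints, `b > a`.
#' @return Numeric vector of the same length.
#' @examples
#' minmaxNormalize(c(2, 4, 6))          # 0, 0.5, 1
#' minmaxNormalize(c(-1, 0, 3))         # 0, 0.25, 1
#' @export
minmaxNormalize <- function(values, a = 0, b = 1) {
  stopifnot(length(values) > 0L, is.numeric(values), b > a)
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) return(rep(a, length(values)))
  (values - lo) * (b - a) / (hi - lo) + a
}

#' Compute per-class scent signatures
#'
#' Per sensor attribute, all rows of the table (all classes pooled) are
#' normalized into `[a, b]` with [minmaxNormalize()]; the normalized values
#' are averaged within each class and the class means are squared. Classes
#' are ordered by label ({1, 5, 6, 7} first, merged rest-labels after);
#' a class with zero rows is omitted with a warning.
#'
#' @param table a [DecisionTable-class].
#' @param a,b normalization interval (default `[0, 1]`).
#' @param classes class set to report; defaults to the classes present in
#'   the table. A requested class with zero rows is omitted with a warning.
#' @return A [ClassSignature-class]; values lie in `[a^2, b^2]` for `a >= 0`.
#' @examples
#' study <- generateStudy(sensorSimConfig(nPerClass = 3, seed = 1))
#' sig <- classSignature(buildDecisionTable(study, "M1", "wooden"))
#' signatureValues(sig)
#' @export
classSignature <- function(table, a = 0, b = 1, classes = NULL) {
  stopifnot(is(table, "DecisionTable"), ncol(table) > 0L)
  feats <- featureMatrix(table)                       # sensors x objects
  labs <- classLabelsOf(table)
  norm <- t(apply(feats, 1L, minmaxNormalize, a = a, b = b))
  if (ncol(table) == 1L) norm <- matrix(norm, N_SENSORS, 1L)
  if (is.null(classes)) classes <- orderLabels(labs)
  classes <- orderLabels(classes)
  empty <- classes[!classes %in% labs]
  if (length(empty)) {
    warning(sprintf("classes with no rows omitted: %s",
                    paste(empty, collapse = ", ")))
    classes <- setdiff(classes, empty)
  }
  vals <- t(vapply(classes, function(cl) {
    rowMeans(norm[, labs == cl, drop = FALSE])^2
  }, numeric(N_SENSORS)))
  colnames(vals) <- sensorNames()
  rownames(vals) <- classes
  new("ClassSignature", values = vals, a = a, b = b)
}

#' Export a class signature as CSV
#'
#' Header: `class,TGS823,...,TGS2603`.
#'
#' @param signature a [ClassSignature-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSignatureCSV <- function(signature, path) {
  out <- data.frame(class = rownames(signature@values),
                    signature@values, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a class signature as a radar polygon
#'
#' Convenience wrapper around the exported numbers: draws one polygon per
#' class over the six sensor axes using base graphics.
#'
#' @param signature a [ClassSignature-class].
#' @param main plot title.
#' @return The signature, invisibly.
#' @export
plotSignature <- function(signature, main = "Class scent signatures") {
  v <- signature@values
  k <- ncol(v)
  ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)] + pi / 2
  lim <- max(v, signature@b^2)
  graphics::plot(NA, xlim = c(-lim, lim) * 1.25, ylim = c(-lim, lim) * 1.25,
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  for (r in pretty(c(0, lim), 4L)[-1L])
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  graphics::text(1.15 * lim * cos(ang), 1.15 * lim * sin(ang), colnames(v))
  for (i in seq_len(nrow(v)))
    graphics::polygon(v[i, ] * cos(ang), v[i, ] * sin(ang),
                      border = i + 1L, lwd = 2)
  graphics::legend("topleft", legend = rownames(v), col = seq_len(nrow(v)) + 1L,
                   lwd = 2, bty = "n", title = "class")
  invisible(signature)
}
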