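nppFromValues <- function(dev, points = NULL) {
  n <- length(dev)
  if (n < 4) validationError("normal probability plot needs at least 4 points")
  ord <- order(dev)
  observed <- dev[ord]
  expected <- stats::qnorm((seq_len(n) - 0.5) / n)
  if (is.null(points)) {
    points <- data.frame(rank = seq_len(n), expected = expected,
                         observed = observed)
  } else {
    points <- points[ord, , drop = FALSE]
    points <- cbind(rank = seq_len(n), expected = expected,
                    observed = observed, points)
    rownames(points) <- NULL
  }
  npp <- new("NppResult", observed = observed, expected = expected,
             slope = NA_real_, intercept = NA_real_, n = as.integer(n),
             points = points)
  coefs <- iqRegression(npp)
  npp@slope <- coefs[["slope"]]
  npp@intercept <- coefs[["intercept"]]
  npp
}

#' Normal probability plot of weighted residuals
#'
#' Builds the every-point normal probability plot: the weighted deviates
#' \eqn{\sqrt{w_i}\,(F_{o,i}^2 - F_{c,i}^2)} sorted ascending, plotted
#' against the standard-normal order-statistic quantiles
#' \eqn{\Phi^{-1}((i - 0.5)/n)}.  Every reflection contributes exactly
#' one point (no binned averaging), and each point keeps its reflection
#' identity for outlier inspection.  The interquartile regression line is
#' fitted immediately (see [iqRegression()]).
#'
#' Deviates are not normalized by the overall goodness of fit, so a
#' slope above 1 directly signals underestimated uncertainties.
#'
#' @param rs a [ReflectionSet-class].
#' @param scheme the applied [WeightingScheme-class].
#' @param p refined parameter count (kept on the report path; the plot
#'   itself does not use it).
#' @return An [NppResult-class].
#' @export
nppData <- function(rs, scheme = weightingScheme(a = 0, b = 0),
                    p = nParams(rs)) {
  d <- rs@refl
  w <- reflectionWeights(rs, scheme)
  dev <- sqrt(w) * (d$fobsSq - d$fcalcSq)
  pts <- data.frame(h = d$h, k = d$k, l = d$l, fobsSq = d$fobsSq,
                    fcalcSq = d$fcalcSq, sigmaFobsSq = d$sigmaFobsSq,
                    w = w)
  nppFromValues(dev, pts)
}

#' @rdname nppData
#' @param deviates a plain numeric vector of deviates (already weighted);
#'   used to study the plot machinery itself, e.g. on simulated
#'   standard-normal draws.
#' @export
nppFromDeviates <- function(deviates) nppFromValues(as.numeric(deviates))

#' Interquartile regression of a normal probability plot
#'
#' Ordinary least squares of observed on expected restricted to the
#' central half of the ranks (i with n/4 < i <= 3n/4), removing bias
#' from large outliers in the tails.  Membership is by rank, never by
#' deviate value, so ties are handled deterministically.  For normally
#' distributed residuals the line approaches slope 1, intercept 0.
#'
#' @param npp an [NppResult-class].
#' @return Named numeric `c(slope = , intercept = )`.
#' @export
iqRegression <- function(npp) {
  n <- npp@n
  idx <- which(seq_len(n) > n / 4 & seq_len(n) <= 3 * n / 4)
  if (length(idx) < 2)
    validationError("fewer than 2 points between the quartiles; cannot fit")
  x <- npp@expected[idx]
  y <- npp@observed[idx]
  if (stats::var(x) == 0) {
    ## all central expected quantiles equal (n tiny): slope undefined,
    ## report flat line through the mean
    return(c(slope = 0, intercept = mean(y)))
  }
  slope <- stats::cov(x, y) / stats::var(x)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Plot a normal probability plot to an image file
#'
#' Scatter of (expected, observed) with a dashed red y = x reference
#' line (the locus of perfectly normal residuals) and the solid
#' interquartile regression line.  The device is chosen from the file
#' extension (.png, .svg or .pdf).
#'
#' @param npp an [NppResult-class].
#' @param path output image path.
#' @param axisRange optional `c(lo, hi)` applied to both axes (the
#'   conventional choice is `c(-4, 4)`); defaults to the data range.
#' @param width,height device size in inches.
#' @return Invisibly, `list(path, xlim, ylim)` with the limits actually
#'   applied.
#' @export
plotNpp <- function(npp, path, axisRange = NULL, width = 6, height = 6) {
  lim <- if (!is.null(axisRange)) {
    if (length(axisRange) != 2 || axisRange[1] >= axisRange[2])
      validationError("axisRange must be c(lo, hi) with lo < hi")
    as.numeric(axisRange)
  } else range(c(npp@expected, npp@observed))
  ext <- tolower(tools::file_ext(path))
  opened <- tryCatch({
    switch(ext,
           png = grDevices::png(path, width = width, height = height,
                                units = "in", res = 150),
           svg = grDevices::svg(path, width = width, height = height),
           grDevices::pdf(path, width = width, height = height))
    TRUE
  }, error = function(e) FALSE)
  if (!opened) ioError(sprintf("cannot open graphics device for %s", path))
  on.exit(grDevices::dev.off())
  graphics::plot(npp@expected, npp@observed, pch = 16, cex = 0.4,
                 xlim = lim, ylim = lim,
                 xlab = "Expected normal quantile",
                 ylab = "Ordered weighted deviate",
                 main = "Normal probability plot")
  graphics::abline(0, 1, lty = 2, col = "red")
  graphics::abline(npp@intercept, npp@slope, col = "blue")
  graphics::legend("topleft", bty = "n", lty = c(2, 1),
                   col = c("red", "blue"),
                   legend = c("normal (y = x)",
                              sprintf("IQ fit: y = %.4f x %+.5f",
                                      npp@slope, npp@intercept)))
  invisible(list(path = path, xlim = lim, ylim = lim))
}

#' Export normal-probability-plot points as tab-separated text
#'
#' One row per rank with the expected and observed deviates and, when
#' present, the reflection identity (h, k, l, Fo^2, Fc^2, sigma, w) —
#' the data-table counterpart of interactive point inspection.
#'
#' @param npp an [NppResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNppTable <- function(npp, path) {
  ok <- tryCatch({
    utils::write.table(npp@points, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ioError(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Aggregate weighting report
#'
#' One JSON-serializable record of a full diagnostic pass: the applied
#' scheme (all six parameters), the cut-offs and how many reflections
#' each removed, the refinement statistics and the normal-probability
#' regression coefficients.
#'
#' @param rs a [ReflectionSet-class].
#' @param scheme the applied [WeightingScheme-class].
#' @param p refined parameter count (defaults to the set's).
#' @param filters a [FilterSpec-class].
#' @return A nested list (see fields); serialize with [writeReport()].
#' @export
weightingReport <- function(rs, scheme, p = nParams(rs),
                            filters = filterSpec()) {
  fl <- applyFilters(rs, filters, counts = TRUE)
  kept <- fl$set
  if (is.na(p)) validationError("refined parameter count p is unknown")
  stats <- refinementStats(kept, scheme, p)
  npp <- nppData(kept, scheme, p)
  list(
    schemaVersion = 1L,
    scheme = list(a = scheme@a, b = scheme@b, c = scheme@c,
                  d = scheme@d, e = scheme@e, f = scheme@f),
    filters = list(
      minIntensity = filters@minIntensity,
      minIOverSigma = filters@minIOverSigma,
      maxSinThetaOverLambda = filters@maxSinThetaOverLambda,
      removed = as.list(fl$removed),
      nKept = fl$nKept),
    n = stats@n, p = stats@p,
    stats = list(r1 = stats@r1, wr2 = stats@wr2,
                 goof = stats@goof, wgoof = stats@wgoof),
    npp = list(slope = npp@slope, intercept = npp@intercept)
  )
}

#' @rdname weightingReport
#' @param report a report list from `weightingReport`.
#' @param path output JSON path.
#' @export
writeReport <- function(report, path) {
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ioError(sprintf("cannot write to %s", path))
  invisible(path)
}
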