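#' @import methods
NULL

#' Unit cell
#'
#' Direct-space unit cell: three lengths in ångström and three angles in
#' degrees.  All file readers take angles in degrees (the universal
#' crystallographic convention); conversion to radians happens internally
#' and only once, in [reciprocalMetric()].
#'
#' @slot a,b,c cell edge lengths (Å), strictly positive.
#' @slot alpha,beta,gamma cell angles (degrees), strictly inside (0, 180);
#'   the direct metric tensor must be positive definite (real, positive
#'   cell volume), which excludes degenerate angle combinations.
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"),
  validity = function(object) {
    v <- c(object@a, object@b, object@c)
    ang <- c(object@alpha, object@beta, object@gamma)
    if (any(!is.finite(v)) || any(v <= 0))
      return("cell lengths must be finite and > 0")
    if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
      return("cell angles must lie strictly in (0, 180) degrees")
    r <- ang * pi / 180
    det3 <- 1 - sum(cos(r)^2) + 2 * prod(cos(r))
    if (det3 <= 0)
      return("degenerate cell: direct metric tensor is not positive definite")
    TRUE
  })

#' @param a,b,c cell lengths (Å).
#' @param alpha,beta,gamma cell angles (degrees).
#' @return A `UnitCell` object.
#' @examples
#' unitCell(10, 10, 10)
#' unitCell(7.1, 8.2, 9.3, 80, 95, 100)
#' @rdname UnitCell-class
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))
}

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.4f b=%.4f c=%.4f Å  alpha=%.3f beta=%.3f gamma=%.3f deg\n",
              object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma))
})

#' Reciprocal metric tensor
#'
#' Symmetric positive-definite 3x3 reciprocal metric tensor G* (Å^-2)
#' such that 1/d^2(hkl) = h' G* h.
#'
#' @slot g symmetric positive-definite 3x3 matrix (Å^-2).
#' @export
setClass("ReciprocalMetric",
  representation(g = "matrix"),
  validity = function(object) {
    g <- object@g
    if (!is.numeric(g) || !all(dim(g) == c(3, 3)))
      return("g must be a numeric 3x3 matrix")
    if (max(abs(g - t(g))) > 1e-10 * max(abs(g)))
      return("reciprocal metric must be symmetric")
    if (any(eigen(g, symmetric = TRUE, only.values = TRUE)$values <= 0))
      return("reciprocal metric must be positive definite")
    TRUE
  })

#' Set of measured reflections
#'
#' Ordered collection of reflections from a completed refinement: Miller
#' indices, observed squared structure factors Fo^2, their standard
#' uncertainties sigma(Fo^2) and the model values Fc^2, all on the file's
#' native refinement scale (no rescaling is ever applied).  Optionally
#' carries the unit cell, radiation wavelength (Å) and the number of
#' independently refined parameters p, which downstream statistics need.
#'
#' Negative Fo^2 (valid weak measurements) are retained; they are clamped
#' to zero only inside the composite intensity P and inside |Fo|.
#'
#' @slot refl data.frame with integer columns `h`, `k`, `l` and numeric
#'   columns `fobsSq`, `sigmaFobsSq`, `fcalcSq`; `sigmaFobsSq > 0`,
#'   `fcalcSq >= 0`, no (0,0,0) index and no duplicated index triple.
#' @slot cell a [UnitCell-class] or `NULL` when unknown.
#' @slot wavelength radiation wavelength in Å (`NA` when unknown).
#' @slot nParams refined parameter count p (`NA` when unknown).
#' @export
setClass("ReflectionSet",
  representation(refl = "data.frame", cell = "ANY",
                 wavelength = "numeric", nParams = "integer"),
  prototype(cell = NULL, wavelength = NA_real_, nParams = NA_integer_),
  validity = function(object) {
    d <- object@refl
    need <- c("h", "k", "l", "fobsSq", "sigmaFobsSq", "fcalcSq")
    if (!all(need %in% names(d)))
      return(paste("refl must have columns:", paste(need, collapse = ", ")))
    if (nrow(d) > 0) {
      if (any(!is.finite(d$sigmaFobsSq)) || any(d$sigmaFobsSq <= 0))
        return("sigma(Fo^2) must be finite and > 0 for every reflection")
      if (any(!is.finite(d$fcalcSq)) || any(d$fcalcSq < 0))
        return("Fc^2 must be finite and >= 0 for every reflection")
      if (any(d$h == 0 & d$k == 0 & d$l == 0))
        return("the (0,0,0) reflection is not allowed")
      if (anyDuplicated(d[c("h", "k", "l")]))
        return("duplicate (h,k,l) triples are not allowed")
    }
    if (!is.null(object@cell) && !is(object@cell, "UnitCell"))
      return("cell must be a UnitCell or NULL")
    TRUE
  })

#' @param h,k,l integer Miller indices.
#' @param fobsSq,sigmaFobsSq,fcalcSq observed Fo^2, its standard
#'   uncertainty and calculated Fc^2 (refinement scale).
#' @param cell optional [UnitCell-class].
#' @param wavelength optional wavelength (Å).
#' @param nParams optional refined parameter count.
#' @return A `ReflectionSet`.
#' @rdname ReflectionSet-class
#' @export
reflectionSet <- function(h, k, l, fobsSq, sigmaFobsSq, fcalcSq,
                          cell = NULL, wavelength = NA_real_,
                          nParams = NA_integer_) {
  d <- data.frame(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                  fobsSq = as.numeric(fobsSq),
                  sigmaFobsSq = as.numeric(sigmaFobsSq),
                  fcalcSq = as.numeric(fcalcSq))
  new("ReflectionSet", refl = d, cell = cell,
      wavelength = as.numeric(wavelength), nParams = as.integer(nParams))
}

#' SHELXL-style weighting scheme
#'
#' The six parameters of the weight
#' \deqn{w = q / [\sigma^2(F_o^2) + (aP)^2 + bP + d + e\,\sin\theta/\lambda]}
#' with \eqn{P = f \max(F_o^2, 0) + (1-f) F_c^2} and \eqn{q} a resolution
#' factor switched by the sign of \eqn{c} (see [qFactor()]).  Defaults are
#' the conventional refinement defaults: `a = 0.1` (a search placeholder
#' only), `b = c = d = e = 0` and `f = 1/3`, the mixing fraction shown to
#' reduce the bias of using Fo^2 or Fc^2 alone.
#'
#' @slot a,b,c,d,e,f numeric weight parameters; `f` in \[0, 1\]; `e` in Å.
#' @export
setClass("WeightingScheme",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 d = "numeric", e = "numeric", f = "numeric"),
  validity = function(object) {
    p <- c(object@a, object@b, object@c, object@d, object@e, object@f)
    if (any(!is.finite(p))) return("all weight parameters must be finite")
    if (object@f < 0 || object@f > 1) return("f must lie in [0, 1]")
    TRUE
  })

#' @param a,b,c,d,e,f weight parameters.
#' @return A `WeightingScheme`.
#' @examples
#' weightingScheme()                    # defaults, f = 1/3
#' weightingScheme(a = 0, b = 0)        # statistical weights w = 1/sigma^2
#' @rdname WeightingScheme-class
#' @export
weightingScheme <- function(a = 0.1, b = 0, c = 0, d = 0, e = 0, f = 1 / 3) {
  new("WeightingScheme", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d), e = as.numeric(e),
      f = as.numeric(f))
}

setMethod("show", "WeightingScheme", function(object) {
  cat(sprintf("WeightingScheme: a=%g b=%g c=%g d=%g e=%g f=%g\n",
              object@a, object@b, object@c, object@d, object@e, object@f))
})

#' Data cut-off specification
#'
#' Lower cuts on intensity and intensity over its uncertainty, and an
#' upper cut on resolution; an `NA` field imposes no cut.
#'
#' @slot minIntensity keep reflections with Fo^2 >= this (refinement scale).
#' @slot minIOverSigma keep reflections with Fo^2/sigma(Fo^2) >= this.
#' @slot maxSinThetaOverLambda keep reflections with sin(theta)/lambda <=
#'   this (Å^-1); requires the set to carry a unit cell.
#' @export
setClass("FilterSpec",
  representation(minIntensity = "numeric", minIOverSigma = "numeric",
                 maxSinThetaOverLambda = "numeric"))

#' @param minIntensity,minIOverSigma,maxSinThetaOverLambda cut values
#'   (`NA` = no cut).
#' @return A `FilterSpec`.
#' @rdname FilterSpec-class
#' @export
filterSpec <- function(minIntensity = NA_real_, minIOverSigma = NA_real_,
                       maxSinThetaOverLambda = NA_real_) {
  new("FilterSpec", minIntensity = as.numeric(minIntensity),
      minIOverSigma = as.numeric(minIOverSigma),
      maxSinThetaOverLambda = as.numeric(maxSinThetaOverLambda))
}

#' Grid-search configuration
#'
#' Geometry and stopping rules of the adaptive 9x9 grid search over
#' (a, b).  When `aStart`/`bStart` are `NA` they are computed from the
#' data with [shelxlStyleStart()].  The reference stopping steps are
#' `aStop = 0.0001`, `bStop = 0.005`; for multipolar (charge-density)
#' data smaller stops (still above `1e-5` and `5e-4`) are recommended,
#' because computed starts can fall below the reference stops and, in
#' strict mode, abort the search before it runs (see [gridSearch()]).
#'
#' @slot aStart,bStart initial grid centre (`NA` = compute from data).
#' @slot aStep,bStep initial step sizes (`NA` = derive from the starts as
#'   `max(start/2, 2*stop)`, or `start/2` in strict mode); explicit steps
#'   are used as given and must not start below their stops.
#' @slot aStop,bStop stopping step sizes, both > 0.
#' @slot nBins number of Fc-ordered bins (default 10).
#' @slot gridSide candidate values per axis per iteration (odd, >= 3;
#'   default 9).
#' @slot maxIterations safety cap on grid refinements.
#' @slot shrinkFactor per-axis step multiplier in (0, 1) applied when that
#'   axis's minimum is interior.
#' @slot strict reproduce the reference behaviour of deriving initial
#'   steps purely from the starts (no floor), erroring when a step starts
#'   below its stop.
#' @slot binDof `"whole"` (per-bin statistic scaled by the whole-set
#'   n/(n-p)) or `"perbin"` (per-bin n_k - p/nBins degrees of freedom).
#' @export
setClass("GridSearchConfig",
  representation(aStart = "numeric", bStart = "numeric",
                 aStep = "numeric", bStep = "numeric",
                 aStop = "numeric", bStop = "numeric",
                 nBins = "integer", gridSide = "integer",
                 maxIterations = "integer", shrinkFactor = "numeric",
                 strict = "logical", binDof = "character"),
  validity = function(object) {
    if (!is.finite(object@aStop) || object@aStop <= 0 ||
        !is.finite(object@bStop) || object@bStop <= 0)
      return("aStop and bStop must be > 0")
    if ((!is.na(object@aStep) && object@aStep <= 0) ||
        (!is.na(object@bStep) && object@bStep <= 0))
      return("explicit aStep/bStep must be > 0")
    if (object@gridSide < 3L || object@gridSide %% 2L == 0L)
      return("gridSide must be odd and >= 3")
    if (object@nBins < 2L) return("nBins must be >= 2")
    if (!is.finite(object@shrinkFactor) ||
        object@shrinkFactor <= 0 || object@shrinkFactor >= 1)
      return("shrinkFactor must lie strictly in (0, 1)")
    if (!object@binDof %in% c("whole", "perbin"))
      return("binDof must be 'whole' or 'perbin'")
    TRUE
  })

#' @param aStart,bStart,aStep,bStep,aStop,bStop,nBins,gridSide,maxIterations,shrinkFactor,strict,binDof
#'   see slots.
#' @return A `GridSearchConfig`.
#' @rdname GridSearchConfig-class
#' @export
gridSearchConfig <- function(aStart = NA_real_, bStart = NA_real_,
                             aStep = NA_real_, bStep = NA_real_,
                             aStop = 0.0001, bStop = 0.005,
                             nBins = 10L, gridSide = 9L,
                             maxIterations = 200L, shrinkFactor = 0.5,
                             strict = FALSE, binDof = "whole") {
  new("GridSearchConfig", aStart = as.numeric(aStart),
      bStart = as.numeric(bStart), aStep = as.numeric(aStep),
      bStep = as.numeric(bStep), aStop = as.numeric(aStop),
      bStop = as.numeric(bStop), nBins = as.integer(nBins),
      gridSide = as.integer(gridSide),
      maxIterations = as.integer(maxIterations),
      shrinkFactor = as.numeric(shrinkFactor), strict = isTRUE(strict),
      binDof = binDof)
}

#' Grid-search result
#'
#' @slot aOpt,bOpt optimized weight parameters (both >= 0).
#' @slot objective binned-wGooF variance at the optimum.
#' @slot nIterations grid refinements performed.
#' @slot converged `TRUE` when both step sizes fell below their stops.
#' @slot trace per-iteration data.frame: centre, step sizes, best cell and
#'   its objective, per-axis edge flags.
#' @slot evaluations every (a, b, objective) triple evaluated, tagged by
#'   iteration.
#' @export
setClass("OptimizationResult",
  representation(aOpt = "numeric", bOpt = "numeric", objective = "numeric",
                 nIterations = "integer", converged = "logical",
                 trace = "data.frame", evaluations = "data.frame"))

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf(
    "OptimizationResult: a=%.6g b=%.6g  objective=%.6g  (%d iterations, %s)\n",
    object@aOpt, object@bOpt, object@objective, object@nIterations,
    if (object@converged) "converged" else "max iterations reached"))
})

#' Normal probability plot data
#'
#' Every-point normal probability plot of weighted residuals
#' \eqn{\sqrt{w}\,(F_o^2 - F_c^2)}: the sorted deviates against the
#' standard-normal quantiles \eqn{\Phi^{-1}((i-0.5)/n)}, plus the
#' interquartile regression line (ordinary least squares restricted to the
#' central half of the ranks, which removes bias from large outliers).
#' Slope 1 and intercept 0 indicate normally distributed residuals.
#'
#' @slot observed sorted ascending weighted deviates.
#' @slot expected matching normal order-statistic quantiles (ascending,
#'   antisymmetric about zero under index reversal).
#' @slot slope,intercept interquartile regression coefficients.
#' @slot n point count.
#' @slot points data.frame mapping each rank back to its reflection
#'   (`rank`, `expected`, `observed`, `h`, `k`, `l`, `fobsSq`, `fcalcSq`,
#'   `sigmaFobsSq`, `w`); empty when the deviates carry no reflection
#'   identity.
#' @export
setClass("NppResult",
  representation(observed = "numeric", expected = "numeric",
                 slope = "numeric", intercept = "numeric",
                 n = "integer", points = "data.frame"),
  validity = function(object) {
    if (length(object@observed) != object@n ||
        length(object@expected) != object@n)
      return("observed and expected must both have length n")
    if (is.unsorted(object@observed)) return("observed must be sorted ascending")
    if (is.unsorted(object@expected)) return("expected must be sorted ascending")
    TRUE
  })

setMethod("show", "NppResult", function(object) {
  cat(sprintf("NppResult: n=%d  IQ regression y = %.4f x %+.5f\n",
              object@n, object@slope, object@intercept))
})

#' Refinement statistics
#'
#' Conventional residual R1, weighted residual wR2, goodness of fit with
#' statistical weights (GooF) and with the applied scheme (wGooF).  With
#' statistical weights the last two coincide by construction.
#'
#' @slot r1,wr2,goof,wgoof dimensionless statistics, all >= 0.
#' @slot n reflection count; @slot p refined parameter count (n > p).
#' @export
setClass("RefinementStats",
  representation(r1 = "numeric", wr2 = "numeric", goof = "numeric",
                 wgoof = "numeric", n = "integer", p = "integer"),
  validity = function(object) {
    if (object@n <= object@p) return("need n > p")
    if (any(c(object@r1, object@wr2, object@goof, object@wgoof) < 0))
      return("statistics must be >= 0")
    TRUE
  })

setMethod("show", "RefinementStats", function(object) {
  cat(sprintf("RefinementStats (n=%d, p=%d):\n", object@n, object@p))
  cat(sprintf("  R1    = %.4f\n  wR2   = %.4f\n  GooF  = %.4f\n  wGooF = %.4f\n",
              object@r1, object@wr2, object@goof, object@wgoof))
})
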