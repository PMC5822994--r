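#' Composite intensity P
#'
#' The f-weighted blend of observed and calculated squared structure
#' factors used throughout the SHELXL-style weight:
#' \eqn{P = f\,\max(F_o^2, 0) + (1 - f)\,F_c^2}.  Negative observed
#' intensities are clamped to zero here (and only here), so P >= 0
#' whenever Fc^2 >= 0.  The default `f = 1/3` reduces the bias of using
#' Fo^2 or Fc^2 alone.
#'
#' @param fobsSq,fcalcSq observed and calculated F^2 (vectors recycle).
#' @param f mixing fraction in \[0, 1\].
#' @return Numeric vector of P values.
#' @examples
#' compositeP(6, 3)        # (6 + 2*3)/3 = 4
#' compositeP(-3, 3)       # negative Fo^2 clamped: 2
#' @export
compositeP <- function(fobsSq, fcalcSq, f = 1 / 3) {
  if (!is.finite(f) || f < 0 || f > 1)
    validationError("mixing fraction f must lie in [0, 1]")
  f * pmax(fobsSq, 0) + (1 - f) * fcalcSq
}

#' Resolution factor q of the weight
#'
#' The q factor multiplying the weight, switched by the sign of parameter
#' c: q = 1 when c = 0, q = exp(c s^2) when c > 0 and q = 1 - exp(c s^2)
#' when c < 0, with s = sin(theta)/lambda.
#'
#' @param c the c parameter of the scheme.
#' @param s sin(theta)/lambda values (Å^-1, >= 0).
#' @return Numeric vector of q values, strictly positive.
#' @export
qFactor <- function(c, s) {
  if (any(!is.finite(s)) || any(s < 0))
    validationError("sin(theta)/lambda must be finite and >= 0")
  if (c == 0) return(rep(1, length(s)))
  if (c > 0) return(exp(c * s^2))
  q <- 1 - exp(c * s^2)
  if (any(q <= 0))
    validationError("q = 1 - exp(c s^2) is non-positive (c < 0 with s = 0); weight undefined")
  q
}

#' Per-reflection weights of a SHELXL-style scheme
#'
#' Evaluates \eqn{w = q / [\sigma^2(F_o^2) + (aP)^2 + bP + d +
#' e\,\sin\theta/\lambda]} for every reflection.  With
#' a = b = c = d = e = 0 this is exactly the statistical weight
#' \eqn{w = 1/\sigma^2(F_o^2)}.  The resolution variable s is only needed
#' (and the set's unit cell only required) when c or e is non-zero.
#'
#' @param rs a [ReflectionSet-class].
#' @param scheme a [WeightingScheme-class].
#' @param s optional precomputed sin(theta)/lambda vector; computed from
#'   the set's cell when needed and absent.
#' @return Numeric vector of strictly positive weights, one per
#'   reflection, in set order.
#' @export
reflectionWeights <- function(rs, scheme, s = NULL) {
  d <- rs@refl
  if (nrow(d) == 0) validationError("empty ReflectionSet: no weights to compute")
  needS <- scheme@c != 0 || scheme@e != 0
  if (needS && is.null(s)) s <- resolutionS(rs)
  P <- compositeP(d$fobsSq, d$fcalcSq, scheme@f)
  denom <- d$sigmaFobsSq^2 + (scheme@a * P)^2 + scheme@b * P + scheme@d
  if (scheme@e != 0) denom <- denom + scheme@e * s
  if (any(denom <= 0)) {
    bad <- which(denom <= 0)
    validationError(sprintf(
      "non-positive weight denominator for reflection(s): %s",
      paste(sprintf("(%d %d %d)", d$h[bad], d$k[bad], d$l[bad]),
            collapse = ", ")))
  }
  q <- if (needS) qFactor(scheme@c, s) else 1
  q / denom
}

#' Apply intensity, I/sigma and resolution cut-offs
#'
#' Keeps a reflection iff Fo^2 >= `minIntensity`, Fo^2/sigma(Fo^2) >=
#' `minIOverSigma` and s <= `maxSinThetaOverLambda` (unset cuts impose
#' nothing).  Order is preserved.  The resolution cut needs the set's
#' unit cell.
#'
#' @param rs a [ReflectionSet-class].
#' @param spec a [FilterSpec-class].
#' @param counts if `TRUE`, return `list(set, removed)` where `removed`
#'   counts reflections failing each criterion (a reflection can fail
#'   several).
#' @return The filtered `ReflectionSet` (or the list above).  An empty
#'   result is a validation error: there is nothing left to optimize.
#' @export
applyFilters <- function(rs, spec = filterSpec(), counts = FALSE) {
  d <- rs@refl
  keep <- rep(TRUE, nrow(d))
  removed <- c(intensity = 0L, iOverSigma = 0L, resolution = 0L)
  if (!is.na(spec@minIntensity)) {
    ok <- d$fobsSq >= spec@minIntensity
    removed["intensity"] <- sum(!ok)
    keep <- keep & ok
  }
  if (!is.na(spec@minIOverSigma)) {
    ok <- d$fobsSq / d$sigmaFobsSq >= spec@minIOverSigma
    removed["iOverSigma"] <- sum(!ok)
    keep <- keep & ok
  }
  if (!is.na(spec@maxSinThetaOverLambda)) {
    ok <- resolutionS(rs) <= spec@maxSinThetaOverLambda
    removed["resolution"] <- sum(!ok)
    keep <- keep & ok
  }
  if (!any(keep))
    validationError(sprintf(
      "all %d reflections removed by cut-offs (intensity: %d, I/sigma: %d, resolution: %d); nothing to optimize",
      nrow(d), removed["intensity"], removed["iOverSigma"],
      removed["resolution"]))
  out <- rs[keep]
  if (counts) list(set = out, removed = removed, nKept = sum(keep)) else out
}

#' Weighted goodness of fit
#'
#' \eqn{\mathrm{wGooF} = \sqrt{\sum_i w_i (F_{o,i}^2 - F_{c,i}^2)^2 /
#' (n - p)}}; approximately 1 when the weights correctly describe the
#' residual variance.
#'
#' @param rs a [ReflectionSet-class].
#' @param weights positive per-reflection weights.
#' @param p refined parameter count (n > p; defaults to the set's).
#' @return The wGooF value (>= 0).
#' @export
wGoof <- function(rs, weights, p = nParams(rs)) {
  d <- rs@refl
  n <- nrow(d)
  if (is.na(p)) validationError("refined parameter count p is unknown")
  if (n <= p) validationError(sprintf("need n > p (n = %d, p = %d)", n, p))
  if (length(weights) != n || any(weights <= 0))
    validationError("weights must be positive, one per reflection")
  sqrt(sum(weights * (d$fobsSq - d$fcalcSq)^2) / (n - p))
}

#' Refinement statistics R1, wR2, GooF and wGooF
#'
#' R1 = sum(| |Fo| - |Fc| |) / sum(|Fo|) with |Fo| = sqrt(max(Fo^2, 0));
#' wR2 = sqrt(sum(w Delta^2) / sum(w (Fo^2)^2)); wGooF uses the applied
#' scheme's weights and GooF the statistical weights 1/sigma^2, so the
#' two coincide exactly under the statistical scheme.
#'
#' @param rs a [ReflectionSet-class].
#' @param scheme the applied [WeightingScheme-class].
#' @param p refined parameter count (defaults to the set's).
#' @return A [RefinementStats-class].
#' @export
refinementStats <- function(rs, scheme, p = nParams(rs)) {
  d <- rs@refl
  n <- nrow(d)
  if (is.na(p)) validationError("refined parameter count p is unknown")
  if (n <= p) validationError(sprintf("need n > p (n = %d, p = %d)", n, p))
  w <- reflectionWeights(rs, scheme)
  wStat <- 1 / d$sigmaFobsSq^2
  fo <- sqrt(pmax(d$fobsSq, 0))
  fc <- sqrt(d$fcalcSq)
  if (sum(fo) == 0) validationError("sum(|Fo|) is zero; R1 undefined")
  delta2 <- (d$fobsSq - d$fcalcSq)^2
  denomWr2 <- sum(w * d$fobsSq^2)
  if (denomWr2 == 0) validationError("sum(w Fo^4) is zero; wR2 undefined")
  new("RefinementStats",
      r1 = sum(abs(fo - fc)) / sum(fo),
      wr2 = sqrt(sum(w * delta2) / denomWr2),
      goof = sqrt(sum(wStat * delta2) / (n - p)),
      wgoof = sqrt(sum(w * delta2) / (n - p)),
      n = as.integer(n), p = as.integer(p))
}
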