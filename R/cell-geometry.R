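## Resolution machinery: the reciprocal metric tensor G* gives
## 1/d^2(hkl) = h' G* h and hence sin(theta)/lambda = 1/(2d), the
## resolution variable entering the q and e terms of the weight and the
## resolution cut-off.

directMetric <- function(cell) {
  r <- c(cell@alpha, cell@beta, cell@gamma) * pi / 180
  a <- cell@a; b <- cell@b; cc <- cell@c
  matrix(c(a * a,            a * b * cos(r[3]), a * cc * cos(r[2]),
           a * b * cos(r[3]), b * b,            b * cc * cos(r[1]),
           a * cc * cos(r[2]), b * cc * cos(r[1]), cc * cc),
         nrow = 3, byrow = TRUE)
}

#' Reciprocal metric tensor of a unit cell
#'
#' Computes G* (Å^-2), the inverse of the direct metric tensor, such that
#' `1/d^2(h,k,l) = t(h) %*% G* %*% h` for any Miller index triple.
#'
#' @param cell a [UnitCell-class].
#' @return A [ReciprocalMetric-class].
#' @examples
#' reciprocalMetric(unitCell(10, 10, 10))  # diag(0.01, 0.01, 0.01)
#' @export
reciprocalMetric <- function(cell) {
  if (!is(cell, "UnitCell")) validationError("cell must be a UnitCell")
  validObject(cell)
  g <- directMetric(cell)
  gstar <- solve(g)
  gstar <- (gstar + t(gstar)) / 2   # enforce exact symmetry
  new("ReciprocalMetric", g = gstar)
}

#' Resolution variable sin(theta)/lambda of reflections
#'
#' Evaluates s = sin(theta)/lambda = 1/(2d) with 1/d^2 = h' G* h, in
#' Å^-1.  Vectorized over the index triples.
#'
#' @param cell a [UnitCell-class].
#' @param h,k,l integer Miller indices (equal lengths); (0,0,0) is
#'   rejected.
#' @return Numeric vector of s values (strictly positive).
#' @examples
#' sinThetaOverLambda(unitCell(10, 10, 10), 1, 0, 0)  # 0.05
#' @export
sinThetaOverLambda <- function(cell, h, k, l) {
  if (any(h == 0 & k == 0 & l == 0))
    validationError("sin(theta)/lambda is undefined for (0,0,0)")
  gstar <- reciprocalMetric(cell)@g
  H <- cbind(h, k, l)
  invDsq <- rowSums((H %*% gstar) * H)
  0.5 * sqrt(invDsq)
}

#' @rdname sinThetaOverLambda
#' @param rs a [ReflectionSet-class] carrying a unit cell.
#' @return `resolutionS` returns one s value per reflection, in set order.
#' @export
resolutionS <- function(rs) {
  if (is.null(rs@cell))
    validationError("ReflectionSet carries no unit cell; cannot compute resolution")
  d <- rs@refl
  sinThetaOverLambda(rs@cell, d$h, d$k, d$l)
}

#' @rdname sinThetaOverLambda
#' @return `dSpacing` returns lattice-plane spacings d = 1/(2s) in Å.
#' @export
dSpacing <- function(cell, h, k, l) 1 / (2 * sinThetaOverLambda(cell, h, k, l))
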