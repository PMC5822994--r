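#' Generate a synthetic reflection set with the scheme's variance model
#'
#' Emulates a measured structure-factor dataset whose errors follow
#' exactly the variance structure the weighting scheme models, so the
#' optimizer and the normality diagnostics can be exercised and validated
#' offline:
#'
#' * Miller indices are drawn without repetition from the lattice points
#'   with 0 < sin(theta)/lambda <= `sMax` for the given cell.
#' * True intensities Fc^2 are exponential with mean `intensityScale`
#'   (Wilson-type acentric intensity statistics).
#' * Reported uncertainties are
#'   `sigma = sigmaFloor * sqrt(1 + Fc^2/intensityScale)` — larger for
#'   stronger reflections, as counting statistics give.
#' * Observations are `Fo^2 = Fc^2 + eps` with
#'   `eps ~ N(0, sigma^2 + (aTrue*P)^2 + bTrue*P)` and `P = Fc^2` on the
#'   generator side (Fo^2 does not exist yet when the error is drawn;
#'   this mirrors the real circularity of weights that depend on the
#'   data they model, and analysis-side P blending Fo^2 differs only
#'   mildly).
#'
#' With `aTrue = bTrue = 0` the reported sigmas describe the errors
#' completely and statistical weights are exactly right; positive
#' `aTrue`/`bTrue` reproduce the variance inflation that makes
#' statistically weighted refinements show wGooF well above 1 and a
#' too-steep normal probability plot.
#'
#' The generator is fully reproducible from `seed` and leaves the
#' global RNG state untouched.
#'
#' @param n number of reflections (>= 20).
#' @param seed RNG seed.
#' @param cell a [UnitCell-class] (default cubic, 10 Å).
#' @param sMax resolution limit in Å^-1 (default 1.0).
#' @param intensityScale mean true intensity (refinement scale).
#' @param sigmaFloor baseline reported sigma scale.
#' @param aTrue,bTrue variance-inflation parameters (>= 0).
#' @param f mixing fraction recorded for reference (the generator's P is
#'   pure Fc^2).
#' @param wavelength wavelength recorded on the set (Å).
#' @return A [ReflectionSet-class] carrying the cell and wavelength.
#' @examples
#' rs <- generateReflections(200, seed = 42, aTrue = 0.05, bTrue = 0.5)
#' @export
generateReflections <- function(n, seed, cell = unitCell(10, 10, 10),
                                sMax = 1.0, intensityScale = 100,
                                sigmaFloor = 1, aTrue = 0, bTrue = 0,
                                f = 1 / 3, wavelength = 0.71073) {
  n <- as.integer(n)
  if (n < 20) validationError("need n >= 20")
  if (intensityScale <= 0 || sigmaFloor <= 0 || sMax <= 0)
    validationError("sMax, intensityScale and sigmaFloor must be > 0")
  if (aTrue < 0 || bTrue < 0)
    validationError("aTrue and bTrue must be >= 0")

  gstar <- reciprocalMetric(cell)@g
  hmax <- ceiling(2 * sMax / sqrt(diag(gstar)))
  lat <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                     l = -hmax[3]:hmax[3])
  H <- as.matrix(lat)
  s <- 0.5 * sqrt(rowSums((H %*% gstar) * H))
  lat <- lat[s > 0 & s <= sMax, , drop = FALSE]
  if (nrow(lat) < n)
    validationError(sprintf(
      "only %d lattice points inside sMax = %g; cannot draw %d distinct reflections",
      nrow(lat), sMax, n))

  ## seed the draw locally; restore whatever RNG state the caller had
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)

  pick <- lat[sample(nrow(lat), n), , drop = FALSE]
  fc2 <- stats::rexp(n, rate = 1 / intensityScale)
  sigma <- sigmaFloor * sqrt(1 + fc2 / intensityScale)
  P <- fc2
  varTot <- sigma^2 + (aTrue * P)^2 + bTrue * P
  fo2 <- fc2 + stats::rnorm(n, mean = 0, sd = sqrt(varTot))
  reflectionSet(pick$h, pick$k, pick$l, fo2, sigma, fc2,
                cell = cell, wavelength = wavelength)
}

#' Write a synthetic refinement bundle (.fcf + .ins + .cif)
#'
#' Emits the three files the command-line workflow consumes: the
#' structure-factor CIF loop, a minimal SHELX instruction file with the
#' CELL card (and a statistical-weight WGHT card), and a minimal .cif
#' carrying the refined-parameter count — enough to exercise the whole
#' optimize/diagnose path offline.
#'
#' @param rs a [ReflectionSet-class] with a cell and wavelength.
#' @param dir output directory (created if needed).
#' @param prefix file name stem.
#' @param p refined parameter count written to the .cif.
#' @return Named character vector of the three paths, invisibly.
#' @export
writeSyntheticBundle <- function(rs, dir, prefix = "synthetic", p = 50L) {
  if (is.null(rs@cell) || is.na(rs@wavelength))
    validationError("bundle needs a ReflectionSet with cell and wavelength")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fcf = file.path(dir, paste0(prefix, ".fcf")),
             ins = file.path(dir, paste0(prefix, ".ins")),
             cif = file.path(dir, paste0(prefix, ".cif")))
  writeFcf(rs, paths["fcf"])
  cl <- rs@cell
  writeLines(c(
    sprintf("TITL %s (synthetic)", prefix),
    sprintf("CELL %.5f %.6f %.6f %.6f %.5f %.5f %.5f", rs@wavelength,
            cl@a, cl@b, cl@c, cl@alpha, cl@beta, cl@gamma),
    "WGHT 0.0 0.0"), paths["ins"])
  writeLines(c(sprintf("data_%s", prefix),
               sprintf("_refine_ls_number_parameters %d", as.integer(p))),
             paths["cif"])
  invisible(paths)
}
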