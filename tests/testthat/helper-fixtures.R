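# Small in-code fixtures shared across test files.

tmpFile <- function(lines, ext = "") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal ReflectionSet with unit sigmas unless given
makeRs <- function(fobsSq, fcalcSq, sigma = rep(1, length(fobsSq)),
                   cell = NULL, nParams = NA_integer_) {
  n <- length(fobsSq)
  reflectionSet(h = seq_len(n), k = rep(0L, n), l = rep(1L, n),
                fobsSq = fobsSq, sigmaFobsSq = sigma, fcalcSq = fcalcSq,
                cell = cell, nParams = nParams)
}

# two-reflection LIST-4 style .fcf body
fcfLines <- function(extraTags = character(), rows = NULL) {
  if (is.null(rows))
    rows <- c(" 1 0 0 4.00 4.10 0.20",
              " 0 1 0 1.00 0.90 0.10")
  c("data_test",
    "_cell_length_a 10.0", "_cell_length_b 10.0", "_cell_length_c 10.0",
    "_cell_angle_alpha 90.0", "_cell_angle_beta 90.0",
    "_cell_angle_gamma 90.0",
    "_diffrn_radiation_wavelength 0.71073",
    "loop_",
    " _refln_index_h", " _refln_index_k", " _refln_index_l",
    " _refln_F_squared_calc", " _refln_F_squared_meas",
    " _refln_F_squared_sigma",
    extraTags,
    rows)
}

# instance whose computed (unfloored) aStart is ~1e-5: constant reflections
# with median(Delta^2) tuned so the inferred variance excess is 1e-6
guardInstance <- function(n = 30) {
  delta <- sqrt(qchisq(0.5, df = 1) * (1 + 1e-6))
  makeRs(fobsSq = rep(100 + delta, n), fcalcSq = rep(100, n),
         sigma = rep(1, n))
}
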