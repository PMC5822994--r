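## Readers for the structure-factor and metadata files of SHELX and XD
## refinements.  Scope is deliberately narrow: refln CIF loops and scalar
## items for .fcf/.cif, the CELL/WGHT instruction cards for .ins, the
## CELL/WAVE records for .mas, and fixed-column tables for .fco.  Parsing
## is column-tag driven for CIF (never positional), numbers are free
## format with Fortran "D" exponents accepted, and every parse error
## carries a line or tag reference.

splitTokens <- function(line) {
  line <- sub("^\\s+", "", line)
  if (nchar(line) == 0) return(character())
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

## Scalar CIF item: first occurrence of `tag <value>` outside loop bodies
## is good enough for the metadata items handled here.
cifScalar <- function(lines, tag) {
  pat <- paste0("^\\s*", tag, "\\s+")
  hit <- grep(pat, lines)
  if (length(hit) == 0) {
    ## value on the following line
    hit2 <- grep(paste0("^\\s*", tag, "\\s*$"), lines)
    if (length(hit2) == 0) return(NULL)
    nxt <- hit2[1] + 1
    while (nxt <= length(lines) && !nzchar(trimws(lines[nxt]))) nxt <- nxt + 1
    if (nxt > length(lines)) return(NULL)
    return(list(value = splitTokens(lines[nxt])[1], line = nxt))
  }
  val <- splitTokens(sub(pat, "", lines[hit[1]]))[1]
  list(value = val, line = hit[1])
}

## Parse every loop_ construct: tags, data rows (wrapping allowed) and the
## source line of each row.
cifLoops <- function(lines) {
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      tags <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, splitTokens(lines[j])[1])
        j <- j + 1L
      }
      toks <- character(); tokLine <- integer()
      while (j <= n) {
        ln <- lines[j]
        if (grepl("^\\s*(loop_|_|data_|#)", ln) || grepl("^\\s*$", ln)) break
        tk <- splitTokens(ln)
        toks <- c(toks, tk)
        tokLine <- c(tokLine, rep(j, length(tk)))
        j <- j + 1L
      }
      if (length(tags) > 0 && length(toks) > 0) {
        nr <- length(toks) %/% length(tags)
        if (nr * length(tags) != length(toks))
          parseError(sprintf(
            "loop ending at line %d: %d values are not a multiple of %d tags",
            j - 1L, length(toks), length(tags)))
        vals <- matrix(toks, nrow = nr, ncol = length(tags), byrow = TRUE)
        colnames(vals) <- tags
        rowLine <- tokLine[seq(1L, by = length(tags), length.out = nr)]
        loops[[length(loops) + 1L]] <- list(tags = tags, values = vals,
                                            rowLine = rowLine)
      }
      i <- j
    } else i <- i + 1L
  }
  loops
}

numCol <- function(vals, tag, rowLine) {
  x <- parseNum(vals[, tag])
  bad <- which(is.na(x))
  if (length(bad) > 0)
    parseError(sprintf("non-numeric value '%s' for %s at line %d",
                       vals[bad[1], tag], tag, rowLine[bad[1]]))
  x
}

cifCell <- function(lines) {
  tags <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  vals <- lapply(tags, function(t) cifScalar(lines, t))
  if (any(vapply(vals, is.null, logical(1)))) return(NULL)
  ## strip standard-uncertainty suffixes like 10.0021(3)
  num <- parseNum(vapply(vals, function(v) sub("\\(.*\\)$", "", v$value),
                         character(1)))
  if (any(is.na(num))) return(NULL)
  unitCell(num[1], num[2], num[3], num[4], num[5], num[6])
}

#' Read a SHELXL .fcf structure-factor file
#'
#' Parses the refln CIF loop of a SHELXL LIST 4 or LIST 8 .fcf file.
#' Columns are matched by CIF tag (`_refln_index_h/k/l`,
#' `_refln_F_squared_calc`, `_refln_F_squared_meas`,
#' `_refln_F_squared_sigma`), never by position, so permuting loop
#' columns has no effect.  Unit cell and wavelength are captured when the
#' corresponding items are present.  When a `_refln_observed_status`
#' column exists (LIST 8), rows not flagged `o` (observed) are excluded
#' by default.
#'
#' @param path path to the .fcf file.
#' @param keepUnobserved keep rows whose observed-status flag is not `o`.
#' @return A [ReflectionSet-class], loop row order preserved.
#' @export
readFcf <- function(path, keepUnobserved = FALSE) {
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  loops <- cifLoops(lines)
  idxTags <- c("_refln_index_h", "_refln_index_k", "_refln_index_l")
  reqTags <- c("_refln_F_squared_calc", "_refln_F_squared_meas",
               "_refln_F_squared_sigma")
  hit <- NULL
  for (lp in loops) if (all(idxTags %in% lp$tags)) { hit <- lp; break }
  if (is.null(hit))
    formatError("no refln loop with _refln_index_h/k/l tags found")
  missing <- setdiff(reqTags, hit$tags)
  if (length(missing) > 0)
    formatError(sprintf("refln loop is missing required tag(s): %s",
                        paste(missing, collapse = ", ")))
  v <- hit$values; rl <- hit$rowLine
  if ("_refln_observed_status" %in% hit$tags && !keepUnobserved) {
    keep <- v[, "_refln_observed_status"] == "o"
    v <- v[keep, , drop = FALSE]; rl <- rl[keep]
  }
  if (nrow(v) == 0) validationError("refln loop has no (observed) rows")
  h <- numCol(v, "_refln_index_h", rl)
  k <- numCol(v, "_refln_index_k", rl)
  l <- numCol(v, "_refln_index_l", rl)
  fc2 <- numCol(v, "_refln_F_squared_calc", rl)
  fo2 <- numCol(v, "_refln_F_squared_meas", rl)
  sig <- numCol(v, "_refln_F_squared_sigma", rl)
  bad <- which(sig <= 0)
  if (length(bad) > 0)
    validationError(sprintf("sigma(Fo^2) <= 0 for reflection(s): %s",
                            paste(sprintf("(%d %d %d)", h[bad], k[bad],
                                          l[bad]), collapse = ", ")))
  wl <- cifScalar(lines, "_diffrn_radiation_wavelength")
  reflectionSet(h, k, l, fo2, sig, fc2, cell = cifCell(lines),
                wavelength = if (is.null(wl)) NA_real_ else parseNum(wl$value))
}

#' Read an XD .fco structure-factor file
#'
#' Reads the fixed-column reflection table of an XD (multipolar
#' refinement) .fco file.  Header lines are skipped up to the first line
#' that has exactly `length(columns)` whitespace-separated tokens, all
#' numeric, with integers in the h, k, l positions; every following
#' non-blank line must be a data row with that field count.  The default
#' column order is `h k l Fc^2 Fo^2 sigma(Fo^2)`; XD versions vary, so
#' the order can be overridden.
#'
#' @param path path to the .fco file.
#' @param columns character permutation of
#'   `c("h","k","l","fcalcSq","fobsSq","sigmaFobsSq")` giving the file's
#'   column order.
#' @return A [ReflectionSet-class], row order preserved.
#' @export
readFco <- function(path,
                    columns = c("h", "k", "l", "fcalcSq", "fobsSq",
                                "sigmaFobsSq")) {
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  want <- c("h", "k", "l", "fcalcSq", "fobsSq", "sigmaFobsSq")
  if (!setequal(columns, want) || length(columns) != 6)
    configError("columns must be a permutation of h, k, l, fcalcSq, fobsSq, sigmaFobsSq")
  lines <- readLines(path, warn = FALSE)
  nc <- length(columns)
  hklPos <- match(c("h", "k", "l"), columns)
  isData <- function(tk) {
    length(tk) == nc && !any(is.na(parseNum(tk))) &&
      all(grepl("^[+-]?[0-9]+$", tk[hklPos]))
  }
  start <- 0L
  for (i in seq_along(lines)) {
    if (isData(splitTokens(lines[i]))) { start <- i; break }
  }
  if (start == 0L)
    validationError("no data rows found (header only or empty file)")
  rows <- list(); rowLine <- integer()
  for (i in start:length(lines)) {
    tk <- splitTokens(lines[i])
    if (length(tk) == 0) next
    if (length(tk) != nc)
      parseError(sprintf("line %d: expected %d fields, found %d",
                         i, nc, length(tk)))
    x <- parseNum(tk)
    if (any(is.na(x)))
      parseError(sprintf("line %d: non-numeric field '%s'",
                         i, tk[which(is.na(x))[1]]))
    rows[[length(rows) + 1L]] <- x
    rowLine <- c(rowLine, i)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- columns
  bad <- which(m[, "sigmaFobsSq"] <= 0)
  if (length(bad) > 0)
    validationError(sprintf("sigma(Fo^2) <= 0 at line(s): %s",
                            paste(rowLine[bad], collapse = ", ")))
  reflectionSet(m[, "h"], m[, "k"], m[, "l"], m[, "fobsSq"],
                m[, "sigmaFobsSq"], m[, "fcalcSq"])
}

#' Read metadata from a SHELX .ins/.res instruction file
#'
#' Extracts the CELL card (wavelength followed by the six cell
#' parameters) and, when present, the WGHT card.  WGHT carries up to six
#' numbers filling a–f in order; absent trailing values take the scheme
#' defaults (0.1, 0, 0, 0, 0, 1/3), and a missing WGHT card returns the
#' full default scheme.
#'
#' @param path path to the .ins file.
#' @return `list(cell = UnitCell, wavelength = numeric,
#'   weight = WeightingScheme)`.
#' @export
readInsMetadata <- function(path) {
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  cellLn <- grep("^\\s*CELL\\b", lines, ignore.case = TRUE)
  if (length(cellLn) == 0) formatError("no CELL card found")
  tk <- splitTokens(lines[cellLn[1]])[-1]
  if (length(tk) != 7)
    parseError(sprintf("line %d: CELL card needs 7 values (lambda + 6 cell parameters), found %d",
                       cellLn[1], length(tk)))
  x <- parseNum(tk)
  if (any(is.na(x)))
    parseError(sprintf("line %d: non-numeric CELL value '%s'",
                       cellLn[1], tk[which(is.na(x))[1]]))
  cell <- unitCell(x[2], x[3], x[4], x[5], x[6], x[7])
  wght <- c(0.1, 0, 0, 0, 0, 1 / 3)
  wLn <- grep("^\\s*WGHT\\b", lines, ignore.case = TRUE)
  if (length(wLn) > 0) {
    wt <- parseNum(splitTokens(lines[wLn[1]])[-1])
    if (any(is.na(wt)) || length(wt) > 6)
      parseError(sprintf("line %d: malformed WGHT card", wLn[1]))
    wght[seq_along(wt)] <- wt
  }
  list(cell = cell, wavelength = x[1],
       weight = weightingScheme(wght[1], wght[2], wght[3], wght[4],
                                wght[5], wght[6]))
}

#' Read metadata from an XD .mas master file
#'
#' Dialect handled: a `CELL` record with six numbers (a b c alpha beta
#' gamma, Å and degrees) and a `WAVE` record with the wavelength in Å.
#' The wavelength record is optional.
#'
#' @param path path to the .mas file.
#' @return `list(cell = UnitCell, wavelength = numeric)` (`NA` wavelength
#'   when no WAVE record exists).
#' @export
readMasMetadata <- function(path) {
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  cellLn <- grep("^\\s*CELL\\b", lines, ignore.case = TRUE)
  if (length(cellLn) == 0) formatError("no CELL record found")
  tk <- splitTokens(lines[cellLn[1]])[-1]
  if (length(tk) < 6)
    parseError(sprintf("line %d: CELL record needs 6 values, found %d",
                       cellLn[1], length(tk)))
  x <- parseNum(tk[1:6])
  if (any(is.na(x)))
    parseError(sprintf("line %d: non-numeric CELL value '%s'",
                       cellLn[1], tk[which(is.na(x))[1]]))
  wl <- NA_real_
  wLn <- grep("^\\s*WAVE\\b", lines, ignore.case = TRUE)
  if (length(wLn) > 0) {
    wtk <- splitTokens(lines[wLn[1]])[-1]
    wl <- parseNum(wtk[1])
    if (length(wtk) < 1 || is.na(wl))
      parseError(sprintf("line %d: malformed WAVE record", wLn[1]))
  }
  list(cell = unitCell(x[1], x[2], x[3], x[4], x[5], x[6]),
       wavelength = wl)
}

#' Read the refined-parameter count from a .cif file
#'
#' @param path path to the CIF file carrying
#'   `_refine_ls_number_parameters`.
#' @return The parameter count p as a positive integer.
#' @export
readCifNParams <- function(path) {
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  it <- cifScalar(lines, "_refine_ls_number_parameters")
  if (is.null(it))
    formatError("item _refine_ls_number_parameters not found")
  x <- parseNum(it$value)
  if (is.na(x) || x != round(x))
    parseError(sprintf("line %d: _refine_ls_number_parameters is not an integer: '%s'",
                       it$line, it$value))
  if (x < 1)
    validationError("_refine_ls_number_parameters must be >= 1")
  as.integer(x)
}

#' Write a ReflectionSet as a SHELXL-style .fcf CIF loop
#'
#' Emits a CIF data block readable by [readFcf()]; numeric fields are
#' written with enough digits that a read/write round trip reproduces
#' them.
#'
#' @param rs a non-empty [ReflectionSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFcf <- function(rs, path) {
  d <- rs@refl
  if (nrow(d) == 0) validationError("refusing to write an empty ReflectionSet")
  out <- c("data_weightopt", "")
  if (!is.null(rs@cell)) {
    cl <- rs@cell
    out <- c(out,
             sprintf("_cell_length_a    %.6f", cl@a),
             sprintf("_cell_length_b    %.6f", cl@b),
             sprintf("_cell_length_c    %.6f", cl@c),
             sprintf("_cell_angle_alpha %.5f", cl@alpha),
             sprintf("_cell_angle_beta  %.5f", cl@beta),
             sprintf("_cell_angle_gamma %.5f", cl@gamma))
  }
  if (!is.na(rs@wavelength))
    out <- c(out, sprintf("_diffrn_radiation_wavelength %.6f", rs@wavelength))
  out <- c(out, "", "loop_",
           " _refln_index_h", " _refln_index_k", " _refln_index_l",
           " _refln_F_squared_calc", " _refln_F_squared_meas",
           " _refln_F_squared_sigma",
           sprintf("%d %d %d %.10g %.10g %.10g",
                   d$h, d$k, d$l, d$fcalcSq, d$fobsSq, d$sigmaFobsSq))
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ioError(sprintf("cannot write to %s", path))
  invisible(path)
}
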