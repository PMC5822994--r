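## Classed conditions so callers (and the CLI) can distinguish error classes.

wtStop <- function(class, msg) {
  cnd <- structure(
    class = c(paste0("weightopt_", class), "weightopt_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cnd)
}

formatError     <- function(msg) wtStop("format_error", msg)
parseError      <- function(msg) wtStop("parse_error", msg)
validationError <- function(msg) wtStop("validation_error", msg)
configError     <- function(msg) wtStop("config_error", msg)
ioError         <- function(msg) wtStop("io_error", msg)

## Free-format numeric parser accepting Fortran-style D exponents
## ("1.5D-02"), as found in legacy crystallographic files.
parseNum <- function(x) {
  suppressWarnings(as.numeric(gsub("[dD]", "e", x)))
}
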