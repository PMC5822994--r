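#' @rdname ReflectionSet-class
#' @param object,x a `ReflectionSet`.
#' @export
setGeneric("reflections", function(x) standardGeneric("reflections"))

#' @rdname ReflectionSet-class
#' @export
setGeneric("nReflections", function(x) standardGeneric("nReflections"))

#' @rdname ReflectionSet-class
#' @export
setGeneric("cellOf", function(x) standardGeneric("cellOf"))

#' @rdname ReflectionSet-class
#' @param value replacement value.
#' @export
setGeneric("cellOf<-", function(x, value) standardGeneric("cellOf<-"))

#' @rdname ReflectionSet-class
#' @export
setGeneric("wavelengthOf", function(x) standardGeneric("wavelengthOf"))

#' @rdname ReflectionSet-class
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' @rdname ReflectionSet-class
#' @export
setGeneric("nParams<-", function(x, value) standardGeneric("nParams<-"))

setMethod("reflections", "ReflectionSet", function(x) x@refl)
setMethod("nReflections", "ReflectionSet", function(x) nrow(x@refl))
setMethod("cellOf", "ReflectionSet", function(x) x@cell)
setMethod("cellOf<-", "ReflectionSet", function(x, value) {
  x@cell <- value
  validObject(x)
  x
})
setMethod("wavelengthOf", "ReflectionSet", function(x) x@wavelength)
setMethod("nParams", "ReflectionSet", function(x) x@nParams)
setMethod("nParams<-", "ReflectionSet", function(x, value) {
  x@nParams <- as.integer(value)
  x
})

setMethod("show", "ReflectionSet", function(object) {
  cat(sprintf("ReflectionSet with %d reflections\n", nReflections(object)))
  if (!is.null(object@cell)) show(object@cell)
  if (!is.na(object@wavelength))
    cat(sprintf("wavelength: %.5f Å\n", object@wavelength))
  if (!is.na(object@nParams))
    cat(sprintf("refined parameters: %d\n", object@nParams))
  if (nReflections(object) > 0)
    print(utils::head(object@refl, 4L))
})

#' @rdname ReflectionSet-class
#' @param i row (reflection) index.
#' @param j,drop,... ignored; present for generic compatibility.
#' @export
setMethod("[", "ReflectionSet", function(x, i, j, ..., drop = FALSE) {
  x@refl <- x@refl[i, , drop = FALSE]
  rownames(x@refl) <- NULL
  validObject(x)
  x
})
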