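#' Accessors for the spectral and pigment containers
#'
#' @param x a [SpectralTimeSeries-class] or [PigmentTimeSeries-class] object.
#' @return `wavelengths()` the wavelength grid (nm); `timePoints()` the
#'   acquisition/sampling times (s); `quantity()` the quantity tag;
#'   `concentrations()` the pigment-by-time matrix; `pigmentNames()` the
#'   pigment rownames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("quantity", function(x) standardGeneric("quantity"))

#' @rdname accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("pigmentNames", function(x) standardGeneric("pigmentNames"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralTimeSeries", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setMethod("timePoints", "SpectralTimeSeries", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("quantity", "SpectralTimeSeries", function(x) x@quantity)

#' @rdname accessors
#' @export
setMethod("timePoints", "PigmentTimeSeries", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("concentrations", "PigmentTimeSeries", function(x) x@concentrations)

#' @rdname accessors
#' @export
setMethod("pigmentNames", "PigmentTimeSeries",
          function(x) rownames(x@concentrations))

#' @describeIn accessors matrix of spectral values with wavelength rownames
#'   and time colnames.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "SpectralTimeSeries", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(format(x@wavelengths, trim = TRUE),
                      format(x@times, trim = TRUE))
  m
})

#' @describeIn accessors `c(n_wavelengths, n_times)`.
#' @export
setMethod("dim", "SpectralTimeSeries",
          function(x) c(length(x@wavelengths), length(x@times)))

setMethod("show", "SpectralTimeSeries", function(object) {
  cat(sprintf("SpectralTimeSeries: %s\n", object@quantity))
  cat(sprintf("  %d wavelengths: %.4g-%.4g nm\n",
              length(object@wavelengths),
              min(object@wavelengths), max(object@wavelengths)))
  cat(sprintf("  %d times: %.4g-%.4g s\n", length(object@times),
              min(object@times), max(object@times)))
  cat(sprintf("  values: [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
  invisible(object)
})

setMethod("show", "PigmentTimeSeries", function(object) {
  cat(sprintf("PigmentTimeSeries: %s (%s), replicate %d\n",
              object@species, object@lightCondition, object@replicate))
  cat(sprintf("  %d pigments x %d times; units mol (mol Chl a)^-1\n",
              nrow(object@concentrations), length(object@times)))
  cat(sprintf("  pigments: %s\n",
              paste(rownames(object@concentrations), collapse = ", ")))
  nmiss <- sum(is.na(object@concentrations))
  if (nmiss) cat(sprintf("  %d missing (nd) value(s)\n", nmiss))
  invisible(object)
})
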