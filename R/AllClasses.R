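#' @import methods
NULL

## Physical constants used in the photon-flux conversion. Values are kept at
## the precision conventionally printed for this conversion; changing them
## changes J_F in the 3rd significant digit at most.
.AVOGADRO <- 6.02e23        # mol^-1
.PLANCK <- 6.62e-34         # J s
.LIGHT_SPEED <- 299792458   # m s^-1
.FLUX_PREFACTOR <- 3.14e-3  # Lambertian hemispherical integration x 1e-3 scaling

#' Spectral quantity labels accepted by [SpectralTimeSeries()]
#' @export
spectralQuantities <- c(
  "radiance_W_m2_sr_nm", "irradiance_W_m2_nm", "reflectance_frac",
  "transmittance_frac", "absorbance_frac", "delta_absorbance"
)

#' Pigment names and chemistry tables
#'
#' `pigmentNamesAccepted` lists the carotenoid (and chlorophyll b) labels a
#' [PigmentTimeSeries()] may carry; concentrations are expressed per mole of
#' chlorophyll a, so Chl a itself is the normalizer rather than an entry.
#' `pigmentMolarMasses` gives molar masses in g/mol (standard chemistry
#' values) used to convert mass-per-area tables to mole ratios on load.
#'
#' @export
pigmentNamesAccepted <- c(
  "Neo", "Vio", "Ant", "Zea", "betaCar", "alphaCar", "Lut", "Lx", "Chlb"
)

#' @rdname pigmentNamesAccepted
#' @export
pigmentMolarMasses <- c(
  Chla = 893.5, Chlb = 907.5, Lut = 568.9, Zea = 568.9, Lx = 584.9,
  Ant = 584.9, Vio = 600.9, Neo = 600.9, alphaCar = 536.9, betaCar = 536.9
)

#' The leaf-disk sampling schedule (seconds) of the transient protocol
#' @export
pigmentSamplingSchedule <- c(0, 1, 2, 3, 5, 7, 10, 15, 20, 30, 40, 60, 90,
                             120, 180)

#' SpectralTimeSeries: a wavelength-by-time matrix of one spectral quantity
#'
#' The backbone container of all spectroscopy stages: rows are wavelengths
#' (nm, strictly increasing), columns are acquisition times (s, strictly
#' increasing, first sample at the start of the record), and `values` holds
#' the measured quantity (radiance, irradiance, reflectance, transmittance,
#' absorbance or delta-absorbance).
#'
#' @slot wavelengths numeric, strictly increasing wavelength grid in nm.
#' @slot times numeric, strictly increasing acquisition times in s.
#' @slot values numeric matrix `[n_wavelengths x n_times]`, finite everywhere.
#' @slot quantity one of [spectralQuantities].
#'
#' @export
setClass("SpectralTimeSeries",
  representation(
    wavelengths = "numeric",
    times = "numeric",
    values = "matrix",
    quantity = "character"
  )
)

setValidity("SpectralTimeSeries", function(object) {
  msg <- character()
  wl <- object@wavelengths
  tt <- object@times
  v <- object@values
  if (length(wl) < 1L) msg <- c(msg, "wavelength grid is empty")
  if (anyDuplicated(wl) || is.unsorted(wl, strictly = TRUE))
    msg <- c(msg, "wavelengths must be strictly increasing with no duplicates")
  if (length(tt) >= 2L && is.unsorted(tt, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (any(tt < 0)) msg <- c(msg, "times must be non-negative")
  if (nrow(v) != length(wl) || ncol(v) != length(tt))
    msg <- c(msg, sprintf("values must be a %d x %d matrix",
                          length(wl), length(tt)))
  if (!all(is.finite(v))) msg <- c(msg, "values must be finite everywhere")
  if (length(object@quantity) != 1L ||
      !object@quantity %in% spectralQuantities)
    msg <- c(msg, paste0("quantity must be one of: ",
                         paste(spectralQuantities, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralTimeSeries
#'
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param times strictly increasing acquisition times (s).
#' @param values numeric matrix `[length(wavelengths) x length(times)]`.
#' @param quantity one of [spectralQuantities].
#' @return A validated [SpectralTimeSeries-class] object. Reflectance or
#'   transmittance values outside `[-0.05, 1.05]` are tolerated (instrument
#'   noise/overshoot) but flagged with a warning.
#' @examples
#' sts <- SpectralTimeSeries(c(500, 510, 520), c(0, 1),
#'                           matrix(0.1, 3, 2), "reflectance_frac")
#' dim(sts)
#' @export
SpectralTimeSeries <- function(wavelengths, times, values, quantity) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  obj <- new("SpectralTimeSeries",
             wavelengths = as.numeric(wavelengths),
             times = as.numeric(times),
             values = values,
             quantity = quantity)
  if (quantity %in% c("reflectance_frac", "transmittance_frac") &&
      any(values < -0.05 | values > 1.05)) {
    warning(sprintf("%d %s value(s) outside [-0.05, 1.05]",
                    sum(values < -0.05 | values > 1.05), quantity))
  }
  obj
}

#' PigmentTimeSeries: replicate-resolved pigment kinetics for one leaf series
#'
#' Carotenoid (and optionally chlorophyll b) concentrations in
#' mol (mol Chl a)^-1 for one replicate of one species x light-condition
#' group, sampled on (a subset of) the transient leaf-disk schedule.
#' Missing determinations ("nd") are carried as `NA`, never as zero.
#'
#' @slot species character label.
#' @slot lightCondition `"sun"` or `"shade"`.
#' @slot replicate integer >= 1.
#' @slot times numeric, subset of [pigmentSamplingSchedule].
#' @slot concentrations matrix `[n_pigments x n_times]`, rownames drawn from
#'   [pigmentNamesAccepted], values >= 0 or `NA`.
#'
#' @export
setClass("PigmentTimeSeries",
  representation(
    species = "character",
    lightCondition = "character",
    replicate = "integer",
    times = "numeric",
    concentrations = "matrix"
  )
)

setValidity("PigmentTimeSeries", function(object) {
  msg <- character()
  conc <- object@concentrations
  if (!object@lightCondition %in% c("sun", "shade"))
    msg <- c(msg, "lightCondition must be 'sun' or 'shade'")
  if (length(object@replicate) != 1L || object@replicate < 1L)
    msg <- c(msg, "replicate must be a single integer >= 1")
  bad <- setdiff(rownames(conc), pigmentNamesAccepted)
  if (length(bad))
    msg <- c(msg, paste0("unknown pigment name(s): ",
                         paste(bad, collapse = ", "),
                         "; accepted: ",
                         paste(pigmentNamesAccepted, collapse = ", ")))
  if (any(conc < 0, na.rm = TRUE))
    msg <- c(msg, "concentrations must be >= 0 (missing values are NA)")
  if (!all(object@times %in% pigmentSamplingSchedule))
    msg <- c(msg, paste0("times must lie on the sampling schedule {",
                         paste(pigmentSamplingSchedule, collapse = ","), "}"))
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (ncol(conc) != length(object@times))
    msg <- c(msg, "concentrations must have one column per time point")
  if (length(msg)) msg else TRUE
})

#' Construct a PigmentTimeSeries
#'
#' @param species species label.
#' @param lightCondition `"sun"` or `"shade"`.
#' @param replicate replicate number (>= 1).
#' @param times sampling times, a subset of [pigmentSamplingSchedule].
#' @param concentrations matrix `[n_pigments x n_times]` in
#'   mol (mol Chl a)^-1 with pigment rownames; `NA` marks a missing ("nd")
#'   determination.
#' @return A validated [PigmentTimeSeries-class] object.
#' @examples
#' conc <- matrix(c(0.05, 0.04, 0.00, 0.01), 2, 2,
#'                dimnames = list(c("Vio", "Zea"), NULL))
#' PigmentTimeSeries("M. alba", "sun", 1, c(0, 180), conc)
#' @export
PigmentTimeSeries <- function(species, lightCondition, replicate, times,
                              concentrations) {
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  new("PigmentTimeSeries",
      species = as.character(species),
      lightCondition = as.character(lightCondition),
      replicate = as.integer(replicate),
      times = as.numeric(times),
      concentrations = concentrations)
}
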