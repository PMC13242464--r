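#' Total fluorescence emission from both leaf sides
#'
#' Sums the upwelling and downwelling fluorescence radiance spectra
#' element-wise. The grids must match exactly; no implicit resampling is
#' performed.
#'
#' @param fUp,fDw [SpectralTimeSeries-class] radiance objects on identical
#'   wavelength and time grids.
#' @return A [SpectralTimeSeries-class] with the summed emission.
#' @export
totalFluorescence <- function(fUp, fDw) {
  stopifnot(is(fUp, "SpectralTimeSeries"), is(fDw, "SpectralTimeSeries"))
  if (!isTRUE(all.equal(fUp@wavelengths, fDw@wavelengths)) ||
      !isTRUE(all.equal(fUp@times, fDw@times)))
    stop("up- and downwelling grids differ; no implicit resampling")
  SpectralTimeSeries(fUp@wavelengths, fUp@times, fUp@values + fDw@values,
                     fUp@quantity)
}

#' Spectrally integrated fluorescence photon flux J_F
#'
#' Converts the total fluorescence radiance to photon-flux units and
#' integrates over 655-850 nm by trapezoidal quadrature on the native grid:
#' \deqn{J_F = \int_{655}^{850} 3.14\times 10^{-3}
#'   \frac{10^6}{N_a} \frac{10^{-9}\lambda}{h c} F_{tot}(\lambda)\, d\lambda}
#' with Avogadro's number \eqn{N_a = 6.02\times 10^{23}} mol\eqn{^{-1}},
#' Planck's constant \eqn{h = 6.62\times 10^{-34}} J s and the speed of
#' light \eqn{c = 299792458} m s\eqn{^{-1}}. The 3.14e-3 prefactor carries
#' the Lambertian hemispherical integration (pi sr) and a 1e-3 scaling and
#' is applied literally.
#'
#' @param fTot total-fluorescence [SpectralTimeSeries-class]
#'   (W m^-2 sr^-1 nm^-1).
#' @return Numeric vector of J_F per time point, in umol m^-2 s^-1.
#' @export
fluorescenceFlux <- function(fTot) {
  stopifnot(is(fTot, "SpectralTimeSeries"))
  wl <- fTot@wavelengths
  if (length(wl) < 2L) stop("need >= 2 grid wavelengths to integrate")
  step <- max(diff(wl))
  if (min(wl) > 655 + step || max(wl) < 850 - step)
    warning(sprintf(
      "grid [%g, %g] nm does not cover the 655-850 nm integration window",
      min(wl), max(wl)))
  x <- restrictWavelength(fTot, 655, 850)
  coefs <- .FLUX_PREFACTOR * (1e6 / .AVOGADRO) *
    (1e-9 * x@wavelengths / (.PLANCK * .LIGHT_SPEED))
  unname(apply(x@values * coefs, 2L,
               function(col) pracma::trapz(x@wavelengths, col)))
}

#' Fluorescence quenching, the NPQ-equivalent parameter
#'
#' The decline of the fluorescence flux relative to its current value:
#' \deqn{Fq(t_i) = (J_F(t_0) - J_F(t_i)) / J_F(t_i)}
#' which is algebraically the conventional NPQ form (Fm - Fm')/Fm' with the
#' first acquired sample standing in for the dark Fm.
#'
#' @param jF numeric vector of fluorescence flux values; all must be > 0.
#' @param times optional time stamps, used only for error messages.
#' @return Numeric vector, 0 at the first sample.
#' @export
fQuenching <- function(jF, times = seq_along(jF) - 1) {
  if (any(jF <= 0)) {
    i <- which(jF <= 0)[1L]
    stop(sprintf("non-positive J_F (%g) at time %g", jF[i], times[i]))
  }
  (jF[1L] - jF) / jF
}

#' Normalized total fluorescence decay
#'
#' Rescales the fluorescence flux decline so the first sample maps to 1 and
#' the final sample to 0:
#' \deqn{[J_F]_{norm}(t_i) = 1 - (J_F(t_0) - J_F(t_i)) /
#'   (J_F(t_0) - J_F(t_{end}))}
#'
#' @param jF numeric vector of fluorescence flux values.
#' @return Numeric vector; exactly 1 at the first and 0 at the last sample.
#' @export
normalizedDecay <- function(jF) {
  n <- length(jF)
  if (n < 2L) stop("need >= 2 samples")
  denom <- jF[1L] - jF[n]
  if (denom == 0)
    stop("degenerate normalization: J_F equal at first and last sample")
  1 - (jF[1L] - jF) / denom
}

#' Red to far-red fluorescence peak ratio (F690/F740)
#'
#' Per time point, the maximum of the raw total-fluorescence spectrum over
#' the red window [650, 700] nm divided by the maximum over the far-red
#' window [700, 800] nm (closed intervals; 700 nm belongs to both).
#'
#' @param fTot total-fluorescence [SpectralTimeSeries-class].
#' @return Numeric vector of peak ratios per time point.
#' @export
peakRatio <- function(fTot) {
  stopifnot(is(fTot, "SpectralTimeSeries"))
  red <- restrictWavelength(fTot, 650, 700)
  farred <- restrictWavelength(fTot, 700, 800)
  mr <- unname(apply(red@values, 2L, max))
  mf <- unname(apply(farred@values, 2L, max))
  if (any(mf == 0)) {
    i <- which(mf == 0)[1L]
    stop(sprintf("far-red window identically <= 0 at time %g", fTot@times[i]))
  }
  mr / mf
}

#' All fluorescence transient metrics in one table
#'
#' Convenience wrapper running [totalFluorescence()], [fluorescenceFlux()],
#' [fQuenching()], [normalizedDecay()] and [peakRatio()].
#'
#' @param fUp,fDw up/downwelling radiance [SpectralTimeSeries-class] objects.
#' @return A data.frame with columns `time_s, j_f, f_quenching,
#'   normalized_decay, peak_ratio`.
#' @export
fluorescenceMetrics <- function(fUp, fDw) {
  fTot <- totalFluorescence(fUp, fDw)
  jF <- fluorescenceFlux(fTot)
  data.frame(
    time_s = fTot@times,
    j_f = jF,
    f_quenching = fQuenching(jF, fTot@times),
    normalized_decay = normalizedDecay(jF),
    peak_ratio = peakRatio(fTot)
  )
}
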