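# fixtures built in code: no data files

gauss <- function(wl, m, s) exp(-(wl - m)^2 / (2 * s^2))

# a small spectral series from a matrix
makeSpectral <- function(wl, tt, vals, quantity = "radiance_W_m2_sr_nm") {
  SpectralTimeSeries(wl, tt, vals, quantity)
}

# three-Gaussian delta-absorbance spectrum from given parameters
threeGaussSpectrum <- function(wl, amps, means, sds = c(8.5, 12.5, 5.0)) {
  rowSums(vapply(1:3, function(k) amps[k] * gauss(wl, means[k], sds[k]),
                 numeric(length(wl))))
}

# replicate pigment series on the full schedule from a pigment x time matrix
makePigment <- function(conc, times = pigmentSamplingSchedule,
                        replicate = 1, species = "toy", cond = "sun") {
  PigmentTimeSeries(species, cond, replicate, times, conc)
}

fullPigmentMatrix <- function(times = pigmentSamplingSchedule) {
  pigs <- c("Neo", "Vio", "Ant", "Zea", "betaCar", "alphaCar", "Lut", "Lx")
  m <- matrix(0.05, length(pigs), length(times),
              dimnames = list(pigs, NULL))
  m
}
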