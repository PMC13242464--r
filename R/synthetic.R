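#' Configuration for the synthetic transient generator
#'
#' Bundles every knob of the seeded synthetic dataset emulating a
#' dark-to-high-light transient measurement: biphasic fluorescence decline,
#' a growing 535 nm delta-absorbance component with transient 520/560 nm
#' features, and first-order carotenoid interconversion kinetics with
#' optional de novo influx. Defaults are the package's reference study
#' conditions; see the methods vignette for their rationale.
#'
#' @param seed integer seed driving all randomness.
#' @param timesSpectral spectral acquisition times (s), default 0.35 s
#'   cadence over `[0, 180]`.
#' @param timesPigment leaf-disk sampling schedule, default
#'   [pigmentSamplingSchedule].
#' @param fluor list: emission peak `means` (nm) and `sds` (nm), relative
#'   peak `amps`, radiance `scale` (W m^-2 sr^-1 nm^-1), and the biphasic
#'   amplitude course `floor + wFast exp(-t/tauFast) + wSlow exp(-t/tauSlow)`
#'   (weights sum with floor to 1 at t = 0); `wavelengths` is the fluorescence
#'   grid.
#' @param deltaAbs list: `wavelengths` (absorbance grid), Gaussian component
#'   time courses (`a2Max`/`halfTimeG2` saturating rise for G2; `a1Max`,
#'   `tau1`, `a3Max`, `tau3` rise-then-decay for G1/G3), and `baseline`
#'   parameters of the dark absorbance spectrum.
#' @param pigments list: `dark` named dark-state pools (mol (mol Chl a)^-1),
#'   `rates` named first-order rate constants (s^-1), `influxAlpha`/
#'   `influxBeta` de novo branch influx (mol (mol Chl a)^-1 s^-1),
#'   `nReplicates`, `sigmaLog` lognormal replicate noise, `species`,
#'   `lightCondition`.
#' @param noise list: additive spectral noise sd for fluorescence
#'   (`fluorSd`) and for each of reflectance/transmittance (`rtSd`).
#' @return A list of class `TransientConfig`.
#' @export
transientConfig <- function(
    seed = 1L,
    timesSpectral = seq(0, 180, by = 0.35),
    timesPigment = pigmentSamplingSchedule,
    fluor = list(),
    deltaAbs = list(),
    pigments = list(),
    noise = list()) {
  fluorDef <- list(
    wavelengths = seq(650, 850, by = 1),
    means = c(690, 740), sds = c(10, 22), amps = c(1, 0.8),
    scale = 0.02, floor = 0.35, wFast = 0.40, tauFast = 8,
    wSlow = 0.25, tauSlow = 60)
  deltaAbsDef <- list(
    wavelengths = seq(400, 650, by = 1),
    a2Max = 0.008, halfTimeG2 = 25,
    a1Max = 0.004, tau1 = 10,
    a3Max = -0.002, tau3 = 15,
    specs = defaultGaussianSpecs())
  pigmentsDef <- list(
    dark = c(Neo = 0.045, Vio = 0.055, Ant = 0.004, Zea = 0,
             betaCar = 0.095, alphaCar = 0.030, Lut = 0.140, Lx = 0.012),
    rates = c(kNV = 0.003, kVN = 0, kVA = 0.02, kAV = 0.002,
              kAZ = 0.04, kZA = 0.001, kBV = 0.001,
              kCX = 0.005, kXL = 0.03, kLX = 0.002),
    influxAlpha = 0, influxBeta = 0,
    nReplicates = 3L, sigmaLog = 0.08,
    species = "synthetic", lightCondition = "sun")
  noiseDef <- list(fluorSd = 1e-4, rtSd = 5e-4)
  ## named parameter vectors (dark pools, rate constants) merge entry-wise,
  ## so callers can override a single rate without restating the rest
  mergeVec <- function(def, usr) {
    if (is.null(usr)) return(def)
    def[names(usr)] <- usr
    def
  }
  pigments$dark <- mergeVec(pigmentsDef$dark, pigments$dark)
  pigments$rates <- mergeVec(pigmentsDef$rates, pigments$rates)
  cfg <- list(
    seed = as.integer(seed),
    timesSpectral = timesSpectral,
    timesPigment = timesPigment,
    fluor = utils::modifyList(fluorDef, fluor),
    deltaAbs = utils::modifyList(deltaAbsDef, deltaAbs),
    pigments = utils::modifyList(pigmentsDef, pigments),
    noise = utils::modifyList(noiseDef, noise))
  with(cfg$fluor, {
    if (tauFast >= tauSlow)
      stop("config error: tauFast must be smaller than tauSlow")
    if (floor < 0 || wFast < 0 || wSlow < 0)
      stop("config error: fluorescence amplitude terms must be >= 0")
  })
  if (any(cfg$pigments$rates < 0) || cfg$pigments$influxAlpha < 0 ||
      cfg$pigments$influxBeta < 0)
    stop("config error: rates and influxes must be >= 0")
  if (any(cfg$pigments$dark < 0))
    stop("config error: dark pools must be >= 0")
  class(cfg) <- "TransientConfig"
  cfg
}

## biphasic fluorescence amplitude course, 1 at t = 0 when weights + floor = 1
.fluorAmplitude <- function(t, f) {
  f$floor + f$wFast * exp(-t / f$tauFast) + f$wSlow * exp(-t / f$tauSlow)
}

#' Generate synthetic up/downwelling fluorescence transients
#'
#' A fixed two-Gaussian emission shape (peaks near 690 and 740 nm) scaled by
#' a biphasic declining amplitude, split 50/50 between the upwelling and
#' downwelling channels, with seeded additive Gaussian noise. The noiseless
#' photon flux J_F of the output is strictly decreasing by construction.
#'
#' @param config a [transientConfig()].
#' @return A list `fUp`, `fDw` of radiance [SpectralTimeSeries-class]
#'   objects.
#' @export
generateFluorescence <- function(config) {
  stopifnot(inherits(config, "TransientConfig"))
  f <- config$fluor
  wl <- f$wavelengths
  tt <- config$timesSpectral
  shape <- f$amps[1L] * exp(-(wl - f$means[1L])^2 / (2 * f$sds[1L]^2)) +
    f$amps[2L] * exp(-(wl - f$means[2L])^2 / (2 * f$sds[2L]^2))
  amp <- .fluorAmplitude(tt, f)
  base <- 0.5 * f$scale * outer(shape, amp)
  set.seed(config$seed)
  mkNoise <- function() matrix(stats::rnorm(length(base), 0,
                                            config$noise$fluorSd),
                               nrow(base), ncol(base))
  list(
    fUp = SpectralTimeSeries(wl, tt, base + mkNoise(), "radiance_W_m2_sr_nm"),
    fDw = SpectralTimeSeries(wl, tt, base + mkNoise(), "radiance_W_m2_sr_nm"))
}

## Gaussian component amplitude time courses of the synthetic delta-absorbance
.gaussCourses <- function(t, d) {
  cbind(
    a1 = d$a1Max * (t / d$tau1) * exp(1 - t / d$tau1),   # rise then decay
    a2 = d$a2Max * (1 - 2^(-t / d$halfTimeG2)),          # saturating rise,
    a3 = d$a3Max * (t / d$tau3) * exp(1 - t / d$tau3))   # half level at H
}

#' Generate synthetic reflectance and transmittance transients
#'
#' Builds A(lambda, t) as a smooth dark baseline plus the three Gaussian
#' components with configured time courses (G2: saturating rise reaching
#' half its plateau at `halfTimeG2`; G1/G3: transient rise-then-decay), then
#' partitions the remainder 50/50 into reflectance and transmittance
#' (R = T = (1 - A)/2) so that energy conservation recovers A exactly in
#' the noiseless case. Seeded Gaussian noise is added to R and T.
#'
#' @param config a [transientConfig()].
#' @return A list `reflectance`, `transmittance` of
#'   [SpectralTimeSeries-class] objects, plus `absorbanceTrue` (the
#'   noiseless absorbance) and `courses` (the generating component
#'   amplitudes per time).
#' @export
generateAbsorbance <- function(config) {
  stopifnot(inherits(config, "TransientConfig"))
  d <- config$deltaAbs
  wl <- d$wavelengths
  tt <- config$timesSpectral
  baseline <- 0.88 - 0.25 * exp(-(wl - 550)^2 / (2 * 40^2))
  courses <- .gaussCourses(tt, d)
  G <- .gaussBasis(wl, d$specs$mean_nm, d$specs$sd_nm)
  A <- baseline + G %*% t(courses)
  if (any(A < 0 | A > 1))
    stop("config error: component time courses push absorbance outside [0,1]")
  half <- (1 - A) / 2
  set.seed(config$seed + 1L)
  mkNoise <- function(sd) matrix(stats::rnorm(length(half), 0, sd),
                                 nrow(half), ncol(half))
  list(
    reflectance = SpectralTimeSeries(wl, tt, half + mkNoise(config$noise$rtSd),
                                     "reflectance_frac"),
    transmittance = SpectralTimeSeries(wl, tt,
                                       half + mkNoise(config$noise$rtSd),
                                       "transmittance_frac"),
    absorbanceTrue = SpectralTimeSeries(wl, tt, A, "absorbance_frac"),
    courses = data.frame(time_s = tt, courses))
}

## right-hand side of the first-order interconversion system
.pigmentDeriv <- function(t, y, p) {
  r <- p$rates
  dNeo <- -r[["kNV"]] * y[["Neo"]] + r[["kVN"]] * y[["Vio"]]
  dVio <- r[["kNV"]] * y[["Neo"]] - r[["kVN"]] * y[["Vio"]] -
    r[["kVA"]] * y[["Vio"]] + r[["kAV"]] * y[["Ant"]] +
    r[["kBV"]] * y[["betaCar"]]
  dAnt <- r[["kVA"]] * y[["Vio"]] - r[["kAV"]] * y[["Ant"]] -
    r[["kAZ"]] * y[["Ant"]] + r[["kZA"]] * y[["Zea"]]
  dZea <- r[["kAZ"]] * y[["Ant"]] - r[["kZA"]] * y[["Zea"]]
  dBeta <- p$influxBeta - r[["kBV"]] * y[["betaCar"]]
  dAlpha <- p$influxAlpha - r[["kCX"]] * y[["alphaCar"]]
  dLx <- r[["kCX"]] * y[["alphaCar"]] - r[["kXL"]] * y[["Lx"]] +
    r[["kLX"]] * y[["Lut"]]
  dLut <- r[["kXL"]] * y[["Lx"]] - r[["kLX"]] * y[["Lut"]]
  list(c(Neo = dNeo, Vio = dVio, Ant = dAnt, Zea = dZea, betaCar = dBeta,
         alphaCar = dAlpha, Lut = dLut, Lx = dLx))
}

#' Exact (noiseless) pigment trajectory of the generator
#'
#' Integrates the first-order interconversion system (VAZ chain, Neo-Vio
#' exchange, beta-Car to Vio, alpha-Car to Lx, LxL exchange, optional de
#' novo branch influx) with fixed-step RK4 (dt = 0.05 s) and samples the
#' leaf-disk schedule.
#'
#' @param config a [transientConfig()].
#' @return A matrix `[n_pigments x n_times]` with pigment rownames.
#' @export
pigmentTrajectory <- function(config) {
  p <- config$pigments
  y0 <- p$dark[c("Neo", "Vio", "Ant", "Zea", "betaCar", "alphaCar",
                 "Lut", "Lx")]
  grid <- seq(0, max(config$timesPigment), by = 0.05)
  sol <- deSolve::ode(y = y0, times = grid, func = .pigmentDeriv,
                      parms = p, method = "rk4")
  idx <- match(config$timesPigment, grid)
  if (anyNA(idx))
    stop("pigment sampling times must lie on the 0.05 s integration grid")
  out <- t(sol[idx, -1L, drop = FALSE])
  if (any(out < -1e-10))
    stop("config error: negative pigment state reached")
  out[out < 0] <- 0
  rownames(out) <- names(y0)
  colnames(out) <- NULL
  out
}

#' Generate replicate pigment time series
#'
#' Samples the exact trajectory from [pigmentTrajectory()] at the leaf-disk
#' schedule and applies independent per-replicate, per-pigment, per-time
#' lognormal noise (keeping pools non-negative). With zero de novo influx
#' and no noise, each branch total is constant along the trajectory.
#'
#' @param config a [transientConfig()].
#' @return A list of [PigmentTimeSeries-class] objects, one per replicate.
#' @export
generatePigments <- function(config) {
  stopifnot(inherits(config, "TransientConfig"))
  p <- config$pigments
  traj <- pigmentTrajectory(config)
  set.seed(config$seed + 2L)
  lapply(seq_len(p$nReplicates), function(r) {
    noisy <- traj * exp(matrix(stats::rnorm(length(traj), 0, p$sigmaLog),
                               nrow(traj), ncol(traj)))
    PigmentTimeSeries(p$species, p$lightCondition, r, config$timesPigment,
                      noisy)
  })
}

#' Generate a full synthetic transient dataset
#'
#' Runs all three generators under one seed and optionally writes the CSV
#' files the readers consume.
#'
#' @param config a [transientConfig()].
#' @param outDir optional directory; when given, writes `f_up.csv`,
#'   `f_dw.csv`, `reflectance.csv`, `transmittance.csv` and `pigments.csv`.
#' @return A list `fUp, fDw, reflectance, transmittance, absorbanceTrue,
#'   courses, pigments` (and `files` when written).
#' @export
simulateTransient <- function(config = transientConfig(), outDir = NULL) {
  fl <- generateFluorescence(config)
  ab <- generateAbsorbance(config)
  pg <- generatePigments(config)
  out <- c(fl, ab, list(pigments = pg))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      f_up = writeSpectralCsv(fl$fUp, file.path(outDir, "f_up.csv")),
      f_dw = writeSpectralCsv(fl$fDw, file.path(outDir, "f_dw.csv")),
      reflectance = writeSpectralCsv(ab$reflectance,
                                     file.path(outDir, "reflectance.csv")),
      transmittance = writeSpectralCsv(ab$transmittance,
                                       file.path(outDir,
                                                 "transmittance.csv")),
      pigments = writePigmentTable(pg, file.path(outDir, "pigments.csv")))
    out$files <- files
  }
  out
}

#' Closed-form fluorescence half-time implied by the generator parameters
#'
#' Solves amplitude(t) = (amplitude(0) + amplitude(tEnd))/2 for the biphasic
#' course `floor + wFast exp(-t/tauFast) + wSlow exp(-t/tauSlow)` by
#' root-finding; this is the value the pipeline's [halfTime()] should
#' recover from a noiseless synthetic fluorescence record.
#'
#' @param config a [transientConfig()].
#' @return Scalar half-time in s.
#' @export
impliedFluorescenceHalfTime <- function(config) {
  f <- config$fluor
  tEnd <- max(config$timesSpectral)
  M <- (.fluorAmplitude(0, f) + .fluorAmplitude(tEnd, f)) / 2
  stats::uniroot(function(t) .fluorAmplitude(t, f) - M,
                 lower = 0, upper = tEnd, tol = 1e-10)$root
}
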