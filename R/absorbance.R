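#' Leaf absorbance from reflectance and transmittance
#'
#' Energy conservation: Absorbance(lambda) = 1 - Transmittance(lambda) -
#' Reflectance(lambda), element-wise on identical grids.
#'
#' @param reflectance,transmittance [SpectralTimeSeries-class] objects on
#'   identical wavelength and time grids.
#' @return An `absorbance_frac` [SpectralTimeSeries-class].
#' @export
absorbanceFromRT <- function(reflectance, transmittance) {
  stopifnot(is(reflectance, "SpectralTimeSeries"),
            is(transmittance, "SpectralTimeSeries"))
  if (!isTRUE(all.equal(reflectance@wavelengths, transmittance@wavelengths)) ||
      !isTRUE(all.equal(reflectance@times, transmittance@times)))
    stop("reflectance and transmittance grids differ")
  SpectralTimeSeries(reflectance@wavelengths, reflectance@times,
                     1 - transmittance@values - reflectance@values,
                     "absorbance_frac")
}

#' Delta-absorbance relative to the dark-adapted spectrum
#'
#' Subtracts the first (dark, t0) column from every time point:
#' dA(lambda, t) = A(lambda, t) - A(lambda, t0). The first column of the
#' result is identically zero.
#'
#' @param a an absorbance [SpectralTimeSeries-class] with >= 2 time points.
#' @return A `delta_absorbance` [SpectralTimeSeries-class].
#' @export
deltaAbsorbance <- function(a) {
  stopifnot(is(a, "SpectralTimeSeries"))
  if (length(a@times) < 2L) stop("need >= 2 time points for delta-absorbance")
  SpectralTimeSeries(a@wavelengths, a@times, a@values - a@values[, 1L],
                     "delta_absorbance")
}

#' Savitzky-Golay smoothing of one spectrum
#'
#' Display/diagnostic smoothing of noisy spectra. Fitting always runs on the
#' raw data; this filter is never applied before [fitGaussians()].
#'
#' @param spectrum numeric vector.
#' @param windowPts odd window length in points (default 15); `1` is the
#'   identity.
#' @param polyorder polynomial order (default 3), must be < `windowPts`.
#' @return Smoothed vector of the same length.
#' @export
sgSmooth <- function(spectrum, windowPts = 15, polyorder = 3) {
  if (windowPts == 1) return(spectrum)
  if (windowPts %% 2 != 1) stop("window length must be odd")
  if (windowPts <= polyorder) stop("window length must exceed polyorder")
  if (windowPts > length(spectrum))
    stop("window longer than the spectrum")
  as.numeric(signal::sgolayfilt(spectrum, p = polyorder, n = windowPts))
}

#' Constrained Gaussian component specifications
#'
#' The three-component model of the 450-650 nm delta-absorbance spectra:
#' G1 (520 nm, sd 8.5 nm), G2 (535 nm, sd 12.5 nm), G3 (560 nm, sd 5 nm).
#' Standard deviations are fixed; fitted means may move at most
#' `meanBound` (2 nm) from nominal; amplitudes are free in sign.
#'
#' @param means nominal means (nm).
#' @param sds fixed standard deviations (nm).
#' @param meanBound allowed |fitted - nominal| (nm).
#' @return A data.frame with columns `mean_nm, sd_nm, mean_bound_nm`.
#' @export
defaultGaussianSpecs <- function(means = c(520, 535, 560),
                                 sds = c(8.5, 12.5, 5.0),
                                 meanBound = 2.0) {
  stopifnot(length(means) == length(sds), all(sds > 0), all(meanBound >= 0))
  data.frame(mean_nm = means, sd_nm = sds,
             mean_bound_nm = rep(meanBound, length.out = length(means)))
}

.gaussBasis <- function(wl, means, sds) {
  vapply(seq_along(means),
         function(k) exp(-(wl - means[k])^2 / (2 * sds[k]^2)),
         numeric(length(wl)))
}

## Variable projection: amplitudes are linear given the means, so solve them
## by least squares at each candidate mean vector and optimize only over the
## (box-bounded) means.
.varproAmps <- function(wl, y, means, sds) {
  G <- .gaussBasis(wl, means, sds)
  qr.coef(qr(G), y)
}

.varproSSR <- function(m, wl, y, sds) {
  G <- .gaussBasis(wl, m, sds)
  a <- qr.coef(qr(G), y)
  sum((y - G %*% a)^2)
}

#' Normalized root-mean-square error of a fit
#'
#' RMSE of the residuals divided by the range (max - min) of the observed
#' values.
#'
#' @param observed,fitted numeric vectors of equal length; `observed` must
#'   not be constant.
#' @return Scalar NRMSE (>= 0).
#' @export
nrmse <- function(observed, fitted) {
  if (length(observed) != length(fitted)) stop("length mismatch")
  rng <- max(observed) - min(observed)
  if (rng == 0) stop("observed vector is constant; NRMSE undefined")
  sqrt(mean((observed - fitted)^2)) / rng
}

#' Relative Gaussian amplitude weights
#'
#' Per-time normalization of the fitted amplitudes so the three relative
#' weights sum to 1: w_k = |a_k| / sum_j |a_j|. Amplitudes may be negative
#' (bleaching features), hence the absolute-value convention. All-zero
#' amplitudes leave the weights undefined (`NA`).
#'
#' @param amplitudes numeric vector of signed amplitudes.
#' @return Numeric vector of weights summing to 1, or all-`NA` if every
#'   amplitude is zero.
#' @export
relativeWeights <- function(amplitudes) {
  tot <- sum(abs(amplitudes))
  if (tot == 0) return(rep(NA_real_, length(amplitudes)))
  abs(amplitudes) / tot
}

#' Fit the constrained three-Gaussian model to one delta-absorbance spectrum
#'
#' Least-squares fit of \eqn{\Delta A(\lambda) \approx \sum_k a_k
#' \exp(-(\lambda-m_k)^2/(2 s_k^2))} over the 450-650 nm window with fixed
#' standard deviations, means box-bounded to nominal +/- 2 nm and signed
#' free amplitudes. No baseline/offset term is included: broader overlapping
#' broadening effects are deliberately left unfitted.
#'
#' The optimizer uses variable projection (amplitudes solved linearly at
#' each candidate mean vector) with multi-start L-BFGS-B over nominal means
#' + \{-2, 0, +2\} nm, followed by coordinate-wise polish, so the mildly
#' multimodal 3-mean landscape is handled robustly. Non-convergence is
#' flagged (`converged = FALSE`, `nrmse = Inf`), never thrown.
#'
#' @param wavelengths wavelength grid (nm) covering the fit window.
#' @param spectrum delta-absorbance values on the grid.
#' @param specs Gaussian specification from [defaultGaussianSpecs()].
#' @param window fit window (nm), default `c(450, 650)`.
#' @param multiStart logical; `FALSE` restricts the search to starts at the
#'   nominal means plus any `warmStart` (used for warm-started series fits).
#' @param warmStart optional mean vector used as an extra start.
#' @return A list of class `GaussianFit` with elements `amplitudes`, `means`,
#'   `sds`, `weights`, `nrmse`, `ssr`, `converged`.
#' @examples
#' wl <- seq(450, 650, by = 1)
#' y <- 0.01 * exp(-(wl - 535)^2 / (2 * 12.5^2))
#' fit <- fitGaussians(wl, y)
#' fit$amplitudes
#' @export
fitGaussians <- function(wavelengths, spectrum, specs = defaultGaussianSpecs(),
                         window = c(450, 650), multiStart = TRUE,
                         warmStart = NULL) {
  keep <- wavelengths >= window[1L] & wavelengths <= window[2L]
  wl <- wavelengths[keep]
  y <- spectrum[keep]
  if (length(wl) < nrow(specs) + 1L)
    stop("fit window contains too few grid points")
  m0 <- specs$mean_nm
  sds <- specs$sd_nm
  lower <- m0 - specs$mean_bound_nm
  upper <- m0 + specs$mean_bound_nm

  starts <- list(m0)
  if (multiStart) {
    offs <- expand.grid(rep(list(c(-2, 0, 2)), nrow(specs)))
    starts <- lapply(seq_len(nrow(offs)), function(i) {
      pmin(pmax(m0 + as.numeric(offs[i, ]), lower), upper)
    })
  }
  if (!is.null(warmStart))
    starts <- c(list(pmin(pmax(warmStart, lower), upper)), starts)

  best <- NULL
  ok <- FALSE
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, .varproSSR, wl = wl, y = y, sds = sds,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!ok) {
    k <- nrow(specs)
    return(structure(list(amplitudes = rep(NA_real_, k), means = m0,
                          sds = sds, weights = rep(NA_real_, k),
                          nrmse = Inf, ssr = Inf, converged = FALSE),
                     class = "GaussianFit"))
  }

  ## coordinate-wise polish: tighten each mean by 1-D golden-section search,
  ## amplitudes re-solved at every evaluation
  m <- best$par
  for (sweep in 1:20) {
    m_prev <- m
    for (k in seq_along(m)) {
      f1 <- function(mk) {
        mm <- m; mm[k] <- mk
        .varproSSR(mm, wl, y, sds)
      }
      m[k] <- stats::optimize(f1, lower = lower[k], upper = upper[k],
                              tol = 1e-8)$minimum
    }
    if (max(abs(m - m_prev)) < 1e-7) break
  }
  if (.varproSSR(m, wl, y, sds) > best$value) m <- best$par

  a <- as.numeric(.varproAmps(wl, y, m, sds))
  a[abs(a) < 1e-14] <- 0
  fitted <- .gaussBasis(wl, m, sds) %*% a
  ssr <- sum((y - fitted)^2)
  nr <- if (max(y) == min(y)) 0 else sqrt(mean((y - fitted)^2)) /
    (max(y) - min(y))
  structure(list(amplitudes = a, means = m, sds = sds,
                 weights = relativeWeights(a), nrmse = nr, ssr = ssr,
                 converged = TRUE),
            class = "GaussianFit")
}

#' @export
print.GaussianFit <- function(x, ...) {
  cat("Constrained Gaussian fit (", length(x$means), " components)\n",
      sep = "")
  df <- data.frame(mean_nm = x$means, sd_nm = x$sds,
                   amplitude = x$amplitudes, weight = x$weights)
  print(df, row.names = paste0("G", seq_along(x$means)))
  cat(sprintf("NRMSE: %.4g, converged: %s\n", x$nrmse, x$converged))
  invisible(x)
}

#' Fit the three-Gaussian model to every time point of a transient
#'
#' Applies [fitGaussians()] independently per time point (no temporal
#' regularization), warm-starting each fit at the previous time point's
#' means alongside the nominal multi-start grid.
#'
#' @param deltaAbs a `delta_absorbance` [SpectralTimeSeries-class].
#' @param specs Gaussian specification from [defaultGaussianSpecs()].
#' @param window fit window (nm).
#' @param times optional subset of time points to fit (values matched to the
#'   nearest grid times); default all.
#' @return A data.frame with one row per fitted time point: `time_s`,
#'   `a1..a3`, `m1..m3`, `w1..w3`, `nrmse`, `converged`.
#' @export
fitGaussianSeries <- function(deltaAbs, specs = defaultGaussianSpecs(),
                              window = c(450, 650), times = NULL) {
  stopifnot(is(deltaAbs, "SpectralTimeSeries"))
  idx <- seq_along(deltaAbs@times)
  if (!is.null(times))
    idx <- unique(vapply(times, function(t)
      which.min(abs(deltaAbs@times - t)), integer(1L)))
  warm <- NULL
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    fit <- fitGaussians(deltaAbs@wavelengths, deltaAbs@values[, idx[j]],
                        specs = specs, window = window,
                        multiStart = is.null(warm), warmStart = warm)
    if (fit$converged) warm <- fit$means
    out[[j]] <- data.frame(
      time_s = deltaAbs@times[idx[j]],
      t(stats::setNames(fit$amplitudes, paste0("a", seq_len(nrow(specs))))),
      t(stats::setNames(fit$means, paste0("m", seq_len(nrow(specs))))),
      t(stats::setNames(fit$weights, paste0("w", seq_len(nrow(specs))))),
      nrmse = fit$nrmse, converged = fit$converged)
  }
  do.call(rbind, out)
}

#' Spectrally integrated delta-absorbance (500-600 nm)
#'
#' Trapezoidal integral of the delta-absorbance over the 500-600 nm window,
#' per time point.
#'
#' @param deltaAbs a `delta_absorbance` [SpectralTimeSeries-class] whose grid
#'   covers the window.
#' @param window integration window (nm), default `c(500, 600)`.
#' @return Numeric vector (nm-weighted absorbance units) per time point.
#' @export
integratedDeltaAbs <- function(deltaAbs, window = c(500, 600)) {
  stopifnot(is(deltaAbs, "SpectralTimeSeries"))
  wl <- deltaAbs@wavelengths
  step <- max(diff(wl))
  if (min(wl) > window[1L] + step || max(wl) < window[2L] - step)
    stop(sprintf("grid [%g, %g] nm does not cover [%g, %g] nm",
                 min(wl), max(wl), window[1L], window[2L]))
  x <- restrictWavelength(deltaAbs, window[1L], window[2L])
  unname(apply(x@values, 2L,
               function(col) pracma::trapz(x@wavelengths, col)))
}

#' Track absorbance at key wavelengths
#'
#' Per requested wavelength, returns the time series at the nearest grid
#' wavelength (ties broken toward the lower wavelength).
#'
#' @param x a [SpectralTimeSeries-class].
#' @param lambdas wavelengths to track (nm), default `c(520, 535, 560)`.
#' @return A data.frame `time_s` plus one column `A<lambda>` per tracked
#'   wavelength.
#' @export
trackWavelengths <- function(x, lambdas = c(520, 535, 560)) {
  stopifnot(is(x, "SpectralTimeSeries"))
  wl <- x@wavelengths
  cols <- lapply(lambdas, function(l) {
    if (l < min(wl) || l > max(wl))
      stop(sprintf("wavelength %g nm outside grid span [%g, %g]",
                   l, min(wl), max(wl)))
    d <- abs(wl - l)
    i <- which(d == min(d))[1L]  # which() is ordered: ties pick the lower
    unname(x@values[i, ])
  })
  out <- data.frame(time_s = x@times, do.call(cbind, cols))
  names(out)[-1L] <- paste0("A", format(lambdas, trim = TRUE))
  out
}
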