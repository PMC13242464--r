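wlA <- seq(450, 650, by = 1)

test_that("absorbance follows energy conservation 1 - T - R", {
  wl <- c(500, 510)
  R <- makeSpectral(wl, 0, cbind(c(0.05, 0)), "reflectance_frac")
  T_ <- makeSpectral(wl, 0, cbind(c(0.05, 0)), "transmittance_frac")
  expect_equal(absorbanceFromRT(R, T_)@values[, 1], c(0.90, 1))
  R2 <- makeSpectral(wl, 0, cbind(c(0.5, 0.5)), "reflectance_frac")
  T2 <- makeSpectral(wl, 0, cbind(c(0.5, 0.5)), "transmittance_frac")
  expect_equal(absorbanceFromRT(R2, T2)@values[, 1], c(0, 0))
  Rbad <- makeSpectral(wl + 1, 0, cbind(c(0.1, 0.1)), "reflectance_frac")
  expect_error(absorbanceFromRT(Rbad, T_), "grids differ")
})

test_that("delta-absorbance subtracts the dark spectrum exactly", {
  g <- 0.01 * gauss(wlA, 535, 12.5)
  tt <- c(0, 5, 10)
  A <- makeSpectral(wlA, tt, outer(rep(0.8, length(wlA)), rep(1, 3)) +
                      outer(g, tt), "absorbance_frac")
  dA <- deltaAbsorbance(A)
  expect_equal(dA@values, outer(g, tt), tolerance = 1e-14)
  expect_true(all(dA@values[, 1] == 0))
  Aconst <- makeSpectral(wlA, tt, matrix(0.8, length(wlA), 3),
                         "absorbance_frac")
  expect_true(all(deltaAbsorbance(Aconst)@values == 0))
  expect_error(deltaAbsorbance(makeSpectral(wlA, 0, cbind(g),
                                            "absorbance_frac")),
               ">= 2 time points")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and damps noise", {
  y <- 2 + 0.3 * wlA - 0.001 * wlA^2
  sm <- sgSmooth(y, 15, 3)
  interior <- 8:(length(y) - 7)
  expect_equal(sm[interior], y[interior], tolerance = 1e-8)
  set.seed(3)
  noise <- rnorm(201)
  expect_lt(var(sgSmooth(noise, 15, 3)), var(noise))
  expect_identical(sgSmooth(noise, 1), noise)
  expect_error(sgSmooth(noise, 14, 3), "odd")
  expect_error(sgSmooth(noise, 3, 5), "exceed")
  expect_error(sgSmooth(noise[1:5], 15, 3), "longer than")
})

test_that("an all-zero spectrum fits to zero amplitudes", {
  fit <- fitGaussians(wlA, rep(0, length(wlA)))
  expect_equal(fit$amplitudes, c(0, 0, 0), tolerance = 1e-10)
  expect_true(all(is.na(fit$weights)))
})

test_that("a single-component spectrum is recovered to fine precision", {
  y <- 0.01 * gauss(wlA, 535, 12.5)
  fit <- fitGaussians(wlA, y)
  expect_equal(fit$amplitudes[2], 0.01, tolerance = 1e-6)
  expect_equal(fit$means[2], 535, tolerance = 1e-3)
  expect_lt(max(abs(fit$amplitudes[c(1, 3)])), 1e-6)
})

test_that("a noiseless three-component spectrum is recovered, matching a grid-search oracle", {
  amps <- c(0.004, 0.008, -0.002)
  means <- c(519, 536, 561)
  y <- threeGaussSpectrum(wlA, amps, means)
  fit <- fitGaussians(wlA, y)
  expect_equal(fit$amplitudes, amps, tolerance = 1e-4)
  expect_equal(fit$means, means, tolerance = 1e-4)

  # independent coarse grid-search oracle over the bounded means with
  # linear least squares for the amplitudes
  sds <- c(8.5, 12.5, 5.0)
  grid <- expand.grid(m1 = seq(518, 522, 0.5), m2 = seq(533, 537, 0.5),
                      m3 = seq(558, 562, 0.5))
  ssr <- apply(grid, 1, function(m) {
    G <- cbind(gauss(wlA, m[1], sds[1]), gauss(wlA, m[2], sds[2]),
               gauss(wlA, m[3], sds[3]))
    sum(lsfit(G, y, intercept = FALSE)$residuals^2)
  })
  bestGrid <- as.numeric(grid[which.min(ssr), ])
  expect_equal(bestGrid, means, tolerance = 0.5)
  expect_lte(fit$ssr, min(ssr) + 1e-15)
})

test_that("fitted means always honour the +/- 2 nm bounds and weights sum to 1", {
  set.seed(4)
  specs <- defaultGaussianSpecs()
  for (i in 1:10) {
    y <- threeGaussSpectrum(wlA, runif(3, -0.01, 0.01),
                            specs$mean_nm + runif(3, -2, 2)) +
      rnorm(length(wlA), 0, 5e-4)
    fit <- fitGaussians(wlA, y)
    expect_true(all(abs(fit$means - specs$mean_nm) <= 2 + 1e-9))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
    expect_true(all(fit$weights >= 0))
    # residual never exceeds the zero model
    expect_lte(fit$nrmse, nrmse(y, rep(0, length(y))))
  }
})

test_that("dominant-component amplitude recovery stays within 10% under 10% noise", {
  set.seed(5)
  amps <- c(0.003, 0.009, -0.002)
  means <- c(520, 535, 560)
  est <- replicate(40, {
    y <- threeGaussSpectrum(wlA, amps, means)
    y <- y + rnorm(length(wlA), 0, 0.1 * max(abs(y)))
    fitGaussians(wlA, y)$amplitudes[2]
  })
  expect_lt(abs(mean(est) - amps[2]) / abs(amps[2]), 0.10)
})

test_that("relative weights use the absolute-amplitude convention", {
  expect_equal(relativeWeights(c(0.5, 1, 0.5)), c(0.25, 0.5, 0.25))
  expect_equal(relativeWeights(c(0, 0.01, 0)), c(0, 1, 0))
  expect_equal(relativeWeights(c(-0.5, 1, 0.5)), c(0.25, 0.5, 0.25))
  expect_true(all(is.na(relativeWeights(c(0, 0, 0)))))
})

test_that("NRMSE is the range-normalized RMSE", {
  obs <- c(0, 0.5, 1, 0.2)
  expect_equal(nrmse(obs, obs), 0)
  expect_equal(nrmse(obs, obs + 0.03 * 1), 0.03)  # range of obs is 1
  expect_error(nrmse(rep(1, 4), rep(1, 4)), "constant")
  expect_error(nrmse(1:3, 1:4), "length")
})

test_that("integrated delta-absorbance matches constant and dense-grid oracles", {
  tt <- c(0, 1)
  const <- makeSpectral(wlA, tt, matrix(0.01, length(wlA), 2),
                        "delta_absorbance")
  expect_equal(integratedDeltaAbs(const), c(1, 1), tolerance = 1e-12)
  zero <- makeSpectral(wlA, tt, matrix(0, length(wlA), 2),
                       "delta_absorbance")
  expect_equal(integratedDeltaAbs(zero), c(0, 0))

  g <- 0.01 * gauss(wlA, 535, 12.5)
  x <- makeSpectral(wlA, 0, cbind(g), "delta_absorbance")
  wlDense <- seq(500, 600, by = 0.01)
  oracle <- pracma::trapz(wlDense, 0.01 * gauss(wlDense, 535, 12.5))
  expect_equal(integratedDeltaAbs(x), oracle, tolerance = 0.005 * oracle)

  narrow <- makeSpectral(seq(520, 580, 1), 0, cbind(rep(1, 61)),
                         "delta_absorbance")
  expect_error(integratedDeltaAbs(narrow), "cover")
})

test_that("wavelength tracking picks the nearest grid row, ties to the lower", {
  x <- makeSpectral(wlA, c(0, 1), matrix(seq_len(2 * length(wlA)),
                                         length(wlA), 2),
                    "delta_absorbance")
  tr <- trackWavelengths(x, 535)
  expect_equal(tr$A535, x@values[which(wlA == 535), ])
  y <- makeSpectral(c(534.2, 535.8), 0, cbind(c(10, 20)),
                    "delta_absorbance")
  expect_equal(trackWavelengths(y, 535)$A535, 10)  # tie -> lower wavelength
  expect_error(trackWavelengths(x, 900), "outside")
})
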