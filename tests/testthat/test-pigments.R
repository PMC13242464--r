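test_that("dynamic pool percentage follows (max - min)/max * 100", {
  expect_equal(dynamicPoolPercent(c(0, 0.02, 0.05)), 100)  # absent in dark
  expect_equal(dynamicPoolPercent(rep(0.3, 5)), 0)
  expect_equal(dynamicPoolPercent(c(0.05, 0.1, 0.20)), 75)
  expect_true(is.na(dynamicPoolPercent(c(NA, NA))))
  expect_true(is.na(dynamicPoolPercent(c(0, 0, 0))))
  # missing values are skipped, not imputed
  expect_equal(dynamicPoolPercent(c(0.1, NA, 0.2)), 50)
})

test_that("dynamic pool lies in [0, 100], hits 100 iff min is 0 and 0 iff constant", {
  set.seed(8)
  for (i in 1:200) {
    v <- abs(rnorm(10))
    p <- dynamicPoolPercent(v)
    expect_gte(p, 0); expect_lte(p, 100)
    expect_identical(p == 100, min(v) == 0)
    expect_identical(p == 0, max(v) == min(v))
  }
})

test_that("dynamic pool and normalized trend match naive reimplementations", {
  naivePool <- function(v) {
    v <- v[!is.na(v)]
    (max(v) - min(v)) / max(v) * 100
  }
  naiveTrend <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      out[i] <- (v[i] - v[1]) /
        (max(v, na.rm = TRUE) - min(v, na.rm = TRUE))
    }
    out
  }
  set.seed(9)
  for (i in 1:1000) {
    v <- abs(rnorm(15))
    expect_equal(dynamicPoolPercent(v), naivePool(v), tolerance = 1e-12)
    expect_equal(normalizedTrend(v), naiveTrend(v), tolerance = 1e-12)
  }
})

test_that("normalized trend is 0 at t0, +1 at max when t0 is min, -1 symmetric", {
  v <- c(0.1, 0.15, 0.3)  # t0 is the minimum
  tr <- normalizedTrend(v)
  expect_equal(tr[1], 0)
  expect_equal(tr[3], 1)
  v2 <- c(0.3, 0.15, 0.1)  # t0 is the maximum
  expect_equal(normalizedTrend(v2)[3], -1)
  expect_true(all(is.na(normalizedTrend(rep(1, 4)))))
})

test_that("normalized trend spans exactly one unit for non-constant series", {
  set.seed(10)
  for (i in 1:100) {
    v <- abs(rnorm(15))
    tr <- normalizedTrend(v)
    expect_equal(max(tr) - min(tr), 1, tolerance = 1e-12)
  }
})

test_that("branch sums add the documented pool members and propagate NA", {
  conc <- fullPigmentMatrix(times = c(0, 1, 2))[, 1:3]
  conc["alphaCar", ] <- 0.02; conc["Lut", ] <- 0.10; conc["Lx", ] <- 0.01
  conc["Lx", 2] <- NA
  p <- makePigment(conc, times = c(0, 1, 2))
  bs <- branchSums(p)
  expect_equal(bs$alpha_branch[1], 0.13)
  expect_equal(bs$vaz_cycle[1], 0.15)            # three 0.05 entries
  expect_equal(bs$beta_branch[1], 0.05 * 4 + 0.05)
  expect_true(is.na(bs$alpha_branch[2]))         # Lx missing at t = 1
  expect_true(is.na(bs$lxl_cycle[2]))
  expect_false(is.na(bs$vaz_cycle[2]))

  zero <- fullPigmentMatrix(times = c(0, 1, 2))[, 1:3] * 0
  expect_true(all(branchSums(makePigment(zero, times = c(0, 1, 2)))[, -1] == 0))

  noLx <- conc[rownames(conc) != "Lx", ]
  expect_error(branchSums(makePigment(noLx, times = c(0, 1, 2))), "Lx")
})

test_that("de novo t-test matches the textbook equal-variance formula", {
  dark <- c(1, 1, 1); light <- c(2, 2.1, 1.9)
  res <- deNovoTest(cbind(dark, light), c(0, 180))
  # textbook oracle computed independently
  sp2 <- (2 * var(dark) + 2 * var(light)) / 4
  tOracle <- (mean(light) - mean(dark)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  pOracle <- 2 * pt(-abs(tOracle), df = 4)
  expect_equal(res$t, tOracle, tolerance = 1e-12)
  expect_equal(res$p_value, pOracle, tolerance = 1e-12)
  expect_identical(res$verdict, "increase")
  expect_lt(res$p_value, 0.01)
  expect_identical(res$stars, "***")  # p = 6.5e-05 is below the 0.001 tier
})

test_that("de novo verdicts degrade gracefully", {
  same <- matrix(c(1, 1.2, 0.9, 1, 1.2, 0.9), 3, 2)
  res <- deNovoTest(same, c(0, 180))
  expect_identical(res$verdict, "ns")
  expect_equal(res$t, 0, tolerance = 1e-12)
  one <- matrix(c(1, 2), 1, 2)
  expect_true(is.na(deNovoTest(one, c(0, 180))$verdict))
  expect_error(deNovoTest(same, c(5, 180)), "dark state")
})

test_that("significance matrix covers pigments and pools with star coding", {
  set.seed(11)
  reps <- lapply(1:3, function(r) {
    conc <- fullPigmentMatrix()
    conc["Zea", ] <- seq(0, 0.07, length.out = 15) * exp(rnorm(15, 0, 0.02))
    conc <- conc * exp(matrix(rnorm(length(conc), 0, 0.02), nrow(conc)))
    makePigment(conc[rownames(conc) != "Chlb", ], replicate = r)
  })
  sig <- deNovoMatrix(reps)
  expect_setequal(unique(sig$pool),
                  c("Neo", "Vio", "Ant", "Zea", "betaCar", "alphaCar",
                    "Lut", "Lx", "alpha_branch", "beta_branch",
                    "vaz_cycle", "lxl_cycle"))
  zea180 <- sig[sig$pool == "Zea" & sig$time_s == 180, ]
  expect_identical(zea180$verdict, "increase")
  expect_true(zea180$stars %in% c("*", "**", "***"))
  expect_true(all(sig$time_s > 0))
})

test_that("mirror trends are detected through anti-correlated delta-series", {
  tt <- pigmentSamplingSchedule
  a <- 0.05 + 0.01 * sin(tt / 20)
  b <- 0.2 - a
  mt <- mirrorTrend(tt, a, b)
  expect_equal(mt$r, -1, tolerance = 1e-12)
  expect_equal(mirrorTrend(tt, a, a)$r, 1, tolerance = 1e-12)
  expect_true(all(mt$times <= 100))
  set.seed(12)
  rUncor <- mirrorTrend(tt, rnorm(15), rnorm(15))$r
  expect_lt(abs(rUncor), 0.9)
  expect_error(mirrorTrend(c(0, 1, 150, 160), 1:4, 1:4, tMax = 1), "fewer")
})
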