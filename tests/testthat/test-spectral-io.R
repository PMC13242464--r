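test_that("spectral CSV write/read round trip preserves the object", {
  wl <- c(500.25, 510.5, 520.75)
  tt <- c(0, 0.35)
  vals <- matrix(c(0.123456789012345, 1e-6, 0.5, 0.9, 1.5, 2.5), 3, 2)
  x <- makeSpectral(wl, tt, vals)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectralCsv(x, path)
  y <- readSpectralCsv(path, "radiance_W_m2_sr_nm")
  expect_equal(dim(y), c(3L, 2L))
  expect_equal(wavelengths(y), wl)
  expect_equal(timePoints(y), tt)
  expect_equal(y@values, vals, tolerance = 1e-12)
})

test_that("reader sorts shuffled time columns and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,2,0,1",
               "500,a2,a0,a1",
               "510,b2,b0,b1"), path)
  # numeric payload version
  writeLines(c("wavelength_nm,2,0,1",
               "500,12,10,11",
               "510,22,20,21"), path)
  x <- readSpectralCsv(path, "radiance_W_m2_sr_nm")
  expect_equal(timePoints(x), c(0, 1, 2))
  expect_equal(x@values[1, ], c(10, 11, 12))

  writeLines(c("wavelength_nm,0,1", "500,1,2", "500,3,4"), path)
  expect_error(readSpectralCsv(path, "radiance_W_m2_sr_nm"), "duplicated")

  writeLines(c("wavelength_nm,t0,1", "500,1,2"), path)
  expect_error(readSpectralCsv(path, "radiance_W_m2_sr_nm"), "non-numeric")
})

test_that("container invariants are enforced", {
  expect_error(makeSpectral(c(510, 500), c(0, 1), matrix(0, 2, 2)),
               "strictly increasing")
  expect_error(makeSpectral(c(500, 510), c(1, 0), matrix(0, 2, 2)),
               "strictly increasing")
  expect_error(makeSpectral(c(500, 510), c(0, 1), matrix(Inf, 2, 2)),
               "finite")
  expect_error(makeSpectral(c(500, 510), c(0, 1), matrix(0, 2, 2), "bogus"),
               "quantity")
  expect_warning(makeSpectral(c(500, 510), c(0, 1), matrix(1.2, 2, 2),
                              "reflectance_frac"),
                 "outside")
})

test_that("wavelength restriction uses a closed interval", {
  x <- makeSpectral(c(650, 655, 660), c(0, 1), matrix(1:6, 3, 2))
  r <- restrictWavelength(x, 655, 850)
  expect_equal(wavelengths(r), c(655, 660))
  expect_equal(restrictWavelength(x, 650, 660)@values, x@values)
  expect_error(restrictWavelength(x, 700, 600), "inverted")
  expect_error(restrictWavelength(x, 900, 950), "no grid wavelengths")
})

test_that("pigment table round trip keeps nd entries missing, not zero", {
  conc <- matrix(c(0.05, NA, 0.04, 0.01), 2, 2,
                 dimnames = list(c("Vio", "Lx"), NULL))
  p <- makePigment(conc, times = c(0, 180))
  path <- withr::local_tempfile(fileext = ".csv")
  writePigmentTable(list(p), path)
  expect_true(any(grepl(",nd,", readLines(path))))
  q <- readPigmentTable(path)[[1]]
  expect_true(is.na(concentrations(q)["Lx", 1]))
  expect_equal(concentrations(q)[rownames(conc), ], conc,
               ignore_attr = TRUE)
  expect_equal(timePoints(q), c(0, 180))
})

test_that("mass-per-area tables convert through molar masses", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species,light_condition,replicate,time_s,pigment,value,units",
    "sp,sun,1,0,Zea,2.5,mass_per_area",
    "sp,sun,1,0,Chla,100,mass_per_area"), path)
  p <- readPigmentTable(path)[[1]]
  # hand arithmetic: (2.5/568.9)/(100/893.5)
  expect_equal(unname(concentrations(p)["Zea", 1]),
               (2.5 / 568.9) / (100 / 893.5), tolerance = 1e-12)
})

test_that("mass->mole->mass conversion is involutive", {
  massZea <- 3.7; massChla <- 120
  mole <- (massZea / pigmentMolarMasses[["Zea"]]) /
    (massChla / pigmentMolarMasses[["Chla"]])
  back <- mole * (massChla / pigmentMolarMasses[["Chla"]]) *
    pigmentMolarMasses[["Zea"]]
  expect_equal(back, massZea, tolerance = 1e-9)
})

test_that("pigment table errors name the offending field", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species,light_condition,replicate,time_s,pigment,value,units",
    "sp,sun,1,0,Xanthofoo,1,mol_per_mol_chla"), path)
  expect_error(readPigmentTable(path), "Xanthofoo.*accepted")
  writeLines(c(
    "species,light_condition,replicate,time_s,pigment,value,units",
    "sp,sun,1,0,Zea,-1,mol_per_mol_chla"), path)
  expect_error(readPigmentTable(path), "negative")
  writeLines(c("species,pigment,value", "sp,Zea,1"), path)
  expect_error(readPigmentTable(path), "missing column")
})
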