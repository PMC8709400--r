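test_that("CSV reading round-trips values and applies the percent flag", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("petal_id,wavelength_nm,reflectance",
               "p1,400,0.1", "p1,500,0.2", "p1,600,0.3"), f)
  set <- read_spectra_csv(f)
  expect_s3_class(set, "spectrum_set")
  expect_length(set, 1L)
  expect_equal(set$spectra[[1]]$wavelengths_nm, c(400, 500, 600))
  expect_equal(set$spectra[[1]]$reflectance, c(0.1, 0.2, 0.3))

  set_pct <- read_spectra_csv(f, percent = TRUE)
  expect_equal(set_pct$spectra[[1]]$reflectance, c(0.001, 0.002, 0.003))
})

test_that("non-monotone wavelengths are rejected with a located error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("petal_id,wavelength_nm,reflectance",
               "p1,500,0.1", "p1,400,0.2", "p1,600,0.3"), f)
  expect_error(read_spectra_csv(f), "strictly increasing.*sample 2")
})

test_that("metadata sidecar is joined and missing petals are flagged", {
  f <- withr::local_tempfile(fileext = ".csv")
  m <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("petal_id,wavelength_nm,reflectance",
               "p1,400,0.1", "p1,500,0.2",
               "p2,400,0.3", "p2,500,0.4"), f)
  writeLines(c("petal_id,plant_id,treatment,area_cm2",
               "p1,pl1,CFA,0.8", "p2,pl1,NFA,0.7"), m)
  set <- read_spectra_csv(f, metadata = m)
  expect_equal(set$spectra[[1]]$meta$treatment, "CFA")
  expect_equal(attr(set, "areas")$area_cm2, c(0.8, 0.7))

  writeLines(c("petal_id,plant_id,treatment", "p1,pl1,CFA"), m)
  expect_error(read_spectra_csv(f, metadata = m), "p2")
})

test_that("resample interpolates linearly and refuses to extrapolate", {
  sp <- petal_spectrum(c(400, 500, 600), c(0.1, 0.2, 0.3), petal_id = "lin")
  rs <- resample(sp, 400:600)
  expect_equal(rs$reflectance, 0.1 + (400:600 - 400) * 0.001)

  const <- flat_spectrum(0.4)
  expect_equal(unique(resample(const, 400:900)$reflectance), 0.4)

  toy <- petal_spectrum(c(400, 500), c(0, 1))
  expect_equal(resample(toy, 450)$reflectance, 0.5)

  # idempotence on the same grid
  expect_equal(resample(rs, 400:600)$reflectance, rs$reflectance)

  expect_error(resample(sp, 300:600), "outside the measured range")
})

test_that("trim subsets by wavelength, preserves metadata, rejects empties", {
  sp <- flat_spectrum(0.5, grid = seq(325, 1075, by = 3))
  tr <- trim(sp, 325, 700)
  expect_gte(min(tr$wavelengths_nm), 325)
  expect_lte(max(tr$wavelengths_nm), 700)
  expect_equal(tr$meta$petal_id, sp$meta$petal_id)

  full <- trim(sp, 325, 1075)
  expect_equal(full$reflectance, sp$reflectance)

  sp2 <- flat_spectrum(0.5, grid = seq(400, 700, by = 3))
  expect_error(trim(sp2, 300, 350), "no samples")
})

test_that("scan averaging is the pointwise mean and is order-invariant", {
  base <- flat_spectrum(0.2)
  expect_equal(average_spectra(rep(list(base), 25))$reflectance,
               base$reflectance)

  two <- average_spectra(list(flat_spectrum(0.2), flat_spectrum(0.4)))
  expect_equal(unique(two$reflectance), 0.3)

  set.seed(11)
  scans <- lapply(1:5, function(i) {
    flat_spectrum(0.3, grid = 400:500, id = "s")
  })
  scans <- lapply(scans, function(s) {
    petal_spectrum(s$wavelengths_nm,
                   s$reflectance + abs(rnorm(101, 0, 0.01)),
                   petal_id = "s")
  })
  expect_equal(average_spectra(scans)$reflectance,
               average_spectra(rev(scans))$reflectance)

  # 25 noisy scans: mean stays within 4 sd/sqrt(25) of the true curve
  set.seed(42)
  sd_noise <- 0.02
  curve <- 0.1 + 0.3 * exp(-((400:700 - 550) / 60)^2)
  noisy <- lapply(1:25, function(i) {
    petal_spectrum(400:700, pmax(curve + rnorm(301, 0, sd_noise), 0),
                   petal_id = "n")
  })
  avg <- average_spectra(noisy)
  expect_true(all(abs(avg$reflectance - curve) < 4 * sd_noise / sqrt(25)))

  expect_error(average_spectra(list(flat_spectrum(0.2, grid = 400:500),
                                    flat_spectrum(0.2, grid = 400:600))),
               "mismatched")
})

test_that("peak height is the windowed maximum with its wavelength", {
  expect_equal(max_peak_height(flat_spectrum(0.4))$height, 0.4)

  bump <- bump_spectrum(center = 450, amp = 0.25, base = 0.05)
  pk <- max_peak_height(bump)
  expect_equal(pk$height, 0.30, tolerance = 1e-9)
  expect_equal(pk$wavelength_nm, 450)

  # bimodal: the 650-nm peak is outside the default window
  grid <- 325:1075
  r <- 0.05 + 0.25 * exp(-((grid - 450) / 25)^2) +
    0.45 * exp(-((grid - 650) / 25)^2)
  bim <- petal_spectrum(grid, r, petal_id = "bim")
  expect_equal(max_peak_height(bim)$height, max(r[grid >= 325 & grid <= 600]))
  expect_lt(max_peak_height(bim)$height, 0.35)

  # invariant to samples outside the window; monotone under scaling inside
  inner <- trim(bim, 325, 600)
  expect_equal(max_peak_height(inner)$height, max_peak_height(bim)$height)
  scaled <- petal_spectrum(grid, r * 1.5, petal_id = "sc")
  expect_gt(max_peak_height(scaled)$height, max_peak_height(bim)$height)

  expect_error(max_peak_height(bim, window = c(200, 600)), "outside")
})

test_that("spectrum and set validation rejects malformed inputs", {
  expect_error(petal_spectrum(c(400, 500), c(0.1, -0.2)), "non-negative")
  expect_error(petal_spectrum(c(400, 500), c(0.1, NA)), "finite")
  expect_error(petal_spectrum(400, 0.1, treatment = "XXX"), "treatment")
  s1 <- flat_spectrum(0.1, grid = 400:500, id = "a")
  s2 <- flat_spectrum(0.1, grid = 400:600, id = "b")
  expect_error(spectrum_set(list(s1, s2)), "one wavelength grid")
  expect_error(spectrum_set(list(s1, s1)), "duplicated petal ids")
})
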