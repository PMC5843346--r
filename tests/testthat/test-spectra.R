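# Amide-I pipeline: I/O, baseline, FSD, derivatives, picking, fitting,
# secondary-structure totals

test_that("spectrum files round-trip, sort and skip comments", {
  gen <- make_amideI_spectrum(amideI_preset("solution"), seed = 2,
                              write_path = withr::local_tempfile(fileext = ".dat"))
  back <- read_spectrum(gen$paths$spectrum)
  expect_equal(back$wavenumber, gen$spectrum$wavenumber, tolerance = 1e-6)
  expect_equal(back$absorbance, gen$spectrum$absorbance, tolerance = 1e-6)
  f <- withr::local_tempfile(fileext = ".csv")
  nu <- seq(1750, 1550, by = -1)
  writeLines(c("# header", sprintf("%.1f,%.6f", nu, exp(-((nu - 1650) / 20)^2))), f)
  sp <- read_spectrum(f)
  expect_true(all(diff(sp$wavenumber) > 0))
  coarse <- withr::local_tempfile(fileext = ".dat")
  nu2 <- seq(1500, 1800, by = 4)
  writeLines(sprintf("%.1f %.6f", nu2, 1 + 0 * nu2), coarse)
  expect_error(read_spectrum(coarse), "insufficient resolution")
})

test_that("baseline subtraction is additive and normalization gives unit area", {
  nu <- seq(1550, 1750, by = 1)
  gauss <- exp(-4 * log(2) * ((nu - 1650) / 15)^2)
  ramp <- 0.3 + 0.002 * (nu - 1550)
  sp_pure <- memdipole:::new_spectrum(nu, gauss)
  sp_ramp <- memdipole:::new_spectrum(nu, gauss + ramp)
  n1 <- baseline_normalize(sp_pure)
  n2 <- baseline_normalize(sp_ramp)
  expect_equal(n2$absorbance, n1$absorbance, tolerance = 1e-6)
  win <- n1$wavenumber >= 1600 & n1$wavenumber <= 1700
  aw <- n1$absorbance[win]
  area <- sum(diff(n1$wavenumber[win]) * (aw[-1] + aw[-length(aw)]) / 2)
  expect_equal(area, 1, tolerance = 1e-9)
  expect_error(baseline_normalize(memdipole:::new_spectrum(nu, 2 + 0.01 * nu)),
               "degenerate")
})

test_that("FSD narrows a matched Lorentzian by k with conserved area", {
  nu <- seq(1500, 1800, by = 0.5)
  y <- lorentzian_band(nu, 1650, 18)
  sp <- memdipole:::new_spectrum(nu, y)
  dec <- fsd(sp, fsd_params(18, 2))
  expect_equal(measure_fwhm(nu, dec$absorbance), 9, tolerance = 0.5)
  expect_equal(sum(dec$absorbance), sum(y), tolerance = 1e-3 * abs(sum(y)))
  expect_identical(fsd(sp, fsd_params(18, 1))$absorbance, sp$absorbance)
  expect_error(fsd(sp, fsd_params(18, 50)), "over-deconvolution")
})

test_that("Savitzky-Golay second derivative marks band centers as minima", {
  nu <- seq(1550, 1750, by = 1)
  g <- function(c0, f) exp(-4 * log(2) * ((nu - c0) / f)^2)
  d1 <- second_derivative(memdipole:::new_spectrum(nu, g(1652, 14)), 7)
  expect_equal(nu[which.min(d1$absorbance)], 1652, tolerance = 1)
  d2 <- second_derivative(memdipole:::new_spectrum(nu, g(1626, 12) + g(1652, 12)), 7)
  mins <- memdipole:::local_minima(d2$absorbance)
  mins <- mins[d2$absorbance[mins] < 0]
  expect_equal(sort(nu[mins]), c(1626, 1652), tolerance = 1)
  dc <- second_derivative(memdipole:::new_spectrum(nu, rep(2, length(nu))), 7)
  expect_equal(dc$absorbance, rep(0, length(nu)), tolerance = 1e-9)
  expect_error(second_derivative(memdipole:::new_spectrum(nu, nu), 4), "odd")
})

test_that("band picking finds the six solution-column components and rejects noise", {
  gen <- make_amideI_spectrum(amideI_preset("solution"), snr = Inf, seed = 1)
  norm <- baseline_normalize(gen$spectrum)
  dec <- fsd(norm, fsd_params(18, 2))
  der <- second_derivative(norm, 5)
  bands <- pick_bands(dec, der, spectrum = norm)
  expect_equal(nrow(bands), 6)
  for (cc in c(1626, 1638, 1652, 1662, 1671, 1684))
    expect_true(any(abs(bands$center - cc) <= 2))
  single <- make_amideI_spectrum(data.frame(center = 1652, area_frac = 100),
                                 snr = Inf, seed = 1)
  nrm1 <- baseline_normalize(single$spectrum)
  b1 <- pick_bands(fsd(nrm1, fsd_params(18, 2)), second_derivative(nrm1, 5),
                   spectrum = nrm1)
  expect_equal(nrow(b1), 1)
  set.seed(77)
  nu <- seq(1550, 1750, by = 1)
  noise <- memdipole:::new_spectrum(nu, stats::rnorm(length(nu), 0, 1e-6) +
                                      (1750 - nu) * 1e-5)
  nn <- baseline_normalize(noise)
  expect_error(pick_bands(fsd(nn, fsd_params(18, 2)),
                          second_derivative(nn, 5), min_prominence = 1.1),
               "no bands")
})

test_that("a single noiseless Gaussian is fitted essentially exactly", {
  gen <- make_amideI_spectrum(data.frame(center = 1652, fwhm = 12,
                                         area_frac = 100),
                              snr = Inf, seed = 1)
  norm <- baseline_normalize(gen$spectrum)
  init <- data.frame(center = 1652.4, fwhm = 14, area_frac = 100)
  m <- fit_bands(norm, init)
  expect_equal(m$center, 1652, tolerance = 1e-4)
  expect_equal(m$fwhm, 12, tolerance = 1e-3)
  expect_equal(m$area_frac, 100)
  # idempotence: re-synthesising the fitted model reproduces the fit window
  resynth <- memdipole:::gaussian_sum(attr(m, "nu"), m$center, m$fwhm,
                                      m$amplitude)
  expect_lt(sqrt(mean((resynth - attr(m, "fitted"))^2)), 1e-12)
  expect_lt(attr(m, "rms"), 1e-6)
})

test_that("two overlapping noisy Gaussians recover generator areas within 3 points", {
  bands <- data.frame(center = c(1640, 1652), fwhm = 10, area_frac = c(60, 40))
  gen <- make_amideI_spectrum(bands, snr = 100, seed = 6)
  norm <- baseline_normalize(gen$spectrum)
  init <- data.frame(center = c(1640.8, 1651.4), fwhm = 14,
                     area_frac = c(50, 50))
  m <- fit_bands(norm, init)
  expect_equal(m$area_frac, c(60, 40), tolerance = 3 / 60)
  expect_equal(sum(m$area_frac), 100, tolerance = 0.5)
})

test_that("class ranges reproduce the published band assignments", {
  expect_equal(classify_band(c(1626, 1638, 1671, 1624, 1635)),
               rep("beta", 5))
  expect_equal(classify_band(1645), "unordered")
  expect_equal(classify_band(c(1652, 1654, 1651)), rep("alpha", 3))
  expect_equal(classify_band(c(1662, 1666, 1667, 1680, 1684)),
               rep("turns", 5))
  m <- data.frame(center = 1652, area_frac = 100, class = "alpha")
  class(m) <- c("band_model", "data.frame")
  expect_equal(assign_secondary_structure(m)[["alpha"]], 100)
})

test_that("the pipeline is invariant to absorbance scaling", {
  gen <- make_amideI_spectrum(amideI_preset("dmpg"), snr = Inf, seed = 3)
  r1 <- amide_decompose(gen$spectrum)
  scaled <- gen$spectrum
  scaled$absorbance <- scaled$absorbance * 37.5
  r2 <- amide_decompose(scaled)
  expect_equal(r2$classes, r1$classes, tolerance = 1e-6)
})

test_that("full decomposition recovers band counts and centers across seeded cases", {
  cases <- list(
    list(center = c(1620, 1645, 1660, 1680), area = c(30, 30, 25, 15)),
    list(center = c(1625, 1640, 1655, 1670, 1685), area = c(25, 25, 20, 20, 10)),
    list(center = c(1618, 1630, 1642, 1654, 1666, 1678, 1690),
         area = c(15, 20, 15, 20, 12, 10, 8)))
  for (i in seq_along(cases)) {
    bands <- data.frame(center = cases[[i]]$center,
                        area_frac = cases[[i]]$area)
    gen <- make_amideI_spectrum(bands, snr = 200, seed = 100 + i)
    # case centers below 1620 cm^-1 fall outside the class ranges by design
    res <- suppressWarnings(amide_decompose(gen$spectrum))
    expect_equal(nrow(res$model), length(bands$center), info = paste("case", i))
    expect_equal(res$model$center, bands$center, tolerance = 1,
                 info = paste("case", i))
  }
})
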