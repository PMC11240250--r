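test_that("peak integration: zero spectra, unit-area peaks, linearity, additivity", {
  cfg <- generator_config(points = 32768, sweep = c(0, 10),
                          frequency = 500)
  flat <- nmr_spectrum(seq(10, 0, length.out = 1024), rep(0, 1024))
  expect_equal(integrate_peak(flat, peak_region(5, 1)), 0)

  # unit-area Lorentzian fully inside a wide region (>= 20 linewidths)
  sp <- synth_spectrum(peak_spec(5, 1, protons = 1, linewidth = 5), cfg)
  area <- integrate_peak(sp, peak_region(5, 1.5))
  expect_equal(area, 1, tolerance = 5e-3)

  # linear in intensity scaling
  sp2 <- sp
  sp2$intensity <- 3.7 * sp$intensity
  expect_equal(integrate_peak(sp2, peak_region(5, 1.5)), 3.7 * area,
               tolerance = 1e-12)

  # additive over disjoint peaks
  both <- synth_spectrum(list(peak_spec(3, 1, linewidth = 5),
                              peak_spec(7, 2, linewidth = 5)), cfg)
  a3 <- integrate_peak(both, peak_region(3, 1.2))
  a7 <- integrate_peak(both, peak_region(7, 1.2))
  expect_equal(a3 + a7, 3, tolerance = 2e-2)

  expect_error(integrate_peak(sp, peak_region(50, 1)), "overlap")
})

test_that("internal-standard referencing accounts for proton counts", {
  expect_equal(concentration_by_reference(2, 2, 6, 3, 3), 6)
  expect_equal(concentration_by_reference(1, 1, 6, 4, 2),
               concentration_by_reference(1, 1, 6, 2, 2) / 2)
  expect_error(concentration_by_reference(1, 0, 6, 2, 2), "> 0")

  # round trip: fumarate (2H) against the 15-proton Cp* ligand at 6 mM
  cfg <- generator_config(points = 32768, sweep = c(0, 10))
  sp <- synth_spectrum(list(peak_spec(6.8, 3, protons = 2, linewidth = 5),
                            peak_spec(2.35, 6, protons = 15,
                                      linewidth = 5)), cfg)
  a_fum <- integrate_peak(sp, peak_region(6.8, 0.8))
  a_cp <- integrate_peak(sp, peak_region(2.35, 0.8))
  conc <- concentration_by_reference(a_fum, a_cp, 6,
                                     analyte_protons = 2,
                                     ref_protons = 15)
  expect_equal(conc, 3, tolerance = 0.02)
})

test_that("SNR estimation round-trips the generator target within 10%", {
  target <- 9
  sigma <- 0.05
  lw <- 15 # Hz; well resolved on the 200 ppm / 8k grid
  hw_ppm <- lw / 125.7 / 2
  conc <- target * sigma * pi * hw_ppm # height = area/(pi*hw)
  measured <- vapply(1:20, function(seed) {
    cfg <- generator_config(seed = seed, noise_sigma = sigma,
                            frequency = 125.7, points = 8192,
                            sweep = c(100, 300))
    sp <- synth_spectrum(peak_spec(175.4, conc, linewidth = lw), cfg,
                         nucleus = "13C")
    snr(sp, peak_region(175.4, 0.03), peak_region(250, 20))
  }, 0)
  expect_equal(mean(measured), target, tolerance = 0.1)

  # a spectrum with a strictly flat noise window has no defined SNR
  clean <- nmr_spectrum(seq(300, 100, length.out = 2048),
                        rep(0, 2048), nucleus = "13C")
  expect_error(snr(clean, peak_region(175.4, 1), peak_region(250, 20)),
               "zero")
  expect_error(snr(clean, peak_region(175.4, 5), peak_region(177, 1)),
               "disjoint")
})

test_that("pure-noise SNR stays of order one", {
  cfg <- generator_config(seed = 3, noise_sigma = 1, sweep = c(0, 10),
                          points = 4096)
  sp <- synth_spectrum(list(), cfg)
  val <- snr(sp, peak_region(7, 0.3), peak_region(3, 1))
  expect_gt(val, 0)
  expect_lt(val, 6)
})

test_that("enhancement factor follows the sqrt-N and concentration scalings", {
  expect_equal(enhancement_factor(2, 2, 1, 5, 5), 1)
  expect_equal(enhancement_factor(9, 2, 32, 3, 1000),
               9 / (2 / sqrt(32)) * (1000 / 3), tolerance = 1e-12)
  expect_equal(enhancement_factor(9, 2, 128, 3, 1000),
               2 * enhancement_factor(9, 2, 32, 3, 1000),
               tolerance = 1e-12)
  expect_error(enhancement_factor(9, 0, 32, 3, 1000), "> 0")
})

test_that("thermal polarization matches the Boltzmann expression", {
  p13c <- thermal_polarization("13C", 11.7, 298)
  expect_equal(p13c, 1.01e-5, tolerance = 0.01)
  expect_equal(thermal_polarization("1H", 11.7, 298) / p13c,
               3.98, tolerance = 0.005)
  # vanishes at high temperature
  expect_lt(thermal_polarization("13C", 11.7, 1e9), 1e-11)
  expect_error(thermal_polarization("23Na", 11.7, 298), "unknown")
})

test_that("percent polarization and yield arithmetic", {
  th <- thermal_polarization("13C", 11.7, 298)
  expect_equal(percent_polarization(1, th), 100 * th)
  expect_equal(percent_polarization(2e3, th), 2 * percent_polarization(1e3, th))
  expect_equal(percent_yield(4.9, 20), 24.5)
  expect_equal(percent_yield(7.0, 20), 35)
  expect_equal(percent_yield(0, 11), 0)
  expect_error(percent_yield(1, 0), "> 0")
})

test_that("the polarization chain is invariant under intensity rescaling", {
  sigma <- 0.03
  hw <- 15 / 125.7 / 2
  mk <- function(scale, seed) {
    cfg <- generator_config(seed = seed, noise_sigma = sigma,
                            frequency = 125.7, points = 8192,
                            sweep = c(0, 300))
    sp <- synth_spectrum(peak_spec(175.4, 9 * sigma * pi * hw,
                                   linewidth = 15), cfg, nucleus = "13C")
    sp$intensity <- scale * sp$intensity
    sp
  }
  chain <- function(scale) {
    s_h <- snr(mk(scale, 11), peak_region(175.4, 0.05),
               peak_region(250, 20))
    s_r <- snr(mk(scale, 12), peak_region(175.4, 0.05),
               peak_region(250, 20))
    percent_polarization(enhancement_factor(s_h, s_r, 32, 3, 1000),
                         thermal_polarization("13C", 11.7, 298))
  }
  expect_equal(chain(1), chain(137.2), tolerance = 1e-10)
})
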