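test_that("the generator is deterministic and respects trivial limits", {
  cfg <- generator_config(seed = 99, noise_sigma = 0.05, points = 1024,
                          sweep = c(0, 10))
  a <- synth_spectrum(peak_spec(5, 1), cfg)
  b <- synth_spectrum(peak_spec(5, 1), cfg)
  expect_identical(a$intensity, b$intensity)

  # a different seed gives different noise
  cfg2 <- generator_config(seed = 100, noise_sigma = 0.05, points = 1024,
                           sweep = c(0, 10))
  expect_false(identical(a$intensity,
                         synth_spectrum(peak_spec(5, 1), cfg2)$intensity))

  # the generator does not disturb the global RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(synth_spectrum(peak_spec(5, 1), cfg))
  expect_identical(rnorm(1), before)

  # zero peaks, zero noise: flat zero spectrum
  flat <- synth_spectrum(list(), generator_config(points = 256,
                                                  sweep = c(0, 10)))
  expect_identical(flat$intensity, rep(0, 256))

  expect_error(synth_spectrum(peak_spec(12, 1),
                              generator_config(sweep = c(0, 10))),
               "outside")
  expect_error(generator_config(points = 32), "points")
  expect_error(generator_config(sweep = c(5, 5)), "sweep")
})

test_that("known concentrations round-trip through the quantification chain", {
  # noise-free: recovery limited only by integration accuracy
  exp0 <- synth_uptake_experiment(beta_chip(), calibrated_tp,
                                  flow_rates = c(2, 10, 20),
                                  noise_sigma = 0, seed = 1)
  rec0 <- vapply(exp0$spectra, quantify_h2, 0)
  expect_equal(rec0, exp0$truth$c_h2_mM, tolerance = 0.02)
  expect_true(all(diff(rec0) < 0))  # monotone non-increasing in flow

  # with noise: recovery within 5% of truth
  expn <- synth_uptake_experiment(beta_chip(), calibrated_tp,
                                  flow_rates = c(4, 12),
                                  noise_sigma = 0.02, seed = 7)
  recn <- vapply(expn$spectra, quantify_h2, 0)
  expect_equal(recn, expn$truth$c_h2_mM, tolerance = 0.05)
})

test_that("noisy uptake recovery is unbiased at the 3-sigma level over 20 seeds", {
  flows <- c(4, 10, 16)
  truth <- synth_uptake_experiment(beta_chip(), calibrated_tp, flows,
                                   noise_sigma = 0, seed = 1)$truth
  rec <- sapply(1:20, function(s) {
    ex <- synth_uptake_experiment(beta_chip(), calibrated_tp, flows,
                                  noise_sigma = 0.05, seed = 100 + s)
    vapply(ex$spectra, quantify_h2, 0)
  })
  for (i in seq_along(flows)) {
    sd_i <- stats::sd(rec[i, ])
    expect_lt(abs(mean(rec[i, ]) - truth$c_h2_mM[i]),
              max(3 * sd_i / sqrt(20), 0.02 * truth$c_h2_mM[i]))
  }
})

test_that("the 13C flow sweep reproduces the qualitative flow response", {
  sweep <- synth_flow_sweep_13c(beta_chip(), calibrated_tp,
                                flow_rates = seq(2, 16, by = 2), seed = 1)
  tr <- sweep$truth
  # rise from the relaxation-dominated low-flow regime...
  expect_gt(tr$amplitude_mM[tr$flow_uL_min == 8],
            3 * tr$amplitude_mM[tr$flow_uL_min == 2])
  # ...followed by a plateau: variation over 8-16 uL/min stays within 30%
  plateau <- tr$amplitude_mM[tr$flow_uL_min >= 8]
  expect_lt((max(plateau) - min(plateau)) / max(plateau), 0.3)

  # at the lowest flow the peak is buried in the noise (< 2x rms)
  hw_ppm <- 15 / 125.7 / 2
  height2 <- tr$amplitude_mM[1] / (pi * hw_ppm)
  expect_lt(height2, 2 * 0.04)
  # ... while the plateau is well above it
  expect_gt(max(plateau) / (pi * hw_ppm), 5 * 0.04)

  # long singlet lifetime + fixed yield: amplitude independent of flow
  flat <- synth_flow_sweep_13c(beta_chip(), calibrated_tp,
                               relaxation = relaxation_params(
                                 t_singlet = 1e9, t1_carbon = 50),
                               flow_rates = c(2, 8, 16),
                               noise_sigma = 0, seed = 1,
                               yield_override = 3)
  expect_lt(diff(range(flat$truth$amplitude_mM)) /
              mean(flat$truth$amplitude_mM), 1e-5)
})

test_that("ground truth is always emitted alongside the spectra", {
  ex <- synth_uptake_experiment(beta_chip(), calibrated_tp, c(4, 8),
                                noise_sigma = 0.01, seed = 3)
  expect_named(ex, c("spectra", "truth"))
  expect_equal(nrow(ex$truth), 2)
  expect_true(all(c("truth", "noise_sigma", "seed") %in%
                  names(ex$spectra[[1]]$metadata)))
})
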