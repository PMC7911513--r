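test_that("scattering vector matches the standard relation", {
  # unit construction: theta = 180 deg, n = 1, lambda = 4*pi m -> q = 1
  inst <- instrument_config(wavelength_nm = 4 * pi * 1e9,
                            scattering_angle_deg = 179.999999,
                            refractive_index = 1)
  expect_equal(scattering_vector(inst), 1, tolerance = 1e-8)
  # backscatter plate-reader optics (oracle value computed independently)
  expect_equal(scattering_vector(instrument_config()), 1.978137e7,
               tolerance = 1e-6)
  # q -> 0 as theta -> 0
  small <- instrument_config(scattering_angle_deg = 1e-6)
  expect_lt(scattering_vector(small), 1)
})

test_that("Stokes-Einstein conversions are exact inverses", {
  expect_equal(stokes_einstein_radius(1.30e-10), 1.8934, tolerance = 1e-4)
  for (R in c(0.5, 1.9, 42.8, 500)) {
    D <- stokes_einstein_diffusion(R)
    expect_equal(stokes_einstein_radius(D), R, tolerance = 1e-12)
  }
  # doubling viscosity halves D at fixed radius
  expect_equal(stokes_einstein_diffusion(1.9, viscosity_mPas = 2 * 0.8872),
               stokes_einstein_diffusion(1.9) / 2)
  expect_error(stokes_einstein_radius(-1), "")
})

test_that("cumulant fit recovers a noiseless single exponential exactly", {
  inst <- quiet_instrument()
  q <- scattering_vector(inst)
  Gamma_true <- 5e4
  D_true <- Gamma_true / q^2
  acf <- synthesize_acf(D_true, inst)
  fit <- cumulant_fit(acf, q)
  expect_equal(fit$Gamma, Gamma_true, tolerance = 1e-10)
  expect_equal(fit$D, D_true, tolerance = 1e-10)
  expect_equal(fit$PDI, 0, tolerance = 1e-8)
  expect_lt(fit$SOS, 1e-3)
  expect_equal(fit$baseline, 1, tolerance = 1e-10)
  expect_length(fit$flags, 0)
})

test_that("cumulant decay rate is invariant to rescaling g2 - 1", {
  inst <- instrument_config(noise_sigma0 = 0.02)
  q <- scattering_vector(inst)
  acf <- synthesize_acf(1.3e-10, inst, seed = 11)
  for (scale in c(0.5, 2, 10)) {
    acf2 <- acf
    acf2$g2 <- 1 + scale * (acf$g2 - 1)
    f1 <- cumulant_fit(acf, q)
    f2 <- cumulant_fit(acf2, q)
    expect_equal(f2$Gamma, f1$Gamma, tolerance = 1e-9)
    expect_equal(f2$beta, scale * f1$beta, tolerance = 1e-9)
  }
})

test_that("all-noise signals fail loudly, not silently", {
  inst <- quiet_instrument()
  q <- scattering_vector(inst)
  acf <- data.frame(lag_s = inst$lag_s,
                    g2 = 1 + rnorm(64, sd = 1e-3))
  expect_error(cumulant_fit(acf, q), class = "platekd_fit_error")
  expect_error(cumulant_fit(data.frame(lag_s = 1:10, g2 = rep(1, 10)), q),
               "16 lags")
})

test_that("default-noise plates pass the quality gates and recover D within 2%", {
  lay <- quick_layout()
  run <- simulate_plate(lay, list(lys = lys_truth()), seed = 5,
                        evaporation = no_evap())
  res <- analyze_plate(run, regularize = "never")
  m <- merge(res, run$truth[, c("well", "D_true")], by = "well")
  rel_err <- abs(m$D_m2_per_s - m$D_true) / m$D_true
  expect_lte(median(rel_err), 0.02)
  expect_equal(median(m$baseline), 1, tolerance = 3e-3)
  expect_lt(median(m$SOS), 20)
  expect_true(all(m$PDI < 0.3))
})

test_that("regularized inversion finds a monodisperse peak on the grid", {
  inst <- quiet_instrument()
  D <- stokes_einstein_diffusion(1.9, inst$temperature_K, inst$viscosity_mPas)
  acf <- synthesize_acf(D, inst)
  dist <- regularized_distribution(acf, inst)
  expect_true(all(dist$weight >= 0))
  expect_equal(sum(dist$weight), 1, tolerance = 1e-12)
  expect_equal(nrow(dist$peaks), 1)
  # within one grid step of the true radius (log grid, ~12% steps)
  expect_equal(dist$peaks$R_H_nm, 1.9, tolerance = 0.13)
  # regularisation spreads a sliver of weight off the peak
  expect_equal(dist$peaks$intensity_pct, 100, tolerance = 1e-3)
})

test_that("regularized inversion resolves a second particle population", {
  # low-noise acquisition: the documented ~43 nm / ~12% population is
  # recovered within grid resolution
  inst <- instrument_config(noise_sigma0 = 0.002)
  D1 <- stokes_einstein_diffusion(1.9, inst$temperature_K, inst$viscosity_mPas)
  base <- synthesize_acf(D1, inst, seed = 21)
  mixed <- inject_second_population(base, 42.8, 0.116, inst, seed = 22)
  dist <- regularized_distribution(mixed, inst)
  expect_gte(nrow(dist$peaks), 2)
  p2 <- dist$peaks[which.max(dist$peaks$R_H_nm), ]
  expect_equal(p2$R_H_nm, 42.8, tolerance = 0.25)
  expect_equal(p2$intensity_pct, 11.6, tolerance = 0.45)
})

test_that("second-population detection is robust at default instrument noise", {
  inst <- instrument_config()
  D1 <- stokes_einstein_diffusion(1.9, inst$temperature_K, inst$viscosity_mPas)
  found <- 0; i2 <- c()
  for (s in 1:40) {
    mixed <- inject_second_population(synthesize_acf(D1, inst, seed = s),
                                      42.8, 0.116, inst, seed = s + 1000)
    pk <- regularized_distribution(mixed, inst)$peaks
    if (nrow(pk) >= 2) {
      found <- found + 1
      i2 <- c(i2, pk$intensity_pct[which.max(pk$R_H_nm)])
    }
  }
  expect_gte(found, 0.6 * 40)
  expect_equal(median(i2), 11.6, tolerance = 0.35)
  # clean wells rarely show a second peak
  fp <- sum(sapply(1:20, function(s) {
    nrow(regularized_distribution(synthesize_acf(D1, inst, seed = s),
                                  inst)$peaks) >= 2
  }))
  expect_lte(fp, 4)
})

test_that("stronger regularization spreads the weights", {
  inst <- instrument_config(noise_sigma0 = 0.02)
  D <- stokes_einstein_diffusion(1.9, inst$temperature_K, inst$viscosity_mPas)
  acf <- synthesize_acf(D, inst, seed = 31)
  wmax <- vapply(c(1e-4, 1e-2, 1, 100), function(lam) {
    max(regularized_distribution(acf, inst, reg_weight = lam)$weight)
  }, 1)
  expect_true(all(diff(wmax) <= 1e-12))
  expect_error(regularized_distribution(acf, inst, reg_weight = -1), "reg_weight")
})

test_that("bimodal wells are flagged through the regularized cross-check", {
  inst <- instrument_config()
  lay <- quick_layout(cc = c(2, 10), reps = 2)
  run <- simulate_plate(
    lay, list(lys = lys_truth()), instrument = inst,
    anomalies = anomaly_spec(second_population_rate = 1), seed = 9,
    evaporation = no_evap())
  res <- analyze_plate(run, regularize = "auto")
  expect_true(any(grepl("multimodal", res$quality_flags)))
  # an ~12%-intensity second population raises the estimated PDI well
  # above the clean-well values (~0), past the auto cross-check trigger
  expect_true(all(res$PDI > 0.1))
})
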