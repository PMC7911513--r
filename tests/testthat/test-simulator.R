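test_that("concentration dependence of diffusion follows D0*(1 + kD*c)", {
  tr0 <- formulation_truth("f", kD = 0, D0 = 1.3e-10)
  expect_equal(forward_diffusion(c(0, 0.002, 0.014), tr0), rep(1.3e-10, 3))
  trp <- formulation_truth("f", kD = 57, D0 = 1.3e-10)
  expect_equal(forward_diffusion(0.010, trp) / trp$D0, 1.570)
  trn <- formulation_truth("f", kD = -14.8, D0 = 1.3e-10)
  expect_equal(forward_diffusion(0.010, trn) / trn$D0, 0.852)
  # unphysical region rejected
  trx <- formulation_truth("f", kD = -120, D0 = 1.3e-10)
  expect_error(forward_diffusion(0.010, trx), "unphysical")
})

test_that("formulation truth links D0 and R_H consistently", {
  tr <- formulation_truth("f", kD = 57, R_H_nm = 1.9)
  expect_equal(stokes_einstein_radius(tr$D0), 1.9, tolerance = 1e-12)
  tr2 <- formulation_truth("f", kD = 57, D0 = tr$D0)
  expect_equal(tr2$R_H_nm, 1.9, tolerance = 1e-12)
})

test_that("evaporation conserves solute mass and is monotone in time", {
  p <- evaporation_params()
  t_grid <- seq(0, 8 * 3600, length.out = 25)
  for (c0 in c(2, 10, 14)) {
    for (edge in c(FALSE, TRUE)) {
      tr <- evaporation_trajectory(c0, edge, t_grid, p)
      # mass conservation to machine precision before the floor engages
      free <- tr$volume_fraction > p$min_volume_fraction
      expect_equal(tr$conc_mg_ml[free] * tr$volume_fraction[free],
                   rep(c0, sum(free)), tolerance = 1e-14)
      # effective concentration never decreases with elapsed time
      expect_true(all(diff(tr$conc_mg_ml) >= -1e-12))
    }
  }
  # zero rate: concentration constant
  tr0 <- evaporation_trajectory(2, FALSE, t_grid, no_evap())
  expect_equal(tr0$conc_mg_ml, rep(2, length(t_grid)))
  # edge wells lose volume faster
  te <- evaporation_trajectory(2, TRUE, 3600, p)
  tc <- evaporation_trajectory(2, FALSE, 3600, p)
  expect_lt(te$volume_fraction, tc$volume_fraction)
  # volume floor respected
  long <- evaporation_trajectory(0.1, TRUE, 100 * 3600, p)
  expect_gte(long$volume_fraction, p$min_volume_fraction)
})

test_that("default evaporation reproduces the 2.5% dilute-sample drift", {
  # a 2 mg/mL centre well measured at the end of a full-plate run
  # (384 wells x 75 s) shows an apparent D increase of ~2.5% for a
  # formulation with kD = 91.8 mL/g
  tr <- formulation_truth("f", kD = 91.8, D0 = 1.3e-10)
  t_end <- 384 * 75
  ev <- evaporation_trajectory(2, FALSE, t_end, evaporation_params())
  drift <- 100 * (forward_diffusion(ev$conc_mg_ml / 1000, tr) /
                    forward_diffusion(0.002, tr) - 1)
  expect_equal(drift, 2.5, tolerance = 0.01)
  # drift decreases with concentration: 2 > 10 > 14 mg/mL
  drift_at <- function(c0) {
    ev <- evaporation_trajectory(c0, FALSE, t_end, evaporation_params())
    100 * (forward_diffusion(ev$conc_mg_ml / 1000, tr) /
             forward_diffusion(c0 / 1000, tr) - 1)
  }
  expect_gt(drift_at(2), drift_at(10))
  expect_gt(drift_at(10), drift_at(14))
})

test_that("noiseless ACF matches the closed form", {
  inst <- quiet_instrument()
  acf <- synthesize_acf(1.3e-10, inst)
  q <- scattering_vector(inst)
  expect_equal(acf$g2, 1 + inst$beta * exp(-2 * 1.3e-10 * q^2 * acf$lag_s))
  # g2 - 1 tends to beta as tau -> 0 and to 0 as tau -> infinity
  short <- synthesize_acf(1.3e-10, inst,
                          lag_s = exp(seq(log(1e-12), log(1), length.out = 64)))
  expect_equal(short$g2[1] - 1, inst$beta, tolerance = 1e-6)
  expect_equal(acf$g2[length(acf$g2)], 1, tolerance = 1e-12)
  expect_error(synthesize_acf(-1, inst), "positive")
})

test_that("ACF noise scale and seed determinism behave as configured", {
  inst <- instrument_config(noise_sigma0 = 0.02, n_acquisitions = 15)
  a1 <- synthesize_acf(1.3e-10, inst, seed = 42)
  a2 <- synthesize_acf(1.3e-10, inst, seed = 42)
  expect_identical(a1, a2)
  a3 <- synthesize_acf(1.3e-10, inst, seed = 43)
  expect_false(identical(a1$g2, a3$g2))
  # noise sd shrinks with averaging over acquisitions
  resid <- replicate(200, {
    a <- synthesize_acf(1.3e-10, inst)
    a$g2[64] - 1
  })
  expect_equal(sd(resid), 0.02 / sqrt(15), tolerance = 0.25)
})

test_that("second-population injection has correct limits", {
  inst <- quiet_instrument()
  base <- synthesize_acf(1.3e-10, inst)
  # f = 0: unchanged
  same <- inject_second_population(base, 42.8, 0, inst)
  expect_equal(same$g2, base$g2, tolerance = 1e-12)
  # f = 1: single exponential at the second population's decay rate
  only2 <- inject_second_population(base, 42.8, 1, inst)
  D2 <- stokes_einstein_diffusion(42.8, inst$temperature_K, inst$viscosity_mPas)
  q <- scattering_vector(inst)
  expect_equal(only2$g2, 1 + inst$beta * exp(-2 * D2 * q^2 * base$lag_s),
               tolerance = 1e-12)
  expect_true(isTRUE(attr(only2, "anomalous")))
  expect_error(inject_second_population(base, 42.8, 1.2, inst), "fraction")
})

test_that("simulated plates are reproducible and carry a truth sidecar", {
  lay <- quick_layout()
  truths <- list(lys = lys_truth())
  r1 <- simulate_plate(lay, truths, seed = 7)
  r2 <- simulate_plate(lay, truths, seed = 7)
  expect_identical(r1$measurements, r2$measurements)
  expect_identical(r1$truth, r2$truth)
  expect_equal(nrow(r1$truth), 20)
  expect_equal(nrow(r1$measurements), 20 * 64)
  # sidecar concentrations: effective >= nominal under evaporation
  expect_true(all(r1$truth$conc_eff_mg_ml >= r1$truth$conc_nominal_mg_ml))
  # missing truth entry is refused
  expect_error(simulate_plate(lay, list(), seed = 1), "missing formulation")
})

test_that("simulated run files round-trip through disk", {
  lay <- quick_layout(cc = c(2, 10), reps = 2)
  run <- simulate_plate(lay, list(lys = lys_truth()), seed = 3)
  dir <- tempfile()
  paths <- write_dls_run(run, dir)
  meas <- read_measurements(paths[["measurements"]])
  expect_equal(nrow(meas), nrow(run$measurements))
  expect_equal(meas$g2, run$measurements$g2, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, 3)
  expect_equal(nrow(truth$truth), nrow(run$truth))
  unlink(dir, recursive = TRUE)
})

test_that("edge wells accumulate more apparent-D drift than centre wells", {
  # matched concentration, adjacent rows (near-identical elapsed time):
  # the edge multiplier makes the measured diffusion coefficient deviate
  # more from its nominal value in the bottom edge row than in the last
  # centre row
  w <- rbind(
    data.frame(well = format_well_address(14L, 2:11), role = "sample",
               formulation_id = "lys", concentration_mg_ml = 2,
               replicate = 1:10, fill_volume_ul = 30,
               stringsAsFactors = FALSE),
    data.frame(well = format_well_address(15L, 2:11), role = "sample",
               formulation_id = "lys", concentration_mg_ml = 2,
               replicate = 1:10, fill_volume_ul = 30,
               stringsAsFactors = FALSE))
  lay <- plate_layout(w)
  devs <- sapply(1:100, function(s) {
    run <- simulate_plate(lay, list(lys = lys_truth()), seed = s, dwell = 600)
    res <- analyze_plate(run, regularize = "never")
    m <- merge(res, run$truth[, c("well", "D_nominal", "edge")], by = "well")
    tapply(abs(m$D_m2_per_s - m$D_nominal) / m$D_nominal, m$edge, mean)
  })
  expect_gte(mean(devs["TRUE", ]), mean(devs["FALSE", ]))
})
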