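# Forward simulator for plate-reader DLS runs: concentration-dependent
# diffusion, evaporation drift by plate position and elapsed time, ACF
# noise, and anomaly injection (second particle populations, gross
# per-well outliers).

#' Ground-truth description of a formulation
#'
#' Couples an infinite-dilution diffusion coefficient `D0`, a diffusion
#' interaction parameter `kD` and the hydrodynamic radius consistent with
#' `D0` by Stokes-Einstein at the simulation temperature. Supply either
#' `D0` or `R_H_nm`; the other is derived.
#'
#' @param formulation_id Identifier string.
#' @param kD Diffusion interaction parameter in mL/g. Positive values mean
#'   net repulsive protein-protein interactions, negative net attraction.
#' @param D0 Diffusion coefficient at infinite dilution, m^2/s.
#' @param R_H_nm Hydrodynamic radius in nm (alternative to `D0`).
#' @param temperature_K,viscosity_mPas Conditions linking `D0` and `R_H_nm`.
#' @return Object of class `formulation_truth`.
#' @examples
#' formulation_truth("lysozyme", kD = 57, R_H_nm = 1.9)
#' @export
formulation_truth <- function(formulation_id, kD, D0 = NULL, R_H_nm = NULL,
                              temperature_K = 298.15, viscosity_mPas = 0.8872) {
  if (is.null(D0) && is.null(R_H_nm)) pk_stop("supply D0 or R_H_nm")
  if (is.null(D0)) D0 <- stokes_einstein_diffusion(R_H_nm, temperature_K, viscosity_mPas)
  if (is.null(R_H_nm)) R_H_nm <- stokes_einstein_radius(D0, temperature_K, viscosity_mPas)
  stopifnot(D0 > 0, R_H_nm > 0)
  structure(list(formulation_id = formulation_id, D0 = D0, kD = kD,
                 R_H_nm = R_H_nm, temperature_K = temperature_K,
                 viscosity_mPas = viscosity_mPas),
            class = "formulation_truth")
}

#' Instrument configuration for the DLS simulator and ACF analysis
#'
#' Defaults describe a backscatter plate reader: 830 nm laser, 158 degree
#' detection angle, aqueous solvent at 25 C, 15 acquisitions of 15 s per
#' well. All optics values are configuration, never hard-coded in the
#' physics.
#'
#' @param wavelength_nm Laser vacuum wavelength, nm.
#' @param scattering_angle_deg Detection angle in degrees, in (0, 180).
#' @param refractive_index Solvent refractive index.
#' @param temperature_K Measurement temperature, K.
#' @param viscosity_mPas Solvent viscosity, mPa s.
#' @param n_acquisitions,acquisition_time_s Number and length (s) of
#'   acquisitions averaged per well.
#' @param noise_sigma0 ACF noise scale; the per-lag Gaussian noise standard
#'   deviation is `noise_sigma0 / sqrt(n_acquisitions)`.
#' @param beta Coherence (intercept) factor of the ideal ACF.
#' @param n_lags,lag_min_s,lag_max_s Logarithmic lag grid specification.
#' @return Object of class `instrument_config`.
#' @export
instrument_config <- function(wavelength_nm = 830, scattering_angle_deg = 158,
                              refractive_index = 1.331, temperature_K = 298.15,
                              viscosity_mPas = 0.8872, n_acquisitions = 15,
                              acquisition_time_s = 15, noise_sigma0 = 0.01,
                              beta = 0.9, n_lags = 64,
                              lag_min_s = 1e-6, lag_max_s = 1) {
  stopifnot(wavelength_nm > 0, scattering_angle_deg > 0, scattering_angle_deg < 180,
            refractive_index > 0, temperature_K > 0, viscosity_mPas > 0,
            n_acquisitions >= 1, acquisition_time_s > 0, noise_sigma0 >= 0,
            beta > 0, n_lags >= 16, lag_min_s > 0, lag_max_s > lag_min_s)
  structure(list(wavelength_nm = wavelength_nm,
                 scattering_angle_deg = scattering_angle_deg,
                 refractive_index = refractive_index,
                 temperature_K = temperature_K,
                 viscosity_mPas = viscosity_mPas,
                 n_acquisitions = n_acquisitions,
                 acquisition_time_s = acquisition_time_s,
                 noise_sigma0 = noise_sigma0, beta = beta,
                 lag_s = lseq(lag_min_s, lag_max_s, n_lags)),
            class = "instrument_config")
}

#' Evaporation model parameters
#'
#' Solvent loss is modelled as linear-in-time fractional volume loss with
#' a multiplicative edge factor and exponential suppression with the
#' initial solute concentration (concentrated samples evaporate less:
#' higher viscosity, bound hydration water). Defaults are calibrated so a
#' dilute (2 mg/mL) centre well measured at the end of a full-plate run
#' shows an apparent diffusion-coefficient increase of 2.5%.
#'
#' @param base_rate_per_h Fractional volume loss per hour for a centre well
#'   at zero concentration.
#' @param edge_factor Multiplier (>= 1) for edge wells.
#' @param suppression_scale_mg_ml Concentration at which evaporation is
#'   attenuated by a factor e.
#' @param min_volume_fraction Floor on V(t)/V0 (default 1/6, i.e. a 30 uL
#'   fill never drops below the 5 uL minimum working volume).
#' @return Object of class `evaporation_params`.
#' @export
evaporation_params <- function(base_rate_per_h = 0.028605, edge_factor = 2,
                               suppression_scale_mg_ml = 4,
                               min_volume_fraction = 1 / 6) {
  stopifnot(base_rate_per_h >= 0, edge_factor >= 1,
            suppression_scale_mg_ml > 0,
            min_volume_fraction > 0, min_volume_fraction <= 1)
  structure(list(base_rate_per_h = base_rate_per_h, edge_factor = edge_factor,
                 suppression_scale_mg_ml = suppression_scale_mg_ml,
                 min_volume_fraction = min_volume_fraction),
            class = "evaporation_params")
}

#' Concentration dependence of the mutual diffusion coefficient
#'
#' Evaluates `D = D0 * (1 + kD * c)` with `kD` in mL/g, so the
#' concentration must be given in g/mL (10 mg/mL = 0.010 g/mL).
#'
#' @param conc_g_ml Concentration in g/mL (>= 0).
#' @param truth A [formulation_truth()].
#' @return Diffusion coefficient(s) in m^2/s.
#' @examples
#' tr <- formulation_truth("f", kD = 57, D0 = 1.3e-10)
#' forward_diffusion(0.010, tr) / tr$D0  # 1.57
#' @export
forward_diffusion <- function(conc_g_ml, truth) {
  stopifnot(inherits(truth, "formulation_truth"), all(conc_g_ml >= 0))
  fac <- 1 + truth$kD * conc_g_ml
  if (any(fac <= 0)) {
    pk_stop("1 + kD*c <= 0: negative diffusion coefficient is unphysical",
            "platekd_model_error")
  }
  truth$D0 * fac
}

#' Evaporation trajectory of a well
#'
#' Volume fraction `V(t)/V0 = max(floor, 1 - rate * t_h)` with
#' `rate = base_rate * edge_mult * exp(-c0 / suppression_scale)`; the
#' effective concentration follows from exact solute-mass conservation,
#' `c(t) * V(t) = c0 * V0` (until the volume floor engages).
#'
#' @param conc0_mg_ml Initial concentration, mg/mL.
#' @param edge Logical: is the well an edge well?
#' @param elapsed_time_s Elapsed time(s) since the start of the run, s.
#' @param params An [evaporation_params()].
#' @return Data frame with `volume_fraction` and `conc_mg_ml`.
#' @export
evaporation_trajectory <- function(conc0_mg_ml, edge, elapsed_time_s,
                                   params = evaporation_params()) {
  stopifnot(all(elapsed_time_s >= 0), all(conc0_mg_ml >= 0))
  mult <- ifelse(edge, params$edge_factor, 1)
  rate <- params$base_rate_per_h * mult *
    exp(-conc0_mg_ml / params$suppression_scale_mg_ml)
  vf <- pmax(params$min_volume_fraction, 1 - rate * elapsed_time_s / 3600)
  data.frame(volume_fraction = vf, conc_mg_ml = conc0_mg_ml / vf)
}

#' Synthesise an intensity autocorrelation function
#'
#' Generates `g2(tau) = 1 + beta * exp(-2 * Gamma * tau) + eps(tau)` with
#' `Gamma = D * q^2` and i.i.d. Gaussian noise of standard deviation
#' `noise_sigma0 / sqrt(n_acquisitions)`. Reproducible under a fixed seed.
#'
#' @param D Diffusion coefficient, m^2/s (> 0).
#' @param instrument An [instrument_config()].
#' @param lag_s Optional lag grid (s, strictly increasing); defaults to the
#'   instrument's grid.
#' @param seed Optional integer seed.
#' @return Data frame `lag_s`, `g2` with attributes `Gamma`, `beta`,
#'   `noise_sd`.
#' @export
synthesize_acf <- function(D, instrument = instrument_config(),
                           lag_s = NULL, seed = NULL) {
  if (!is.numeric(D) || length(D) != 1L || D <= 0) {
    pk_stop("D must be a single positive number", "platekd_model_error")
  }
  if (is.null(lag_s)) lag_s <- instrument$lag_s
  stopifnot(length(lag_s) >= 16, all(diff(lag_s) > 0))
  q <- scattering_vector(instrument)
  Gamma <- D * q^2
  sd_noise <- instrument$noise_sigma0 / sqrt(instrument$n_acquisitions)
  g2 <- with_seed(seed, {
    1 + instrument$beta * exp(-2 * Gamma * lag_s) +
      (if (sd_noise > 0) stats::rnorm(length(lag_s), sd = sd_noise) else 0)
  })
  structure(data.frame(lag_s = lag_s, g2 = g2),
            Gamma = Gamma, beta = instrument$beta, noise_sd = sd_noise)
}

#' Inject a second particle population into an ACF
#'
#' Replaces the field correlation by the two-component mixture
#' `g2 - 1 = beta * ((1 - f) * exp(-Gamma1 * tau) + f * exp(-Gamma2 * tau))^2`
#' where `f` is the intensity fraction of the second population and
#' `Gamma2` follows from its hydrodynamic radius via Stokes-Einstein.
#' Fresh noise of the same scale is applied.
#'
#' @param acf Output of [synthesize_acf()] (carries `Gamma`, `beta`,
#'   `noise_sd` attributes).
#' @param R_H2_nm Hydrodynamic radius of the second population, nm.
#' @param intensity_fraction Intensity fraction `f` in (0, 1); the
#'   degenerate endpoints 0 and 1 are allowed and give the corresponding
#'   single-exponential.
#' @param instrument An [instrument_config()].
#' @param seed Optional integer seed for the fresh noise.
#' @return Data frame like `acf`, flagged with attribute `anomalous = TRUE`.
#' @export
inject_second_population <- function(acf, R_H2_nm, intensity_fraction,
                                     instrument = instrument_config(),
                                     seed = NULL) {
  if (intensity_fraction < 0 || intensity_fraction > 1) {
    pk_stop("intensity_fraction must lie in [0, 1]", "platekd_model_error")
  }
  Gamma1 <- attr(acf, "Gamma")
  beta <- attr(acf, "beta")
  noise_sd <- attr(acf, "noise_sd")
  if (is.null(Gamma1) || is.null(beta)) pk_stop("acf lacks Gamma/beta attributes")
  D2 <- stokes_einstein_diffusion(R_H2_nm, instrument$temperature_K,
                                  instrument$viscosity_mPas)
  Gamma2 <- D2 * scattering_vector(instrument)^2
  f <- intensity_fraction
  g1 <- (1 - f) * exp(-Gamma1 * acf$lag_s) + f * exp(-Gamma2 * acf$lag_s)
  g2 <- with_seed(seed, {
    1 + beta * g1^2 +
      (if (noise_sd > 0) stats::rnorm(length(acf$lag_s), sd = noise_sd) else 0)
  })
  structure(data.frame(lag_s = acf$lag_s, g2 = g2),
            Gamma = Gamma1, Gamma2 = Gamma2, beta = beta,
            noise_sd = noise_sd, anomalous = TRUE)
}

#' Anomaly specification for the plate simulator
#'
#' @param second_population_rate Per-well probability of injecting a second
#'   particle population (soluble aggregates/oligomers).
#' @param R_H2_mean_nm,R_H2_sd_nm Normal distribution the second
#'   population's radius is drawn from (defaults 42.8 and 7.9 nm).
#' @param intensity_fraction Intensity fraction of the second population.
#' @param outlier_rate Per-well probability of a gross outlier (dust,
#'   bubbles, splashes): the well's diffusion coefficient is scaled by a
#'   random factor between `outlier_magnitude` bounds, up or down.
#' @param outlier_magnitude Two positive numbers: range of the
#'   multiplicative |log| displacement (default 0.2-0.5).
#' @return List of class `anomaly_spec`.
#' @export
anomaly_spec <- function(second_population_rate = 0, R_H2_mean_nm = 42.8,
                         R_H2_sd_nm = 7.9, intensity_fraction = 0.116,
                         outlier_rate = 0, outlier_magnitude = c(0.2, 0.5)) {
  stopifnot(second_population_rate >= 0, second_population_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            length(outlier_magnitude) == 2, all(outlier_magnitude > 0))
  structure(list(second_population_rate = second_population_rate,
                 R_H2_mean_nm = R_H2_mean_nm, R_H2_sd_nm = R_H2_sd_nm,
                 intensity_fraction = intensity_fraction,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude),
            class = "anomaly_spec")
}

#' Simulate a full plate-reader DLS run
#'
#' Composes the forward model per well: the acquisition schedule assigns
#' elapsed times, evaporation converts nominal to effective concentration,
#' the concentration dependence gives the true diffusion coefficient, and
#' an ACF with instrument noise is synthesised. Control and placebo wells
#' (concentration 0) scatter at `D0` of a reference formulation if one is
#' supplied for them, otherwise they are skipped.
#'
#' @param layout A [plate_layout()].
#' @param truths Named list of [formulation_truth()] objects keyed by
#'   formulation id; every sample formulation needs an entry.
#' @param instrument An [instrument_config()].
#' @param evaporation An [evaporation_params()]; use
#'   `evaporation_params(base_rate_per_h = 0)` to switch evaporation off.
#' @param anomalies An [anomaly_spec()].
#' @param seed Integer seed; the run is fully reproducible from
#'   (layout, parameters, seed).
#' @param dwell,order Passed to [acquisition_schedule()].
#' @param run_id Run identifier recorded in the output.
#' @return Object of class `dls_run`: a list with `measurements` (long
#'   data frame `run_id`, `well`, `elapsed_time_s`, `lag_s`, `g2`),
#'   `truth` (per-well sidecar: nominal and effective concentration,
#'   nominal and true D, anomaly flags), `schedule`, and parameter echoes.
#' @export
simulate_plate <- function(layout, truths, instrument = instrument_config(),
                           evaporation = evaporation_params(),
                           anomalies = anomaly_spec(), seed = 1,
                           dwell = 75, order = "row-major",
                           run_id = "run1") {
  stopifnot(inherits(layout, "plate_layout"))
  sched <- acquisition_schedule(layout, order = order, dwell = dwell)
  w <- layout$wells
  w <- w[match(sched$well, w$well), , drop = FALSE]
  w$elapsed_time_s <- sched$elapsed_time_s
  smp <- w[w$role == "sample", , drop = FALSE]
  need <- setdiff(unique(smp$formulation_id), names(truths))
  if (length(need)) {
    pk_stop(sprintf("missing formulation truth(s): %s", paste(need, collapse = ", ")),
            "platekd_model_error")
  }
  pos <- classify_position(smp)
  with_seed(seed, {
    n <- nrow(smp)
    is_second <- stats::runif(n) < anomalies$second_population_rate
    is_outlier <- stats::runif(n) < anomalies$outlier_rate
    meas <- vector("list", n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      tr <- truths[[smp$formulation_id[i]]]
      ev <- evaporation_trajectory(smp$concentration_mg_ml[i], pos$edge[i],
                                   smp$elapsed_time_s[i], evaporation)
      D_nom <- forward_diffusion(smp$concentration_mg_ml[i] / 1000, tr)
      D_true <- forward_diffusion(ev$conc_mg_ml / 1000, tr)
      if (is_outlier[i]) {
        shift <- stats::runif(1, anomalies$outlier_magnitude[1],
                              anomalies$outlier_magnitude[2])
        D_true <- D_true * exp(sample(c(-1, 1), 1) * shift)
      }
      acf <- synthesize_acf(D_true, instrument)
      if (is_second[i]) {
        R2 <- abs(stats::rnorm(1, anomalies$R_H2_mean_nm, anomalies$R_H2_sd_nm))
        acf <- inject_second_population(acf, R2, anomalies$intensity_fraction,
                                        instrument)
      }
      meas[[i]] <- data.frame(run_id = run_id, well = smp$well[i],
                              elapsed_time_s = smp$elapsed_time_s[i],
                              lag_s = acf$lag_s, g2 = acf$g2,
                              stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(
        run_id = run_id, well = smp$well[i],
        formulation_id = smp$formulation_id[i],
        conc_nominal_mg_ml = smp$concentration_mg_ml[i],
        conc_eff_mg_ml = ev$conc_mg_ml,
        volume_fraction = ev$volume_fraction,
        elapsed_time_s = smp$elapsed_time_s[i],
        edge = pos$edge[i],
        D_nominal = D_nom, D_true = D_true,
        second_population = is_second[i], outlier = is_outlier[i],
        stringsAsFactors = FALSE)
    }
    structure(list(measurements = do.call(rbind, meas),
                   truth = do.call(rbind, truth_rows),
                   schedule = sched, layout = layout,
                   instrument = instrument, evaporation = evaporation,
                   anomalies = anomalies, seed = seed, run_id = run_id),
              class = "dls_run")
  })
}

#' @export
print.dls_run <- function(x, ...) {
  cat(sprintf("<dls_run '%s'>: %d wells x %d lags (seed %s)\n", x$run_id,
              nrow(x$truth), length(x$instrument$lag_s), format(x$seed)))
  invisible(x)
}

#' Write a simulated run to disk
#'
#' Writes the long-format measurement CSV (`run_id`, `well`,
#' `elapsed_time_s`, `lag_s`, `g2`) and a ground-truth sidecar JSON with
#' per-well true values, anomaly flags, the seed and a full parameter echo.
#'
#' @param run A `dls_run` from [simulate_plate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dls_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, paste0(run$run_id, "_measurements.csv"))
  tpath <- file.path(dir, paste0(run$run_id, "_truth.json"))
  utils::write.csv(run$measurements, mpath, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  echo <- list(run_id = run$run_id, seed = run$seed,
               instrument = unclass(run$instrument),
               evaporation = unclass(run$evaporation),
               anomalies = unclass(run$anomalies),
               truth = run$truth)
  jsonlite::write_json(echo, tpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(measurements = mpath, truth = tpath))
}

#' Read a long-format measurement CSV
#'
#' @param path CSV with columns `run_id`, `well`, `elapsed_time_s`,
#'   `lag_s`, `g2`.
#' @return Data frame in the same long format.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("run_id", "well", "elapsed_time_s", "lag_s", "g2")
  miss <- setdiff(need, names(df))
  if (length(miss)) pk_stop(paste("measurement file missing columns:",
                                  paste(miss, collapse = ", ")))
  df
}
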