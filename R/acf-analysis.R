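# Extraction of diffusion coefficients, hydrodynamic radii and quality
# metrics from intensity autocorrelation functions: second-order cumulant
# fits and non-negative Tikhonov-regularised size distributions.

#' Scattering vector magnitude
#'
#' `q = (4 * pi * n / lambda) * sin(theta / 2)` with the wavelength in
#' metres.
#'
#' @param instrument An [instrument_config()].
#' @return q in 1/m.
#' @examples
#' scattering_vector(instrument_config())  # ~1.98e7 for 830 nm / 158 deg
#' @export
scattering_vector <- function(instrument = instrument_config()) {
  lambda <- instrument$wavelength_nm * 1e-9
  theta <- instrument$scattering_angle_deg * pi / 180
  4 * pi * instrument$refractive_index / lambda * sin(theta / 2)
}

#' Stokes-Einstein conversions
#'
#' `R_H = kB * T / (6 * pi * eta * D)` and its exact inverse.
#'
#' @param D Diffusion coefficient, m^2/s.
#' @param R_H_nm Hydrodynamic radius, nm.
#' @param temperature_K Temperature, K.
#' @param viscosity_mPas Solvent viscosity, mPa s.
#' @return Radius in nm, or diffusion coefficient in m^2/s.
#' @examples
#' stokes_einstein_radius(1.3e-10)  # ~1.9 nm: a lysozyme monomer
#' @export
stokes_einstein_radius <- function(D, temperature_K = 298.15,
                                   viscosity_mPas = 0.8872) {
  stopifnot(all(D > 0), temperature_K > 0, viscosity_mPas > 0)
  .kB * temperature_K / (6 * pi * viscosity_mPas * 1e-3 * D) * 1e9
}

#' @rdname stokes_einstein_radius
#' @export
stokes_einstein_diffusion <- function(R_H_nm, temperature_K = 298.15,
                                      viscosity_mPas = 0.8872) {
  stopifnot(all(R_H_nm > 0), temperature_K > 0, viscosity_mPas > 0)
  .kB * temperature_K / (6 * pi * viscosity_mPas * 1e-3 * (R_H_nm * 1e-9))
}

#' Second-order cumulant fit of an ACF
#'
#' Fits `ln(g2 - baseline) = ln(beta) - 2 * Gamma * tau + mu2 * tau^2` by
#' weighted least squares over the lag window where the baseline-corrected
#' signal exceeds `window_frac` of a crude two-pass intercept estimate
#' (log-transform weights proportional to the squared signal). The
#' baseline is estimated as the mean of the long-lag tail.
#'
#' Quality flags follow common plate-reader acceptance rules: baseline
#' outside `[0.997, 1.003]`, `SOS >= sos_threshold` (residual sum of
#' squares over the fit window, normalised by the tail-estimated noise
#' variance) and `PDI > 0.3`.
#'
#' @param acf Data frame with `lag_s` and `g2` (e.g. from
#'   [synthesize_acf()]), or a numeric vector of lags with `g2` supplied
#'   separately.
#' @param q Scattering vector, 1/m (see [scattering_vector()]).
#' @param g2 Optional numeric vector when `acf` is a lag vector.
#' @param window_frac Fit-window threshold as a fraction of the crude
#'   intercept (default 0.05).
#' @param sos_threshold SOS acceptance threshold (default 20).
#' @param tail_frac Fraction of trailing lags used for the baseline and
#'   noise estimates (default 0.25).
#' @return Object of class `cumulant_fit`: `Gamma` (1/s), `beta`, `mu2`,
#'   `PDI`, `baseline`, `SOS`, `D` (m^2/s), `n_window`, `flags`
#'   (character vector).
#' @export
cumulant_fit <- function(acf, q, g2 = NULL, window_frac = 0.05,
                         sos_threshold = 20, tail_frac = 0.25) {
  if (is.data.frame(acf)) {
    lag_s <- acf$lag_s; g2 <- acf$g2
  } else {
    lag_s <- acf
  }
  n <- length(lag_s)
  if (n < 16) pk_stop("need at least 16 lags", "platekd_fit_error")
  stopifnot(length(g2) == n, q > 0)

  tail_idx <- seq.int(n - max(4L, floor(tail_frac * n)) + 1L, n)
  baseline <- mean(g2[tail_idx])
  y <- g2 - baseline
  beta_crude <- mean(y[1:3])
  if (!is.finite(beta_crude) || beta_crude <= 0) {
    pk_stop("no positive signal at short lags: all-noise ACF", "platekd_fit_error")
  }
  # contiguous window from the first lag: stray late noise excursions
  # above the threshold must not enter the log fit
  below <- y <= window_frac * beta_crude
  win <- seq_len(if (any(below)) which(below)[1] - 1L else n)
  win <- win[y[win] > 0]
  if (length(win) < 6) {
    pk_stop("fit window too small: signal is noise-dominated", "platekd_fit_error")
  }
  tau <- lag_s[win]
  ly <- log(y[win])
  wt <- y[win]^2                       # delta-method weights for log-transform
  # scale tau for conditioning of the quadratic basis
  s <- max(tau)
  X <- cbind(1, tau / s, (tau / s)^2)
  fit <- stats::lm.wfit(X, ly, wt)
  cf <- fit$coefficients
  beta_hat <- exp(cf[1])
  Gamma <- -cf[2] / (2 * s)
  mu2 <- cf[3] / s^2
  flags <- character()
  if (!is.finite(Gamma) || Gamma <= 0) {
    pk_stop("cumulant fit produced a non-positive decay rate", "platekd_fit_error")
  }
  PDI <- max(0, mu2) / Gamma^2
  # SOS: residuals in g2 space over the window, noise variance from tail
  pred <- beta_hat * exp(-2 * Gamma * tau + mu2 * tau^2)
  rss <- sum((y[win] - pred)^2)
  noise_var <- stats::var(g2[tail_idx])
  SOS <- rss / max(noise_var, 1e-20)
  if (baseline < 0.997 || baseline > 1.003) flags <- c(flags, "baseline_out_of_range")
  if (SOS >= sos_threshold) flags <- c(flags, "sos_high")
  if (PDI > 0.3) flags <- c(flags, "pdi_high")
  structure(list(Gamma = unname(Gamma), beta = unname(beta_hat),
                 mu2 = unname(mu2), PDI = unname(PDI),
                 baseline = baseline, SOS = unname(SOS),
                 D = unname(Gamma / q^2), n_window = length(win),
                 flags = flags),
            class = "cumulant_fit")
}

#' @export
print.cumulant_fit <- function(x, ...) {
  cat(sprintf("<cumulant_fit> D = %.4g m^2/s (Gamma %.4g 1/s), PDI %.3f, baseline %.4f, SOS %.2f%s\n",
              x$D, x$Gamma, x$PDI, x$baseline, x$SOS,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Regularised size-distribution inversion of an ACF
#'
#' Solves the non-negative Tikhonov-regularised least-squares problem
#' `sqrt(g2 - baseline) ~ sum_j w_j * exp(-Gamma_j * tau)` on a
#' logarithmic radius grid, with `Gamma_j` from the grid radii via
#' Stokes-Einstein and the scattering vector. Weights are reported
#' normalised to 1 (scattered-intensity fractions; no Mie or volume
#' correction). Peaks are contiguous weight masses above a threshold.
#'
#' @param acf Data frame with `lag_s`, `g2`.
#' @param instrument An [instrument_config()] (supplies q, temperature,
#'   viscosity).
#' @param radius_grid_nm Radius grid in nm; default 60 log-spaced points
#'   from 0.5 to 500 nm.
#' @param reg_weight Tikhonov regularisation weight (>= 0, default 0.005).
#' @param weight_clip Cap on the heteroscedastic weight ratio between the
#'   best- and worst-determined lags (default 5).
#' @param peak_threshold Normalised weight below which grid points are
#'   considered empty when segmenting peaks (default 1e-3).
#' @param min_peak_pct Peaks carrying less than this intensity percentage
#'   are discarded (default 1): the square-root linearisation leaves a
#'   small positive noise floor at long lags that would otherwise show up
#'   as spurious slow modes.
#' @param tail_frac Trailing-lag fraction for the baseline estimate.
#' @return Object of class `size_distribution`: `radius_nm`, `weight`
#'   (non-negative, sums to 1) and `peaks`, a data frame of
#'   intensity-weighted peak radii and intensity percentages sorted by
#'   radius.
#' @export
regularized_distribution <- function(acf, instrument = instrument_config(),
                                     radius_grid_nm = NULL, reg_weight = 0.005,
                                     peak_threshold = 1e-3, min_peak_pct = 1,
                                     weight_clip = 5, tail_frac = 0.25) {
  if (reg_weight < 0) pk_stop("reg_weight must be >= 0", "platekd_fit_error")
  if (is.null(radius_grid_nm)) radius_grid_nm <- lseq(0.5, 500, 60)
  lag_s <- acf$lag_s; g2 <- acf$g2
  n <- length(lag_s)
  tail_idx <- seq.int(n - max(4L, floor(tail_frac * n)) + 1L, n)
  baseline <- mean(g2[tail_idx])
  # censor lags past the last pair of consecutive clear signal
  # excursions: the half-normal floor sqrt(max(eps, 0)) of pure baseline
  # noise would otherwise feed spurious slow modes; requiring two
  # consecutive lags above 2 sd keeps coherent low-amplitude plateaus
  # (second populations) while isolated noise spikes do not extend the
  # window
  noise_sd <- max(stats::sd(g2[tail_idx]), 1e-12)
  y <- g2 - baseline
  ex <- y > 2 * noise_sd
  pair <- which(ex[-n] & ex[-1]) + 1L
  if (!length(pair)) {
    pk_stop("no signal above the baseline noise", "platekd_fit_error")
  }
  L <- max(pair)
  if (L < n) y[(L + 1L):n] <- 0
  z <- sqrt(pmax(y, 0))
  # heteroscedastic weights: delta-method noise of sqrt(y) where the
  # signal is clear, half-normal scale where it is censored; the ratio is
  # clipped so short lags cannot completely dominate the slow-mode rows
  sd_z <- ifelse(y > noise_sd, noise_sd / (2 * sqrt(pmax(y, noise_sd))),
                 0.5 * sqrt(noise_sd))
  wt <- 1 / sd_z
  wt <- pmin(wt, weight_clip * min(wt))
  wt <- wt / mean(wt)
  q <- scattering_vector(instrument)
  Gam <- stokes_einstein_diffusion(radius_grid_nm, instrument$temperature_K,
                                   instrument$viscosity_mPas) * q^2
  A <- exp(-outer(lag_s, Gam)) * wt
  m <- length(Gam)
  Aaug <- rbind(A, sqrt(reg_weight) * diag(m))
  zaug <- c(z * wt, rep(0, m))
  sol <- tryCatch(pracma::lsqnonneg(Aaug, zaug),
                  error = function(e) pk_stop(
                    paste("regularised inversion failed:", conditionMessage(e)),
                    "platekd_fit_error"))
  u <- sol$x
  if (sum(u) <= 0) pk_stop("degenerate inversion: all weights zero", "platekd_fit_error")
  w <- u / sum(u)
  # peak segmentation: contiguous regions above the threshold; regions
  # separated by gaps of <= 2 grid points belong to the same mode (noise
  # can knock individual grid weights to zero inside a broad lobe)
  above <- w > peak_threshold
  ia <- which(above)
  if (length(ia) > 1L) {
    d <- diff(ia)
    for (k in which(d > 1L & d <= 3L)) {
      above[(ia[k] + 1L):(ia[k + 1L] - 1L)] <- TRUE
    }
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    mass <- sum(w[idx])
    peaks[[length(peaks) + 1L]] <- data.frame(
      R_H_nm = sum(w[idx] * radius_grid_nm[idx]) / mass,
      intensity_pct = 100 * mass)
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(R_H_nm = numeric(), intensity_pct = numeric())
  peaks <- peaks[peaks$intensity_pct >= min_peak_pct, , drop = FALSE]
  peaks <- peaks[order(peaks$R_H_nm), , drop = FALSE]
  structure(list(radius_nm = radius_grid_nm, weight = w, peaks = peaks,
                 baseline = baseline, reg_weight = reg_weight),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %d grid points, %d peak(s)\n",
              length(x$radius_nm), nrow(x$peaks)))
  if (nrow(x$peaks)) print(format(x$peaks, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Analyse a plate of autocorrelograms
#'
#' Runs the cumulant fit per well and, depending on `regularize`, the
#' regularised size-distribution inversion (`"auto"` runs it only for
#' wells flagged polydisperse, `PDI > 0.3`; `"always"`/`"never"` as
#' named). Failed fits are recorded, not dropped silently.
#'
#' @param x A `dls_run` from [simulate_plate()], or a long measurement
#'   data frame (`run_id`, `well`, `elapsed_time_s`, `lag_s`, `g2`).
#' @param instrument An [instrument_config()]; defaults to the run's own.
#' @param regularize `"auto"` (default), `"always"` or `"never"`.
#' @param pdi_trigger PDI above which `"auto"` runs the regularised
#'   cross-check (default 0.1, a common polydispersity cue; a
#'   second population at ~10% intensity raises the estimated PDI above
#'   this while clean wells stay near 0). The `pdi_high` quality flag at
#'   0.3 is unaffected.
#' @param ... Passed on to [cumulant_fit()].
#' @return Data frame with one row per well: `run_id`, `well`,
#'   `elapsed_time_s`, `D_m2_per_s`, `R_H_nm`, `PDI`, `SOS`, `baseline`,
#'   `n_peaks`, `peak2_RH_nm`, `peak2_intensity_pct`, `quality_flags`
#'   (semicolon-separated).
#' @export
analyze_plate <- function(x, instrument = NULL,
                          regularize = c("auto", "always", "never"),
                          pdi_trigger = 0.1, ...) {
  regularize <- match.arg(regularize)
  if (inherits(x, "dls_run")) {
    if (is.null(instrument)) instrument <- x$instrument
    meas <- x$measurements
  } else {
    meas <- x
    if (is.null(instrument)) instrument <- instrument_config()
  }
  q <- scattering_vector(instrument)
  keys <- unique(meas[, c("run_id", "well", "elapsed_time_s")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- meas$well == keys$well[i] & meas$run_id == keys$run_id[i]
    acf <- data.frame(lag_s = meas$lag_s[sel], g2 = meas$g2[sel])
    fit <- tryCatch(cumulant_fit(acf, q, ...), platekd_fit_error = function(e) e)
    if (inherits(fit, "condition")) {
      rows[[i]] <- data.frame(run_id = keys$run_id[i], well = keys$well[i],
                              elapsed_time_s = keys$elapsed_time_s[i],
                              D_m2_per_s = NA_real_, R_H_nm = NA_real_,
                              PDI = NA_real_, SOS = NA_real_, baseline = NA_real_,
                              n_peaks = NA_integer_, peak2_RH_nm = NA_real_,
                              peak2_intensity_pct = NA_real_,
                              quality_flags = "fit_failed",
                              stringsAsFactors = FALSE)
      next
    }
    flags <- fit$flags
    n_peaks <- NA_integer_; p2r <- NA_real_; p2i <- NA_real_
    if (regularize == "always" || (regularize == "auto" && fit$PDI > pdi_trigger)) {
      dist <- tryCatch(regularized_distribution(acf, instrument),
                       platekd_fit_error = function(e) NULL)
      if (!is.null(dist)) {
        n_peaks <- nrow(dist$peaks)
        if (n_peaks >= 2) {
          flags <- c(flags, "multimodal")
          p2r <- dist$peaks$R_H_nm[2]
          p2i <- dist$peaks$intensity_pct[2]
        }
      }
    }
    rows[[i]] <- data.frame(run_id = keys$run_id[i], well = keys$well[i],
                            elapsed_time_s = keys$elapsed_time_s[i],
                            D_m2_per_s = fit$D,
                            R_H_nm = stokes_einstein_radius(
                              fit$D, instrument$temperature_K,
                              instrument$viscosity_mPas),
                            PDI = fit$PDI, SOS = fit$SOS,
                            baseline = fit$baseline,
                            n_peaks = n_peaks, peak2_RH_nm = p2r,
                            peak2_intensity_pct = p2i,
                            quality_flags = paste(flags, collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
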