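# Outlier-screened estimation of the diffusion interaction parameter kD
# and the infinite-dilution hydrodynamic radius.

#' Two-sided Grubbs critical value
#'
#' `G_crit = ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t` the
#' upper `alpha / (2n)` quantile of Student's t with `n - 2` degrees of
#' freedom (extreme studentized deviate test, two-sided).
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level (default 0.05).
#' @return Critical value(s) for `G = max|x - mean| / sd`.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(all(n >= 3))
  t <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Grubbs outlier screen of replicate groups
#'
#' Applies the two-sided single-outlier Grubbs test iteratively (up to
#' `max_removals` exclusions) within each replicate group. Groups with
#' fewer than 3 values, or zero variance, pass through untested/clean.
#' Each group is first checked for normality by a Kolmogorov-Smirnov test
#' against a normal with the group's moments (advisory: screening
#' proceeds either way, the p-value is reported).
#'
#' @param values Numeric vector of observations (e.g. diffusion
#'   coefficients).
#' @param groups Grouping vector (replicate structure, typically one group
#'   per concentration); `NULL` treats all values as one group.
#' @param alpha Significance level (default 0.05).
#' @param max_removals Maximum exclusions per group (default 2).
#' @return Object of class `grubbs_screen`: `keep` (logical, original
#'   order), `report` (per group: n before/after, G statistics and
#'   critical values of each removal decision, KS normality p), `alpha`,
#'   `max_removals`.
#' @examples
#' grubbs_screen(c(1.00, 1.02, 0.98, 1.01, 5.00))$keep
#' @export
grubbs_screen <- function(values, groups = NULL, alpha = 0.05,
                          max_removals = 2L) {
  stopifnot(is.numeric(values), alpha > 0, alpha < 1, max_removals >= 0)
  if (is.null(groups)) groups <- rep(1L, length(values))
  stopifnot(length(groups) == length(values))
  keep <- rep(TRUE, length(values))
  reports <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    x <- values[idx]
    n0 <- length(x)
    ks_p <- NA_real_
    if (n0 >= 3 && stats::sd(x) > 0) {
      ks_p <- suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }
    Gs <- numeric(0); Gcrits <- numeric(0); removed <- integer(0)
    if (n0 >= 3) {
      active <- seq_along(x)
      for (r in seq_len(max_removals)) {
        nn <- length(active)
        if (nn < 3) break
        s <- stats::sd(x[active])
        if (!is.finite(s) || s == 0) break  # zero variance: no outlier
        dev <- abs(x[active] - mean(x[active]))
        G <- max(dev) / s
        Gc <- grubbs_critical(nn, alpha)
        Gs <- c(Gs, G); Gcrits <- c(Gcrits, Gc)
        if (G > Gc) {
          drop <- active[which.max(dev)]
          removed <- c(removed, drop)
          active <- setdiff(active, drop)
        } else break
      }
      keep[idx[removed]] <- FALSE
    }
    reports[[length(reports) + 1L]] <- data.frame(
      group = as.character(g), n_before = n0, n_after = n0 - length(removed),
      n_removed = length(removed),
      G = paste(signif(Gs, 6), collapse = ";"),
      G_crit = paste(signif(Gcrits, 6), collapse = ";"),
      removed_values = paste(signif(values[idx[removed]], 8), collapse = ";"),
      tested = n0 >= 3, ks_normality_p = ks_p,
      stringsAsFactors = FALSE)
  }
  structure(list(keep = keep, report = do.call(rbind, reports),
                 alpha = alpha, max_removals = max_removals),
            class = "grubbs_screen")
}

#' @export
print.grubbs_screen <- function(x, ...) {
  cat(sprintf("<grubbs_screen> %d/%d values kept (alpha %.3g)\n",
              sum(x$keep), length(x$keep), x$alpha))
  print(x$report[, c("group", "n_before", "n_after", "G", "G_crit")],
        row.names = FALSE)
  invisible(x)
}

#' Normality and variance-equality checks of replicate groups
#'
#' Kolmogorov-Smirnov test of each group against a normal with the
#' group's fitted moments, and pairwise F-tests for equality of variances
#' (F = larger variance over smaller; two-sided p).
#'
#' @param values Numeric vector.
#' @param groups Grouping vector; every group needs n >= 3.
#' @param alpha Significance level (default 0.05).
#' @return List with `normality` (per group: n, KS statistic, p) and
#'   `variance` (per pair: F, df, p, reject flag). Zero-variance groups
#'   are flagged `degenerate`, not errors.
#' @export
distribution_checks <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  gl <- split(values, groups)
  if (any(lengths(gl) < 3)) pk_stop("every group needs n >= 3", "platekd_stat_error")
  normality <- do.call(rbind, lapply(names(gl), function(g) {
    x <- gl[[g]]
    if (stats::sd(x) == 0) {
      return(data.frame(group = g, n = length(x), ks_D = NA_real_,
                        p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(group = g, n = length(x), ks_D = unname(kt$statistic),
               p = kt$p.value, degenerate = FALSE, stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(names(gl), 2, simplify = FALSE)
  variance <- do.call(rbind, lapply(pairs, function(pr) {
    x <- gl[[pr[1]]]; y <- gl[[pr[2]]]
    v1 <- stats::var(x); v2 <- stats::var(y)
    if (v1 == 0 && v2 == 0) {
      return(data.frame(group1 = pr[1], group2 = pr[2], F = NA_real_,
                        df1 = NA_integer_, df2 = NA_integer_, p = NA_real_,
                        reject = NA, degenerate = TRUE, stringsAsFactors = FALSE))
    }
    if (v1 >= v2) {
      Fv <- v1 / max(v2, .Machine$double.xmin)
      df1 <- length(x) - 1L; df2 <- length(y) - 1L
    } else {
      Fv <- v2 / v1
      df1 <- length(y) - 1L; df2 <- length(x) - 1L
    }
    p <- min(1, 2 * (1 - stats::pf(Fv, df1, df2)))
    data.frame(group1 = pr[1], group2 = pr[2], F = Fv, df1 = df1, df2 = df2,
               p = p, reject = p <= alpha, degenerate = FALSE,
               stringsAsFactors = FALSE)
  }))
  list(normality = normality, variance = variance, alpha = alpha)
}

#' Linear fit of the diffusion interaction parameter kD
#'
#' Ordinary least squares of `D = D0 * (1 + kD * c)`: fit `D = a + b * c`
#' with the concentration converted to g/mL internally, then
#' `D0 = a` and `kD = b / a` in mL/g. Pass the `keep` mask of a
#' [grubbs_screen()] to obtain the screened ("based on averaged data")
#' variant; omitting it fits the raw data.
#'
#' @param conc_mg_ml Concentrations in mg/mL.
#' @param D Diffusion coefficients, m^2/s.
#' @param keep Optional logical mask (e.g. `screen$keep`) of points to
#'   retain.
#' @param wells Optional well labels recorded against excluded points.
#' @param weights Optional OLS weights (default unweighted).
#' @return Object of class `kd_fit`: `D0` (m^2/s), `kD_mL_g`, `R2`,
#'   `n_points_used`, `se_D0`, `se_slope`, `conc_used_mg_ml`, `excluded`
#'   (data frame of dropped points).
#' @examples
#' tr <- formulation_truth("f", kD = 57, D0 = 1.3e-10)
#' cc <- c(2, 5, 10, 14)
#' fit_kd(cc, forward_diffusion(cc / 1000, tr))$kD_mL_g  # 57
#' @export
fit_kd <- function(conc_mg_ml, D, keep = NULL, wells = NULL, weights = NULL) {
  stopifnot(length(conc_mg_ml) == length(D))
  if (is.null(keep)) keep <- rep(TRUE, length(D))
  if (inherits(keep, "grubbs_screen")) keep <- keep$keep
  stopifnot(length(keep) == length(D))
  ok <- keep & is.finite(conc_mg_ml) & is.finite(D)
  c_g <- conc_mg_ml[ok] / 1000
  d <- D[ok]
  if (length(unique(c_g)) < 2) {
    pk_stop("need >= 2 distinct concentrations after screening",
            "platekd_fit_error")
  }
  fit <- if (is.null(weights)) stats::lm(d ~ c_g) else
    stats::lm(d ~ c_g, weights = weights[ok])
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (!is.finite(a) || a <= 0) {
    pk_stop("non-positive intercept D0: kD undefined", "platekd_fit_error")
  }
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit notice
  excluded <- data.frame(
    well = if (is.null(wells)) rep(NA_character_, sum(!keep)) else wells[!keep],
    conc_mg_ml = conc_mg_ml[!keep], D = D[!keep], stringsAsFactors = FALSE)
  structure(list(D0 = a, kD_mL_g = b / a, R2 = sm$r.squared,
                 n_points_used = sum(ok),
                 se_D0 = sm$coefficients[1, 2],
                 se_slope = sm$coefficients[2, 2],
                 conc_used_mg_ml = sort(unique(conc_mg_ml[ok])),
                 excluded = excluded),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> kD = %.3f mL/g, D0 = %.4g m^2/s, R2 = %.4f (n = %d, %d excluded)\n",
              x$kD_mL_g, x$D0, x$R2, x$n_points_used, nrow(x$excluded)))
  invisible(x)
}

#' Extrapolate the hydrodynamic radius to infinite dilution
#'
#' Linear fit of `R_H` against concentration restricted to a fit range
#' (default 2-7 mg/mL); the intercept is `R_H(c -> 0)`.
#'
#' @param conc_mg_ml Concentrations, mg/mL.
#' @param R_H_nm Hydrodynamic radii, nm.
#' @param range Inclusive concentration fit range, mg/mL.
#' @return List: `R_H0_nm`, `slope_nm_per_mg_ml`, `n_used`,
#'   `excluded` (points outside the range).
#' @export
extrapolate_rh0 <- function(conc_mg_ml, R_H_nm, range = c(2, 7)) {
  stopifnot(length(conc_mg_ml) == length(R_H_nm), length(range) == 2)
  inr <- conc_mg_ml >= range[1] & conc_mg_ml <= range[2] &
    is.finite(R_H_nm) & is.finite(conc_mg_ml)
  if (!any(inr)) pk_stop("no data points inside the fit range", "platekd_fit_error")
  if (length(unique(conc_mg_ml[inr])) < 2) {
    pk_stop("need >= 2 distinct concentrations inside the fit range",
            "platekd_fit_error")
  }
  fit <- stats::lm(R_H_nm[inr] ~ conc_mg_ml[inr])
  list(R_H0_nm = unname(stats::coef(fit)[1]),
       slope_nm_per_mg_ml = unname(stats::coef(fit)[2]),
       n_used = sum(inr),
       excluded = data.frame(conc_mg_ml = conc_mg_ml[!inr],
                             R_H_nm = R_H_nm[!inr]))
}

#' Estimate kD from per-well analysis results and a layout
#'
#' Joins the per-well results of [analyze_plate()] with the layout,
#' screens diffusion coefficients for outliers per concentration group
#' within each fitting unit (a formulation, or a caller-supplied well
#' grouping such as the `kd_groups` of a built-in layout), and fits kD.
#'
#' @param results Data frame from [analyze_plate()].
#' @param layout The [plate_layout()] the plate was measured with.
#' @param groups Optional named list of well-label vectors, one entry per
#'   single-kD fit; default: one fit per formulation.
#' @param screen Apply the Grubbs screen before fitting (default TRUE).
#' @param alpha,max_removals Passed to [grubbs_screen()].
#' @return Data frame with one row per fit: `fit_id`, `formulation_id`,
#'   `D0`, `kD_mL_g`, `R2`, `n_points_used`, `n_excluded`.
#' @export
estimate_kd <- function(results, layout, groups = NULL, screen = TRUE,
                        alpha = 0.05, max_removals = 2L) {
  w <- layout$wells[layout$wells$role == "sample",
                    c("well", "formulation_id", "concentration_mg_ml")]
  df <- merge(results, w, by = "well")
  df <- df[is.finite(df$D_m2_per_s), , drop = FALSE]
  if (is.null(groups)) {
    groups <- split(df$well, df$formulation_id)
  }
  rows <- lapply(names(groups), function(gid) {
    sub <- df[df$well %in% groups[[gid]], , drop = FALSE]
    if (nrow(sub) < 4) return(NULL)
    kp <- if (screen) {
      grubbs_screen(sub$D_m2_per_s, sub$concentration_mg_ml,
                    alpha = alpha, max_removals = max_removals)$keep
    } else rep(TRUE, nrow(sub))
    fit <- tryCatch(
      fit_kd(sub$concentration_mg_ml, sub$D_m2_per_s, keep = kp,
             wells = sub$well),
      platekd_fit_error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(fit_id = gid,
               formulation_id = paste(unique(sub$formulation_id), collapse = "+"),
               D0 = fit$D0, kD_mL_g = fit$kD_mL_g, R2 = fit$R2,
               n_points_used = fit$n_points_used,
               n_excluded = sum(!kp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) pk_stop("no kD fit succeeded", "platekd_fit_error")
  out
}
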