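test_that("Grubbs critical values match the closed form and tables", {
  # closed form at n = 5, alpha = 0.05 (frozen oracle value)
  expect_equal(grubbs_critical(5), 1.715037, tolerance = 1e-5)
  # published two-sided table values for n = 3..30
  for (n in as.integer(names(.grubbs_table))) {
    expect_equal(grubbs_critical(n), .grubbs_table[[as.character(n)]],
                 tolerance = 2e-3)
  }
})

test_that("Grubbs screen flags the documented outlier and spares clean data", {
  scr <- grubbs_screen(c(1.00, 1.02, 0.98, 1.01, 5.00))
  expect_equal(scr$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(scr$report$n_removed, 1)
  expect_gt(as.numeric(strsplit(scr$report$G, ";")[[1]][1]), 1.715)
  # zero-variance group: no outlier
  expect_true(all(grubbs_screen(rep(1, 5))$keep))
  # groups below n = 3 pass through untested
  scr2 <- grubbs_screen(c(1, 100), groups = c("a", "a"))
  expect_true(all(scr2$keep))
  expect_false(scr2$report$tested)
  # normality check is reported
  set.seed(1)
  scr3 <- grubbs_screen(rnorm(20))
  expect_true(is.finite(scr3$report$ks_normality_p))
})

test_that("iterative screening removes at most max_removals per group", {
  x <- c(rnorm(10, sd = 0.01), 5, -5)
  scr <- grubbs_screen(x, max_removals = 2)
  expect_lte(sum(!scr$keep), 2)
  scr1 <- grubbs_screen(x, max_removals = 1)
  expect_lte(sum(!scr1$keep), 1)
})

test_that("Grubbs decisions agree with a table-based oracle", {
  # random small datasets; borderline cases within table rounding skipped
  set.seed(1234)
  n_checked <- 0
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    x <- rnorm(n)
    if (runif(1) < 0.5) x[sample(n, 1)] <- x[sample(n, 1)] + runif(1, 2, 6)
    o <- oracle_grubbs_once(x)
    if (abs(o$G - o$crit) < 5e-3) next
    scr <- grubbs_screen(x, max_removals = 1)
    expect_equal(sum(!scr$keep) == 1, o$outlier)
    if (o$outlier) expect_false(scr$keep[o$idx])
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 900)
})

test_that("distribution checks compute KS and pairwise F-tests", {
  set.seed(7)
  g <- rep(c("a", "b"), each = 20)
  v <- c(rnorm(20, sd = 1), rnorm(20, sd = 2))
  ck <- distribution_checks(v, g)
  expect_equal(nrow(ck$normality), 2)
  expect_true(all(ck$normality$p > 0 & ck$normality$p <= 1))
  expect_equal(ck$variance$F, max(var(v[g == "b"]), var(v[g == "a"])) /
                 min(var(v[g == "b"]), var(v[g == "a"])))
  # identical groups: F = 1, p = 1
  ck2 <- distribution_checks(rep(rnorm(5), 2), rep(c("a", "b"), each = 5))
  expect_equal(ck2$variance$F, 1)
  expect_equal(ck2$variance$p, 1)
  # known power case: variance ratio 4 at n = 20 rejects at alpha = .05
  expect_lt(2 * (1 - pf(4, 19, 19)), 0.05)
  expect_error(distribution_checks(1:4, c("a", "a", "b", "b")), "n >= 3")
})

test_that("KS normality screen holds its nominal level", {
  set.seed(99)
  rejections <- mean(replicate(400, {
    x <- rnorm(50)
    # parameters fixed (known null), so the KS level is exact
    suppressWarnings(ks.test(x, "pnorm", 0, 1)$p.value) < 0.05
  }))
  expect_equal(rejections, 0.05, tolerance = 0.5)
})

test_that("kD fit is exact on noiseless forward-model data", {
  tr <- lys_truth(kD = 57)
  cc <- c(2, 5, 10, 14)
  D <- forward_diffusion(cc / 1000, tr)
  fit <- fit_kd(cc, D)
  expect_equal(fit$kD_mL_g, 57, tolerance = 1e-9)
  expect_equal(fit$D0, tr$D0, tolerance = 1e-9)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  # constant D: kD = 0 exactly
  fit0 <- fit_kd(cc, rep(1.3e-10, 4))
  expect_equal(fit0$kD_mL_g, 0)
})

test_that("kD estimate is invariant to rescaling all D values", {
  set.seed(3)
  cc <- rep(c(2, 5, 10, 14), each = 5)
  D <- forward_diffusion(cc / 1000, lys_truth()) * (1 + rnorm(20, sd = 0.01))
  f1 <- fit_kd(cc, D)
  f2 <- fit_kd(cc, D * 1e3)
  expect_equal(f2$kD_mL_g, f1$kD_mL_g, tolerance = 1e-12)
  expect_equal(f2$R2, f1$R2, tolerance = 1e-12)
})

test_that("kD fit rejects degenerate designs", {
  expect_error(fit_kd(c(5, 5, 5), c(1, 1.1, 0.9) * 1e-10), "distinct")
  # a steeply increasing D(c) extrapolates to a negative intercept
  expect_error(fit_kd(c(2, 10), c(1e-11, 1e-9)), "intercept")
})

test_that("screening a gross outlier improves the fit", {
  set.seed(11)
  cc <- rep(c(2, 5, 10, 14), each = 5)
  D <- forward_diffusion(cc / 1000, lys_truth()) * (1 + rnorm(20, sd = 0.005))
  D[7] <- D[7] * 1.5
  raw <- fit_kd(cc, D)
  scr <- grubbs_screen(D, groups = cc)
  cleaned <- fit_kd(cc, D, keep = scr, wells = sprintf("w%02d", 1:20))
  expect_false(scr$keep[7])
  expect_gt(cleaned$R2, raw$R2)
  expect_equal(cleaned$excluded$well, "w07")
  expect_equal(cleaned$kD_mL_g, 57, tolerance = 0.1)
})

test_that("infinite-dilution radius extrapolation respects the fit range", {
  cc <- c(2, 3.5, 5, 7, 8, 10, 12, 14)
  # constant radius: intercept equals the constant
  out <- extrapolate_rh0(cc, rep(1.9, 8), range = c(2, 7))
  expect_equal(out$R_H0_nm, 1.9, tolerance = 1e-12)
  expect_equal(out$n_used, 4)
  expect_equal(nrow(out$excluded), 4)
  # linear trend extrapolates to the true intercept
  out2 <- extrapolate_rh0(cc, 1.9 + 0.01 * cc, range = c(2, 7))
  expect_equal(out2$R_H0_nm, 1.9, tolerance = 1e-10)
  expect_error(extrapolate_rh0(cc, rep(1.9, 8), range = c(20, 30)), "range")
})

test_that("radius extrapolation recovers the truth from a simulated dilution series", {
  lay <- quick_layout(cc = c(2, 3.5, 5, 7), reps = 5)
  run <- simulate_plate(lay, list(lys = formulation_truth("lys", kD = 57,
                                                          R_H_nm = 1.9)),
                        seed = 17, evaporation = no_evap())
  res <- analyze_plate(run, regularize = "never")
  m <- merge(res, lay$wells[, c("well", "concentration_mg_ml")], by = "well")
  out <- extrapolate_rh0(m$concentration_mg_ml, m$R_H_nm, range = c(2, 7))
  expect_equal(out$R_H0_nm, 1.9, tolerance = 0.1)
})

test_that("estimate_kd composes analysis, screening and fitting per formulation", {
  lay <- quick_layout()
  run <- simulate_plate(lay, list(lys = lys_truth()), seed = 23,
                        evaporation = no_evap())
  res <- analyze_plate(run, regularize = "never")
  est <- estimate_kd(res, lay)
  expect_equal(nrow(est), 1)
  expect_equal(est$fit_id, "lys")
  expect_equal(est$kD_mL_g, 57, tolerance = 0.15 * 57)
  expect_lte(est$n_excluded, 2 * 4)
})

test_that("the exact simulate-analyze-fit round trip recovers kD", {
  lay <- quick_layout()
  run <- simulate_plate(lay, list(lys = lys_truth()),
                        instrument = quiet_instrument(),
                        evaporation = no_evap(), seed = 1)
  res <- analyze_plate(run, regularize = "never")
  est <- estimate_kd(res, lay, screen = FALSE)
  expect_equal(est$kD_mL_g, 57, tolerance = 1e-9)
})
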