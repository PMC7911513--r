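# Intra- and inter-plate variability statistics: coefficients of
# variation, pooled CVs, one-way and repeated-measures ANOVA, post-hoc
# t tests, and range-based span metrics for kD estimates.

#' Coefficient of variation
#'
#' `CV = 100 * SD / |mean|` with the sample (n - 1) standard deviation.
#' A zero mean is an explicit error: the CV diverges as the mean
#' approaches zero (relative precision is meaningless for a vanishing
#' quantity, as for kD values near 0 mL/g).
#'
#' @param values Numeric vector, n >= 2.
#' @return CV in percent.
#' @export
cv <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) pk_stop("CV undefined for zero mean", "platekd_stat_error")
  100 * stats::sd(values) / abs(m)
}

#' CV from a reported mean and standard deviation
#'
#' @param mean,sd Summary moments (mean must be nonzero).
#' @return CV in percent.
#' @examples
#' cv_from_moments(55.6, 0.9)  # 1.6
#' @export
cv_from_moments <- function(mean, sd) {
  if (any(mean == 0)) pk_stop("CV undefined for zero mean", "platekd_stat_error")
  100 * sd / abs(mean)
}

#' Pooled intra-plate coefficient of variation
#'
#' Pools the within-group standard deviation over all replicate groups of
#' a plate, `pooled SD = sqrt(sum((n_i - 1) * s_i^2) / sum(n_i - 1))`,
#' and reports `100 * pooled SD / grand mean`, the grand mean being the
#' mean of all values entering the pooled SD. [average_intra_cv()]
#' averages the per-run intra-plate CVs arithmetically.
#'
#' @param values Numeric vector.
#' @param groups Replicate-group labels; at least one group needs n >= 2.
#' @return Intra-plate CV in percent.
#' @export
pooled_intra_cv <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, length(values))
  gl <- split(values, groups)
  ns <- lengths(gl)
  if (all(ns < 2)) pk_stop("all groups are singletons", "platekd_stat_error")
  use <- ns >= 2
  dfree <- ns[use] - 1
  pooled_sd <- sqrt(sum(dfree * vapply(gl[use], stats::var, 1)) / sum(dfree))
  grand <- mean(unlist(gl[use]))
  if (grand == 0) pk_stop("CV undefined for zero grand mean", "platekd_stat_error")
  100 * pooled_sd / abs(grand)
}

#' @rdname pooled_intra_cv
#' @param runs Run label per value; one pooled CV is computed per run and
#'   the per-run CVs are averaged.
#' @export
average_intra_cv <- function(values, groups, runs) {
  stopifnot(length(values) == length(groups), length(values) == length(runs))
  per_run <- vapply(split(seq_along(values), runs), function(idx) {
    pooled_intra_cv(values[idx], groups[idx])
  }, 1)
  mean(per_run)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via [stats::lm()]; reports the
#' omnibus F, its critical value at `alpha`, p, and the significance flag
#' using the double rule `F > F_crit` and `p <= alpha`.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return List: `F`, `F_crit`, `p`, `df` (c(between, within)),
#'   `significant`.
#' @export
anova_oneway <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) pk_stop("need >= 2 groups", "platekd_stat_error")
  if (any(table(groups) < 2)) pk_stop("every group needs n >= 2", "platekd_stat_error")
  tab <- stats::anova(stats::lm(values ~ groups))
  Fv <- tab$`F value`[1]
  df1 <- tab$Df[1]; df2 <- tab$Df[2]
  if (!is.finite(Fv)) Fv <- 0  # zero residual AND zero between variance
  list(F = Fv, F_crit = stats::qf(1 - alpha, df1, df2),
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df = c(between = df1, within = df2),
       significant = Fv > stats::qf(1 - alpha, df1, df2) &&
         stats::pf(Fv, df1, df2, lower.tail = FALSE) <= alpha)
}

#' Repeated-measures ANOVA (two factors without replication)
#'
#' Rows are samples, columns are runs; the decomposition removes the
#' sample effect and tests the run factor against the residual
#' (sample x run) mean square.
#'
#' @param mat Complete numeric matrix, samples x runs (>= 2 each).
#' @param alpha Significance level.
#' @return List: `F` (run factor), `F_crit`, `p`, `df`, `significant`,
#'   and the full `table`.
#' @export
anova_repeated <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) pk_stop("missing cells are not allowed", "platekd_stat_error")
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    pk_stop("need >= 2 samples and >= 2 runs", "platekd_stat_error")
  }
  d <- data.frame(value = as.vector(mat),
                  sample = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                  run = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  tab <- suppressWarnings(stats::anova(stats::lm(value ~ sample + run, data = d)))
  i <- which(rownames(tab) == "run")
  Fv <- tab$`F value`[i]
  # degenerate case: run sums of squares are numerically zero (identical
  # runs give a 0/0 F from the perfect fit)
  grand <- mean(mat)
  ssc <- nrow(mat) * sum((colMeans(mat) - grand)^2)
  if (!is.finite(Fv) || ssc <= 1e-20 * max(1, grand^2)) Fv <- 0
  df1 <- tab$Df[i]; df2 <- tab$Df[nrow(tab)]
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  Fc <- stats::qf(1 - alpha, df1, df2)
  list(F = Fv, F_crit = Fc, p = p, df = c(run = df1, residual = df2),
       significant = Fv > Fc && p <= alpha, table = tab)
}

#' Post-hoc pairwise t tests
#'
#' Two-sample pooled-variance t tests for every pair of groups, with
#' multiplicity-adjusted p-values (Bonferroni by default; any
#' [stats::p.adjust()] method). Pairs with adjusted `p <= alpha` are
#' flagged as driving the omnibus rejection.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 non-singleton groups).
#' @param method Adjustment method (default `"bonferroni"`).
#' @param alpha Significance level.
#' @return Data frame per pair: `group1`, `group2`, `t`, `df`, `p`,
#'   `p_adj`, `significant`.
#' @export
posthoc_ttests <- function(values, groups, method = "bonferroni",
                           alpha = 0.05) {
  gl <- split(values, groups)
  if (length(gl) < 2) pk_stop("need >= 2 groups", "platekd_stat_error")
  if (any(lengths(gl) < 2)) pk_stop("singleton group", "platekd_stat_error")
  pairs <- utils::combn(names(gl), 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    x <- gl[[pr[1]]]; y <- gl[[pr[2]]]
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      tt <- list(statistic = c(t = 0), parameter = length(x) + length(y) - 2,
                 p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
    }
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out$significant <- out$p_adj <= alpha
  out
}

#' Span of a set of kD estimates
#'
#' Range-based dispersion metric across single-kD estimates. The primary
#' definition is `100 * (max - min) / |min|`; range over a reference
#' value and range over the mean are selectable. The definition used is
#' always reported in the result, because for sign-mixed or negative kD
#' sets the definitions diverge.
#'
#' @param kd Numeric vector of kD values (>= 2).
#' @param reference Reference kD for the `"range_over_reference"`
#'   definition (e.g. a total average).
#' @param definition One of `"range_over_min"` (default),
#'   `"range_over_reference"`, `"range_over_mean"`.
#' @return List: `span_pct`, `definition`, `kd_low`, `kd_high`.
#' @examples
#' span_kd(c(47.4, 65.9))$span_pct  # ~39.0
#' @export
span_kd <- function(kd, reference = NULL,
                    definition = c("range_over_min", "range_over_reference",
                                   "range_over_mean")) {
  definition <- match.arg(definition)
  stopifnot(length(kd) >= 2)
  rng <- max(kd) - min(kd)
  denom <- switch(definition,
                  range_over_min = abs(min(kd)),
                  range_over_reference = {
                    if (is.null(reference)) {
                      pk_stop("reference required for range_over_reference",
                              "platekd_stat_error")
                    }
                    abs(reference)
                  },
                  range_over_mean = abs(mean(kd)))
  if (denom == 0) pk_stop("zero reference for span", "platekd_stat_error")
  list(span_pct = 100 * rng / denom, definition = definition,
       kd_low = min(kd), kd_high = max(kd))
}

#' Summary table across kD-calculation approaches
#'
#' The machine twin of an approach-comparison table: for each approach
#' (a set of single-kD estimates with a known number of data points per
#' estimate), reports the average kD, SD, count, data points per single
#' kD, CV and span, plus a pooled total row across approaches.
#'
#' @param kd_by_approach Named list of numeric vectors of single-kD
#'   estimates (each >= 2 values).
#' @param points_per_kd Named list/vector parallel to `kd_by_approach`:
#'   number of data points per single kD (a string such as `"64/56"` is
#'   allowed where group sizes differ within an approach).
#' @param span_definition Passed to [span_kd()].
#' @return Data frame with rows per approach plus `"total"`: `approach`,
#'   `avg_kD_mL_g`, `sd_kD_mL_g`, `n_single_kD`, `points_per_kD`,
#'   `CV_pct`, `span_pct`.
#' @export
summarize_approaches <- function(kd_by_approach, points_per_kd,
                                 span_definition = "range_over_min") {
  stopifnot(is.list(kd_by_approach), length(kd_by_approach) >= 1)
  nm <- names(kd_by_approach)
  if (!setequal(nm, names(points_per_kd))) {
    pk_stop("kd_by_approach and points_per_kd must share names",
            "platekd_stat_error")
  }
  row1 <- function(name, kd, pts) {
    data.frame(approach = name, avg_kD_mL_g = mean(kd),
               sd_kD_mL_g = stats::sd(kd), n_single_kD = length(kd),
               points_per_kD = as.character(pts),
               CV_pct = cv(kd),
               span_pct = if (length(kd) >= 2 && max(kd) > min(kd))
                 span_kd(kd, reference = mean(kd),
                         definition = span_definition)$span_pct else 0,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(nm, function(a) row1(a, kd_by_approach[[a]],
                                      points_per_kd[[a]]))
  all_kd <- unlist(kd_by_approach, use.names = FALSE)
  total <- row1("total", all_kd, "n.a.")
  out <- rbind(do.call(rbind, rows), total)
  attr(out, "span_definition") <- span_definition
  out
}
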