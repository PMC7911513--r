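# Shared fixtures: small layouts, default truths, and independent
# brute-force oracles used to cross-check the package's statistics.

# a compact centre-well layout: one formulation, vertical replicates
quick_layout <- function(cc = c(2, 5, 10, 14), reps = 5,
                         form = "lys", start_row = 1L, start_col = 2L,
                         fill = 30) {
  rows <- start_row + seq_len(reps) - 1L
  wells <- do.call(rbind, lapply(seq_along(cc), function(j) {
    data.frame(well = format_well_address(rows, start_col + j - 1L),
               role = "sample", formulation_id = form,
               concentration_mg_ml = cc[j], replicate = seq_len(reps),
               fill_volume_ul = fill, stringsAsFactors = FALSE)
  }))
  plate_layout(wells, plate_id = "quick")
}

lys_truth <- function(kD = 57) {
  formulation_truth("lys", kD = kD, D0 = 1.30e-10)
}

quiet_instrument <- function(...) {
  instrument_config(noise_sigma0 = 0, ...)
}

no_evap <- function() evaporation_params(base_rate_per_h = 0)

# ---- independent oracles (deliberately naive implementations) ----

# one-way ANOVA by explicit sums of squares
oracle_anova_oneway <- function(values, groups) {
  gl <- split(values, groups)
  grand <- mean(values)
  ssb <- sum(vapply(gl, function(x) length(x) * (mean(x) - grand)^2, 1))
  ssw <- sum(vapply(gl, function(x) sum((x - mean(x))^2), 1))
  df1 <- length(gl) - 1
  df2 <- length(values) - length(gl)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = 1 - pf(F, df1, df2))
}

# two-factor (rows x cols) decomposition without replication
oracle_anova_repeated <- function(mat) {
  grand <- mean(mat)
  ssr <- ncol(mat) * sum((rowMeans(mat) - grand)^2)
  ssc <- nrow(mat) * sum((colMeans(mat) - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  df_c <- ncol(mat) - 1
  df_e <- (nrow(mat) - 1) * (ncol(mat) - 1)
  F <- (ssc / df_c) / (sse / df_e)
  list(F = F, p = 1 - pf(F, df_c, df_e))
}

# pooled two-sample t statistic from first principles
oracle_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

oracle_pooled_sd <- function(gl) {
  dfree <- lengths(gl) - 1
  sqrt(sum(dfree * vapply(gl, var, 1)) / sum(dfree))
}

# single-pass two-sided Grubbs decision against published critical values
# (standard two-sided table, alpha = 0.05)
.grubbs_table <- c(`3` = 1.1543, `4` = 1.4812, `5` = 1.7150, `6` = 1.8871,
                   `7` = 2.0200, `8` = 2.1266, `9` = 2.2150, `10` = 2.2900,
                   `11` = 2.3547, `12` = 2.4116, `13` = 2.4620, `14` = 2.5073,
                   `15` = 2.5483, `16` = 2.5857, `17` = 2.6200, `18` = 2.6516,
                   `19` = 2.6809, `20` = 2.7082, `21` = 2.7336, `22` = 2.7573,
                   `23` = 2.7795, `24` = 2.8004, `25` = 2.8202, `26` = 2.8388,
                   `27` = 2.8564, `28` = 2.8730, `29` = 2.8889, `30` = 2.9040)

oracle_grubbs_once <- function(x) {
  n <- length(x)
  stopifnot(n >= 3, n <= 30)
  if (sd(x) == 0) return(list(outlier = FALSE, G = 0, crit = .grubbs_table[[as.character(n)]]))
  dev <- abs(x - mean(x))
  G <- max(dev) / sd(x)
  crit <- .grubbs_table[[as.character(n)]]
  list(outlier = G > crit, G = G, crit = crit, idx = which.max(dev))
}
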