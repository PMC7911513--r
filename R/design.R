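# Screening plate designs: recommended API-efficient layouts, encodings
# of the experimental layouts and approach well-groupings, exact API
# budgets, and Monte-Carlo design evaluation.

# assemble a wells data.frame row block
.wells_df <- function(row, col, role = "sample", formulation_id = "",
                      conc = 0, replicate = 1L, fill = 30) {
  n <- max(length(row), length(col))
  data.frame(well = format_well_address(rep_len(row, n), rep_len(col, n)),
             role = rep_len(role, n),
             formulation_id = rep_len(formulation_id, n),
             concentration_mg_ml = rep_len(conc, n),
             replicate = rep_len(replicate, n),
             fill_volume_ul = rep_len(fill, n),
             stringsAsFactors = FALSE)
}

#' Recommended screening plate designs
#'
#' Two API-efficient 384-well designs for kD screening. Both exclude the
#' 76 edge wells, place low concentrations on upper rows, use vertical
#' replicates and pass [validate_layout()] with zero findings.
#'
#' * `"low_risk"`: 8 formulations, concentration series 2/4/6/8/10 mg/mL
#'   arranged horizontally, 6 vertical replicates each: 240 sample wells
#'   in two six-row bands (first well B3, last M22).
#' * `"high_quantity"`: 20 formulations, series 2/5/10 mg/mL, 5
#'   replicates: 300 sample wells (first well B2). The 14 non-edge rows
#'   cannot host three aligned five-row concentration bands, so the
#'   fifth replicate of the highest concentration is placed in two spare
#'   upper-row columns; the packing is deterministic and documented.
#'
#' @param kind `"low_risk"` or `"high_quantity"`.
#' @param n_formulations,concentrations,replicates Optional overrides of
#'   the defaults; overrides must keep the design inside the non-edge
#'   block.
#' @param fill_volume_ul Fill volume per well (default 30).
#' @param buffer_fill If `TRUE`, edge rows A and P are filled with
#'   placebo (buffer) wells for thermal insulation of the neighbours.
#' @param plate_id Plate id of the returned layout.
#' @return A [plate_layout()].
#' @examples
#' lay <- recommended_design("low_risk")
#' sum(lay$wells$role == "sample")  # 240
#' @export
recommended_design <- function(kind = c("low_risk", "high_quantity"),
                               n_formulations = NULL, concentrations = NULL,
                               replicates = NULL, fill_volume_ul = 30,
                               buffer_fill = FALSE, plate_id = NULL) {
  kind <- match.arg(kind)
  if (kind == "low_risk") {
    nf <- if (is.null(n_formulations)) 8L else as.integer(n_formulations)
    cc <- if (is.null(concentrations)) c(2, 4, 6, 8, 10) else sort(concentrations)
    nr <- if (is.null(replicates)) 6L else as.integer(replicates)
    forms_per_strip <- floor(22 / length(cc))
    n_strips <- ceiling(nf / forms_per_strip)
    if (forms_per_strip < 1 || n_strips * nr > 14) {
      pk_stop("overrides exceed the non-edge capacity of the plate",
              "platekd_layout_error")
    }
    used_cols <- min(nf, forms_per_strip) * length(cc)
    col0 <- 1L + floor((22 - used_cols) / 2)
    blocks <- list()
    for (f in seq_len(nf)) {
      strip <- (f - 1L) %/% forms_per_strip
      k <- (f - 1L) %% forms_per_strip
      rows <- 1L + strip * nr + seq_len(nr) - 1L
      for (j in seq_along(cc)) {
        blocks[[length(blocks) + 1L]] <- .wells_df(
          rows, col0 + k * length(cc) + j - 1L,
          formulation_id = sprintf("F%02d", f), conc = cc[j],
          replicate = seq_len(nr), fill = fill_volume_ul)
      }
    }
  } else {
    nf <- if (is.null(n_formulations)) 20L else as.integer(n_formulations)
    cc <- if (is.null(concentrations)) c(2, 5, 10) else sort(concentrations)
    nr <- if (is.null(replicates)) 5L else as.integer(replicates)
    if (!(nf == 20L && length(cc) == 3L && nr == 5L)) {
      # general fallback: aligned bands, one concentration per band
      if (length(cc) * nr > 14 || nf > 22) {
        pk_stop("overrides exceed the non-edge capacity of the plate",
                "platekd_layout_error")
      }
      blocks <- list()
      for (j in seq_along(cc)) {
        rows <- 1L + (j - 1L) * nr + seq_len(nr) - 1L
        for (f in seq_len(nf)) {
          blocks[[length(blocks) + 1L]] <- .wells_df(
            rows, f, formulation_id = sprintf("F%02d", f), conc = cc[j],
            replicate = seq_len(nr), fill = fill_volume_ul)
        }
      }
    } else {
      blocks <- list()
      for (j in 1:2) {            # 2 and 5 mg/mL: aligned 5-row bands B-F, G-K
        rows <- 1L + (j - 1L) * 5L + 0:4
        for (f in seq_len(20L)) {
          blocks[[length(blocks) + 1L]] <- .wells_df(
            rows, f, formulation_id = sprintf("F%02d", f), conc = cc[j],
            replicate = 1:5, fill = fill_volume_ul)
        }
      }
      for (f in seq_len(20L)) {   # 10 mg/mL: 4 replicates in rows L-O ...
        blocks[[length(blocks) + 1L]] <- .wells_df(
          11:14, f, formulation_id = sprintf("F%02d", f), conc = cc[3],
          replicate = 1:4, fill = fill_volume_ul)
      }
      for (f in seq_len(20L)) {   # ... 5th replicate in spare columns 22/23
        blocks[[length(blocks) + 1L]] <- .wells_df(
          if (f <= 10L) f else f - 10L, if (f <= 10L) 21L else 22L,
          formulation_id = sprintf("F%02d", f), conc = cc[3],
          replicate = 5L, fill = fill_volume_ul)
      }
    }
  }
  wells <- do.call(rbind, blocks)
  if (buffer_fill) {
    edge_rows <- c(0L, 15L)
    buf <- .wells_df(rep(edge_rows, each = PLATE_COLS),
                     rep(0:(PLATE_COLS - 1L), 2L), role = "placebo",
                     formulation_id = "", conc = 0, replicate = 1L,
                     fill = fill_volume_ul)
    wells <- rbind(wells, buf)
  }
  plate_layout(wells,
               plate_id = if (is.null(plate_id)) kind else plate_id,
               metadata = list(design = kind))
}

#' Exact API budget of a layout
#'
#' Mass per well is `concentration (mg/mL) * fill volume (mL)`; control
#' and placebo wells carry no API. The arithmetic is plain sums of exact
#' products, so totals are reproducible to full double precision.
#'
#' @param layout A [plate_layout()].
#' @return List with `total_mg`, `per_formulation` (data frame) and
#'   `per_well` (data frame).
#' @examples
#' api_budget(recommended_design("low_risk"))$total_mg  # 43.2
#' @export
api_budget <- function(layout) {
  w <- layout$wells
  smp <- w[w$role == "sample", , drop = FALSE]
  if (nrow(smp) && anyNA(smp$fill_volume_ul)) {
    pk_stop("sample wells with missing fill volume", "platekd_layout_error")
  }
  per_well <- data.frame(well = smp$well, formulation_id = smp$formulation_id,
                         mass_mg = smp$concentration_mg_ml *
                           smp$fill_volume_ul / 1000,
                         stringsAsFactors = FALSE)
  per_form <- if (nrow(per_well)) {
    stats::aggregate(mass_mg ~ formulation_id, data = per_well, FUN = sum)
  } else data.frame(formulation_id = character(), mass_mg = numeric())
  list(total_mg = sum(per_well$mass_mg), per_formulation = per_form,
       per_well = per_well)
}

# clockwise perimeter well sequences (0-based coords), outer ring then
# the second ring: 76 + 68 = 144 wells
.perimeter_sequence <- function() {
  ring <- function(r0, r1, c0, c1) {
    rbind(cbind(r0, c0:c1),
          cbind((r0 + 1):(r1 - 1), c1),
          cbind(r1, c1:c0),
          cbind((r1 - 1):(r0 + 1), c0))
  }
  rbind(ring(0L, 15L, 0L, 23L), ring(1L, 14L, 1L, 22L))
}

# vertical-replicate concentration blocks in a rows x cols rectangle:
# conc j occupies cols_per_conc adjacent columns over all rows
.block_vertical <- function(rows, cols, cc, cols_per_conc, formulation_id,
                            fill) {
  out <- list()
  for (j in seq_along(cc)) {
    cj <- cols[(j - 1L) * cols_per_conc + seq_len(cols_per_conc)]
    grid <- expand.grid(row = rows, col = cj)
    out[[j]] <- .wells_df(grid$row, grid$col, formulation_id = formulation_id,
                          conc = cc[j], replicate = seq_len(nrow(grid)),
                          fill = fill)
  }
  do.call(rbind, out)
}

#' Built-in experimental layouts and approach well-groupings
#'
#' Encodings of the experimental 384-well layouts used for the
#' variability studies, and the A-H well-grouping "approaches" used to
#' compare kD-calculation strategies. Exact well positions for the
#' approaches are a deterministic interpretation reconstructed from the
#' reported counts (number of single kD fits, data points per fit,
#' edge/centre character, replicate orientation); the grouping sizes are
#' exact.
#'
#' * `"lysozyme-intra"`: two lysozyme batches with/without 400 mM NaCl,
#'   eight-step horizontal concentration series (2-14 mg/mL), five
#'   replicates, packed row-major from A1.
#' * `"lysozyme-inter"`: four-step series (2/5/10/14 mg/mL), five
#'   replicates, four formulations at three plate positions
#'   (upper/middle/bottom bands); with three runs this yields nine
#'   single-kD fits per batch. Controls in row P.
#' * `"Ac-A"` .. `"Ac-H"`, `"Ph-A"` .. `"Ph-H"`: peptide plates
#'   (acetate/phosphate buffer), five-step series 2/4/6/8/10 mg/mL.
#'   Groupings: A = 8x30 points mixed edge+centre; B = 2x120 centre;
#'   C, D = 64/64/56/56 with the edge-flanked pairs first; E = 4x30
#'   perimeter-heavy; F = 4x30 centre; G = 4x60 horizontal replicates;
#'   H = 4x60 vertical replicates.
#'
#' The returned layout carries attributes `kd_groups` (named list of
#' well-label vectors, one per single-kD fit), `points_per_kd`, and for
#' `"lysozyme-inter"` also `n_positions` and `n_runs`.
#'
#' @param name Layout name (see above).
#' @param fill_volume_ul Fill volume (default 30).
#' @return A [plate_layout()] with grouping attributes.
#' @export
builtin_layout <- function(name, fill_volume_ul = 30) {
  fill <- fill_volume_ul
  if (name == "lysozyme-intra") {
    cc <- c(2, 3.5, 5, 7, 8, 10, 12, 14)
    forms <- c("Lys2243", "Lys2243+NaCl", "Lys5161", "Lys5161+NaCl")
    wells <- list(); groups <- list()
    pos <- 0L
    for (f in forms) {
      labs <- character(0)
      for (r in 1:5) {
        for (j in seq_along(cc)) {
          row <- pos %/% 24L; col <- pos %% 24L
          wells[[length(wells) + 1L]] <- .wells_df(
            row, col, formulation_id = f, conc = cc[j], replicate = r,
            fill = fill)
          labs <- c(labs, format_well_address(row, col))
          pos <- pos + 1L
        }
      }
      groups[[f]] <- labs
    }
    ctrl <- .wells_df(15L, 0:7, role = "control", formulation_id = "",
                      conc = 0, replicate = 1L, fill = fill)
    lay <- plate_layout(rbind(do.call(rbind, wells), ctrl),
                        plate_id = "lysozyme-intra")
    attr(lay, "kd_groups") <- groups
    attr(lay, "points_per_kd") <- stats::setNames(rep("40", 4), names(groups))
    return(lay)
  }
  if (name == "lysozyme-inter") {
    cc <- c(2, 5, 10, 14)
    forms <- c("Lys2243", "Lys2243+NaCl", "Lys5161", "Lys5161+NaCl")
    band_start <- c(0L, 5L, 10L)   # upper, middle, bottom position bands
    wells <- list(); groups <- list()
    for (p in 1:3) {
      pos <- band_start[p] * 24L
      for (f in forms) {
        labs <- character(0)
        for (r in 1:5) {
          for (j in seq_along(cc)) {
            row <- pos %/% 24L; col <- pos %% 24L
            wells[[length(wells) + 1L]] <- .wells_df(
              row, col, formulation_id = f, conc = cc[j], replicate = r,
              fill = fill)
            labs <- c(labs, format_well_address(row, col))
            pos <- pos + 1L
          }
        }
        groups[[sprintf("%s.pos%d", f, p)]] <- labs
      }
    }
    ctrl <- .wells_df(15L, 0:7, role = "control", formulation_id = "",
                      conc = 0, replicate = 1L, fill = fill)
    lay <- plate_layout(rbind(do.call(rbind, wells), ctrl),
                        plate_id = "lysozyme-inter")
    attr(lay, "kd_groups") <- groups
    attr(lay, "points_per_kd") <- stats::setNames(rep("20", length(groups)),
                                                  names(groups))
    attr(lay, "n_positions") <- 3L
    attr(lay, "n_runs") <- 3L
    return(lay)
  }
  m <- regmatches(name, regexec("^(Ac|Ph)-([A-H])$", name))[[1]]
  if (length(m) != 3L) pk_stop(sprintf("unknown layout name '%s'", name))
  form <- if (m[2] == "Ac") "peptide12-acetate" else "peptide12-phosphate"
  appr <- m[3]
  cc <- c(2, 4, 6, 8, 10)
  per <- .perimeter_sequence()
  # assign a concentration pattern to a sequence of coords
  seq_block <- function(coords, counts) {
    stopifnot(nrow(coords) == sum(counts))
    out <- list(); at <- 0L
    for (j in seq_along(cc)) {
      idx <- at + seq_len(counts[j]); at <- at + counts[j]
      out[[j]] <- .wells_df(coords[idx, 1], coords[idx, 2],
                            formulation_id = form, conc = cc[j],
                            replicate = seq_len(counts[j]), fill = fill)
    }
    do.call(rbind, out)
  }
  blocks <- list(); groups <- list()
  add_group <- function(gname, df) {
    blocks[[length(blocks) + 1L]] <<- df
    groups[[gname]] <<- df$well
  }
  rowmajor <- function(n, start = 0L) {
    p <- start + seq_len(n) - 1L
    cbind(p %/% 24L, p %% 24L)
  }
  if (appr == "A") {          # 8 x 30, mixed edge + centre, packed row-major
    for (g in 1:8) add_group(paste0("kD", g),
                             seq_block(rowmajor(30L, (g - 1L) * 30L),
                                       rep(6L, 5)))
    pts <- "30"
  } else if (appr == "B") {   # 2 x 120, centre block, 24 vertical replicates
    add_group("kD1", .block_vertical(2:13, 2:11, cc, 2L, form, fill))
    add_group("kD2", .block_vertical(2:13, 12:21, cc, 2L, form, fill))
    groups <- lapply(blocks, function(b) b$well)
    names(groups) <- c("kD1", "kD2")
    pts <- "120"
  } else if (appr %in% c("C", "D")) {
    # kD1/kD2: 64 points each along the two perimeter rings (lowest and
    # highest concentrations flanking); kD3/kD4: 56-point centre blocks
    off <- if (appr == "C") 0L else 36L   # D: rotated variant
    idx <- ((off + seq_len(128L) - 1L) %% 144L) + 1L
    add_group("kD1", seq_block(per[idx[1:64], , drop = FALSE],
                               c(12L, 12L, 16L, 12L, 12L)))
    add_group("kD2", seq_block(per[idx[65:128], , drop = FALSE],
                               c(12L, 12L, 16L, 12L, 12L)))
    ctr_rows <- if (appr == "C") list(4:7, 8:11) else list(3:6, 9:12)
    for (g in 1:2) {
      grid <- expand.grid(row = ctr_rows[[g]], col = 4:17)
      add_group(paste0("kD", g + 2L),
                seq_block(as.matrix(grid)[, c("row", "col")],
                          c(12L, 12L, 8L, 12L, 12L)))
    }
    pts <- "64/56"
  } else if (appr == "E") {   # 4 x 30, perimeter-heavy
    for (g in 1:4) add_group(paste0("kD", g),
                             seq_block(per[(g - 1L) * 30L + 1:30, , drop = FALSE],
                                       rep(6L, 5)))
    pts <- "30"
  } else if (appr == "F") {   # 4 x 30, centre, vertical replicates
    for (g in 1:4) {
      add_group(paste0("kD", g),
                .block_vertical(5:10, 2:6 + (g - 1L) * 5L, cc, 1L, form, fill))
    }
    pts <- "30"
  } else if (appr == "G") {   # 4 x 60, horizontal replicates (12 per row)
    corners <- list(c(1L, 0L), c(1L, 12L), c(6L, 0L), c(6L, 12L))
    for (g in 1:4) {
      r0 <- corners[[g]][1]; c0 <- corners[[g]][2]
      out <- list()
      for (j in seq_along(cc)) {
        out[[j]] <- .wells_df(r0 + j - 1L, c0 + 0:11, formulation_id = form,
                              conc = cc[j], replicate = 1:12, fill = fill)
      }
      add_group(paste0("kD", g), do.call(rbind, out))
    }
    pts <- "60"
  } else {                    # H: 4 x 60, vertical replicates (12 per column)
    for (g in 1:4) {
      add_group(paste0("kD", g),
                .block_vertical(1:12, 1:5 + (g - 1L) * 5L, cc, 1L, form, fill))
    }
    pts <- "60"
  }
  lay <- plate_layout(do.call(rbind, blocks), plate_id = name)
  attr(lay, "kd_groups") <- groups
  attr(lay, "points_per_kd") <- stats::setNames(rep(pts, length(groups)),
                                                names(groups))
  lay
}

#' Monte-Carlo evaluation of a plate design
#'
#' Repeatedly simulates a plate run under the given truths and
#' instrument/evaporation parameters, analyses it, fits kD per grouping
#' unit, and summarises the distribution of the estimates: the expected
#' bias and coefficient of variation of kD a design delivers.
#'
#' @param layout A [plate_layout()]; its `kd_groups` attribute (if any)
#'   defines the fitting units, otherwise one fit per formulation.
#' @param truths Named list of [formulation_truth()] objects.
#' @param instrument,evaporation,anomalies Simulator parameters.
#' @param n_sims Number of simulated plates (>= 2).
#' @param seed Integer master seed; per-simulation seeds are derived
#'   deterministically.
#' @param screen Apply the Grubbs screen in each fit (default TRUE).
#' @param dwell,order Acquisition schedule parameters.
#' @return Data frame, one row per formulation: `formulation_id`,
#'   `kD_true`, `mean_kD`, `sd_kD`, `cv_pct`, `bias_pct`, `n_estimates`.
#'   The per-fit estimates are attached as attribute `estimates`.
#' @export
monte_carlo_design_eval <- function(layout, truths,
                                    instrument = instrument_config(),
                                    evaporation = evaporation_params(),
                                    anomalies = anomaly_spec(),
                                    n_sims = 100, seed = 1, screen = TRUE,
                                    dwell = 75, order = "row-major") {
  stopifnot(n_sims >= 2)
  groups <- attr(layout, "kd_groups")
  ests <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    si <- (as.integer(seed) + i * 9973L) %% 2147483587L
    run <- simulate_plate(layout, truths, instrument = instrument,
                          evaporation = evaporation, anomalies = anomalies,
                          seed = si, dwell = dwell, order = order,
                          run_id = sprintf("sim%04d", i))
    res <- analyze_plate(run, regularize = "never")
    est <- estimate_kd(res, layout, groups = groups, screen = screen)
    est$sim <- i
    ests[[i]] <- est
  }
  est <- do.call(rbind, ests)
  out <- do.call(rbind, lapply(split(est, est$formulation_id), function(s) {
    kd_true <- if (s$formulation_id[1] %in% names(truths)) {
      truths[[s$formulation_id[1]]]$kD
    } else NA_real_
    data.frame(formulation_id = s$formulation_id[1], kD_true = kd_true,
               mean_kD = mean(s$kD_mL_g), sd_kD = stats::sd(s$kD_mL_g),
               cv_pct = if (mean(s$kD_mL_g) != 0)
                 100 * stats::sd(s$kD_mL_g) / abs(mean(s$kD_mL_g)) else NA_real_,
               bias_pct = if (!is.na(kd_true) && kd_true != 0)
                 100 * (mean(s$kD_mL_g) - kd_true) / abs(kd_true) else NA_real_,
               n_estimates = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "estimates") <- est
  out
}
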