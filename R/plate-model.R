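# 384-well plate geometry: addressing, position classes, layouts, schedules.

PLATE_ROWS <- 16L
PLATE_COLS <- 24L

.row_letters <- LETTERS[1:16]

#' Parse 384-well plate well labels
#'
#' Converts display labels such as `"B3"` into 0-based row/column indices.
#' Rows run A-P (0-15), columns 1-24 (0-23). Parsing is the exact inverse
#' of [format_well_address()].
#'
#' @param label Character vector of well labels (letter A-P followed by a
#'   column number 1-24).
#' @return A data frame with integer columns `row` and `col` (0-based) and
#'   the normalised `well` label.
#' @examples
#' parse_well_address(c("A1", "B3", "P24"))
#' @export
parse_well_address <- function(label) {
  label <- toupper(trimws(as.character(label)))
  m <- regmatches(label, regexec("^([A-Z])([0-9]{1,2})$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    pk_stop(sprintf("malformed well label(s): %s",
                    paste(label[bad], collapse = ", ")),
            "platekd_address_error")
  }
  row <- match(vapply(m, `[`, "", 2L), .row_letters) - 1L
  col <- as.integer(vapply(m, `[`, "", 3L)) - 1L
  if (anyNA(row) || any(col < 0L | col >= PLATE_COLS)) {
    off <- is.na(row) | col < 0L | col >= PLATE_COLS
    pk_stop(sprintf("well label(s) outside the A1-P24 grid: %s",
                    paste(label[off], collapse = ", ")),
            "platekd_address_error")
  }
  data.frame(well = paste0(.row_letters[row + 1L], col + 1L),
             row = row, col = col, stringsAsFactors = FALSE)
}

#' Format 0-based well coordinates as display labels
#'
#' @param row,col Integer vectors of 0-based row (0-15) and column (0-23)
#'   indices.
#' @return Character vector of labels, e.g. `"B3"`.
#' @export
format_well_address <- function(row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | row >= PLATE_ROWS) || any(col < 0L | col >= PLATE_COLS)) {
    pk_stop("row must be in 0-15 and col in 0-23", "platekd_address_error")
  }
  paste0(.row_letters[row + 1L], col + 1L)
}

#' Classify plate positions as edge/centre and by row band
#'
#' A well is an edge well iff it lies in row A or P or column 1 or 24 (the
#' 76-well perimeter of a 384-well plate). Row bands split the plate into
#' upper/middle/bottom thirds; the defaults are rows A-E, F-K and L-P.
#'
#' @param well Character vector of well labels, or a data frame carrying
#'   `row`/`col` columns (0-based).
#' @param bands Integer vector of length 2: 0-based row indices at which
#'   the middle and bottom bands start. Default `c(5, 11)` (F and L).
#' @return Data frame with columns `well`, `row`, `col`, `edge` (logical)
#'   and `band` (factor upper/middle/bottom).
#' @examples
#' classify_position(c("A1", "H12", "P3"))
#' @export
classify_position <- function(well, bands = c(5L, 11L)) {
  addr <- if (is.data.frame(well)) well else parse_well_address(well)
  stopifnot(length(bands) == 2L, bands[1] > 0L, bands[2] > bands[1])
  edge <- addr$row == 0L | addr$row == PLATE_ROWS - 1L |
    addr$col == 0L | addr$col == PLATE_COLS - 1L
  band <- cut(addr$row, breaks = c(-1L, bands[1] - 1L, bands[2] - 1L, PLATE_ROWS),
              labels = c("upper", "middle", "bottom"))
  data.frame(well = addr$well, row = addr$row, col = addr$col,
             edge = edge, band = band, stringsAsFactors = FALSE)
}

#' Construct a plate layout
#'
#' A plate layout assigns a role, formulation, concentration, replicate
#' number and fill volume to each occupied well of a 384-well plate.
#'
#' @param wells Data frame with columns `well` (label), `role` (one of
#'   sample/control/placebo/empty), `formulation_id`, `concentration_mg_ml`,
#'   `replicate`, `fill_volume_ul`.
#' @param plate_id Plate identifier string.
#' @param metadata Optional named list of free-form metadata.
#' @param fill_volume_range Permitted working volume in microlitres;
#'   default 5-40 (the plate manufacturer's working range).
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(wells, plate_id = "plate1", metadata = list(),
                         fill_volume_range = c(5, 40)) {
  need <- c("well", "role", "formulation_id", "concentration_mg_ml",
            "replicate", "fill_volume_ul")
  miss <- setdiff(need, names(wells))
  if (length(miss)) pk_stop(paste("layout missing columns:", paste(miss, collapse = ", ")))
  addr <- parse_well_address(wells$well)
  wells$well <- addr$well
  wells$row <- addr$row
  wells$col <- addr$col
  if (anyDuplicated(wells$well)) {
    pk_stop(sprintf("duplicate well address(es): %s",
                    paste(unique(wells$well[duplicated(wells$well)]), collapse = ", ")),
            "platekd_layout_error")
  }
  if (!all(wells$role %in% c("sample", "control", "placebo", "empty"))) {
    pk_stop("role must be one of sample/control/placebo/empty", "platekd_layout_error")
  }
  smp <- wells$role == "sample"
  if (any(smp & (is.na(wells$concentration_mg_ml) | wells$concentration_mg_ml <= 0))) {
    pk_stop("sample wells require concentration > 0", "platekd_layout_error")
  }
  if (any(smp & (is.na(wells$formulation_id) | !nzchar(wells$formulation_id)))) {
    pk_stop("sample wells require a nonempty formulation_id", "platekd_layout_error")
  }
  occ <- wells$role != "empty"
  vol <- wells$fill_volume_ul[occ]
  if (any(!is.na(vol) & (vol < fill_volume_range[1] | vol > fill_volume_range[2]))) {
    pk_stop(sprintf("fill volumes outside the %g-%g uL working range",
                    fill_volume_range[1], fill_volume_range[2]),
            "platekd_layout_error")
  }
  structure(list(plate_id = plate_id, wells = wells, metadata = metadata),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  w <- x$wells
  cat(sprintf("<plate_layout '%s'>: %d occupied wells (%d sample, %d control, %d placebo)\n",
              x$plate_id, sum(w$role != "empty"), sum(w$role == "sample"),
              sum(w$role == "control"), sum(w$role == "placebo")))
  if (any(w$role == "sample")) {
    cat(sprintf("  formulations: %s\n",
                paste(unique(w$formulation_id[w$role == "sample"]), collapse = ", ")))
    cat(sprintf("  concentrations (mg/mL): %s\n",
                paste(sort(unique(w$concentration_mg_ml[w$role == "sample"])), collapse = ", ")))
  }
  invisible(x)
}

#' Acquisition schedule of a plate run
#'
#' Maps every occupied well to the elapsed time at which its DLS
#' measurement starts, assuming the reader visits wells sequentially with
#' a fixed per-well dwell. Default reading order is row-major
#' (A1..A24, B1..), matching a first well in the upper row and a last well
#' in the bottom row; `"column-major"` is available as an option.
#'
#' @param layout A [plate_layout()].
#' @param order `"row-major"` (default) or `"column-major"`.
#' @param dwell Per-well dwell time in seconds (default 75).
#' @return Data frame `well`, `elapsed_time_s`, with attributes
#'   `per_well_dwell` and `duration_s` (first-to-last duration,
#'   `n_wells * dwell`).
#' @examples
#' lay <- recommended_design("low_risk")
#' sched <- acquisition_schedule(lay)
#' attr(sched, "duration_s") / 3600  # hours
#' @export
acquisition_schedule <- function(layout, order = c("row-major", "column-major"),
                                 dwell = 75) {
  order <- match.arg(order)
  stopifnot(dwell > 0)
  w <- layout$wells[layout$wells$role != "empty", , drop = FALSE]
  if (nrow(w) == 0L) pk_stop("layout has no occupied wells", "platekd_layout_error")
  o <- if (order == "row-major") order(w$row, w$col) else order(w$col, w$row)
  w <- w[o, , drop = FALSE]
  sched <- data.frame(well = w$well,
                      elapsed_time_s = (seq_len(nrow(w)) - 1) * dwell,
                      stringsAsFactors = FALSE)
  attr(sched, "per_well_dwell") <- dwell
  attr(sched, "duration_s") <- nrow(w) * dwell
  sched
}

#' Validate a layout against screening design rules
#'
#' Checks a layout against the design rules supported by the variability
#' findings: no samples in edge wells, at least `min_replicates` replicates
#' per formulation/concentration, at least `min_conc_steps` concentration
#' steps per formulation, and no lower concentration of a formulation
#' positioned below a higher one (evaporation is worst for dilute samples
#' measured late, i.e. in bottom rows).
#'
#' @param layout A [plate_layout()].
#' @param min_replicates Minimum replicates per concentration (default 5).
#' @param min_conc_steps Minimum distinct concentration steps (default 3).
#' @return Data frame of findings with columns `code` and `message`;
#'   zero rows for a compliant layout.
#' @export
validate_layout <- function(layout, min_replicates = 5L, min_conc_steps = 3L) {
  w <- layout$wells
  findings <- list()
  add <- function(code, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      code = code, message = message, stringsAsFactors = FALSE)
  }
  smp <- w[w$role == "sample", , drop = FALSE]
  if (nrow(smp)) {
    pos <- classify_position(smp)
    if (any(pos$edge)) {
      add("edge_wells_used",
          sprintf("%d sample well(s) in edge rows/columns (e.g. %s)",
                  sum(pos$edge), pos$well[which(pos$edge)[1]]))
    }
    reps <- stats::aggregate(replicate ~ formulation_id + concentration_mg_ml,
                             data = smp, FUN = length)
    low <- reps[reps$replicate < min_replicates, , drop = FALSE]
    if (nrow(low)) {
      add("replicates_lt_min",
          sprintf("replicates < %d for %d formulation/concentration group(s)",
                  min_replicates, nrow(low)))
    }
    steps <- tapply(smp$concentration_mg_ml, smp$formulation_id,
                    function(x) length(unique(x)))
    if (any(steps < min_conc_steps)) {
      add("conc_steps_lt_min",
          sprintf("fewer than %d concentration steps for formulation(s): %s",
                  min_conc_steps, paste(names(steps)[steps < min_conc_steps], collapse = ", ")))
    }
    # low concentrations should sit on upper rows (measured earlier)
    for (f in unique(smp$formulation_id)) {
      sf <- smp[smp$formulation_id == f, ]
      mr <- tapply(sf$row, sf$concentration_mg_ml, mean)
      cc <- as.numeric(names(mr))
      oc <- order(cc)
      if (length(cc) > 1 && any(diff(mr[oc]) < -1e-9)) {
        add("low_conc_below_high",
            sprintf("formulation %s: a lower concentration sits below a higher one", f))
        break
      }
    }
  }
  if (length(findings)) do.call(rbind, findings) else
    data.frame(code = character(), message = character(), stringsAsFactors = FALSE)
}

#' Read or write a plate-map CSV
#'
#' Plate maps are UTF-8 CSV files with one row per occupied well and
#' columns `well`, `role`, `formulation_id`, `concentration_mg_per_ml`,
#' `replicate`, `fill_volume_ul`. Layouts round-trip losslessly.
#'
#' @param path File path.
#' @param plate_id Plate id to attach on read (default: file name).
#' @return `read_plate_map()` returns a [plate_layout()];
#'   `write_plate_map()` returns `path` invisibly.
#' @export
read_plate_map <- function(path, plate_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("well", "role", "formulation_id", "concentration_mg_per_ml",
            "replicate", "fill_volume_ul")
  miss <- setdiff(need, names(df))
  if (length(miss)) pk_stop(paste("plate map missing columns:", paste(miss, collapse = ", ")))
  df$formulation_id <- as.character(df$formulation_id)
  df$formulation_id[is.na(df$formulation_id)] <- ""
  plate_layout(
    data.frame(well = df$well, role = df$role,
               formulation_id = df$formulation_id,
               concentration_mg_ml = df$concentration_mg_per_ml,
               replicate = df$replicate, fill_volume_ul = df$fill_volume_ul,
               stringsAsFactors = FALSE),
    plate_id = if (is.null(plate_id)) sub("\\.csv$", "", basename(path)) else plate_id)
}

#' @rdname read_plate_map
#' @param layout A [plate_layout()] to write.
#' @export
write_plate_map <- function(layout, path) {
  w <- layout$wells
  w <- w[order(w$row, w$col), ]
  out <- data.frame(well = w$well, role = w$role,
                    formulation_id = w$formulation_id,
                    concentration_mg_per_ml = w$concentration_mg_ml,
                    replicate = w$replicate, fill_volume_ul = w$fill_volume_ul,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
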