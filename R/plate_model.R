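#' Default plate-layout column mapping
#'
#' Maps the canonical well fields used throughout the package to column names
#' in a plate CSV. Override individual entries (or supply a YAML file via
#' [read_layout_config()]) when reading plates exported with other headers.
#'
#' @return Named list mapping canonical names to CSV column names.
#' @export
default_layout <- function() {
  list(
    plate_id = "plate_id",
    well     = "well",
    drug_a   = "drug_a",
    conc_a   = "conc_a_uM",
    drug_b   = "drug_b",
    conc_b   = "conc_b_uM",
    signal   = "signal"
  )
}

#' Read a plate-layout configuration from YAML
#'
#' @param path Path to a YAML file whose keys are a subset of
#'   `names(default_layout())`.
#' @return Named list usable as `layout_config` in [read_plate()].
#' @export
read_layout_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_layout()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0) {
    stop("unknown layout keys: ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(base, cfg)
}

#' Read a viability plate from CSV
#'
#' Parses one record per well into the canonical well table. Wells with zero
#' concentration on both drug axes are flagged as no-drug controls. Drug
#' identifiers are kept as opaque strings; empty or NA identifiers denote an
#' unused axis (concentration 0).
#'
#' @param path Path to a plate CSV.
#' @param layout_config Named list mapping canonical fields to CSV columns;
#'   see [default_layout()].
#' @return A `data.frame` with columns `plate_id`, `well`, `row`, `col`,
#'   `drug_a`, `conc_a`, `drug_b`, `conc_b`, `raw_signal`, `is_control`.
#' @export
read_plate <- function(path, layout_config = default_layout()) {
  layout <- utils::modifyList(default_layout(), as.list(layout_config))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- unlist(layout[c("well", "conc_a", "signal")])
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("plate CSV lacks required column(s): ", paste(missing, collapse = ", "))
  }
  get_col <- function(key, default = NA) {
    col <- layout[[key]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  wells <- data.frame(
    plate_id = as.character(get_col("plate_id", "plate1")),
    well = as.character(raw[[layout$well]]),
    drug_a = as.character(get_col("drug_a")),
    conc_a = as.numeric(raw[[layout$conc_a]]),
    drug_b = as.character(get_col("drug_b")),
    conc_b = as.numeric(get_col("conc_b", 0)),
    raw_signal = as.numeric(raw[[layout$signal]]),
    stringsAsFactors = FALSE
  )
  wells$drug_a[!nzchar(wells$drug_a) | is.na(wells$drug_a)] <- NA_character_
  wells$drug_b[!nzchar(wells$drug_b) | is.na(wells$drug_b)] <- NA_character_
  wells$conc_a[is.na(wells$conc_a)] <- 0
  wells$conc_b[is.na(wells$conc_b)] <- 0
  if (any(!is.finite(wells$conc_a)) || any(!is.finite(wells$conc_b))) {
    stop("non-finite concentration in plate file")
  }
  if (any(wells$conc_a < 0) || any(wells$conc_b < 0)) {
    stop("negative concentration in plate file")
  }
  if (any(!is.finite(wells$raw_signal)) || any(wells$raw_signal < 0)) {
    stop("raw signals must be finite and non-negative")
  }
  wells$row <- gsub("[0-9]+$", "", wells$well)
  wells$col <- suppressWarnings(as.integer(gsub("^[A-Za-z]+", "", wells$well)))
  wells$is_control <- wells$conc_a == 0 & wells$conc_b == 0
  wells[, c("plate_id", "well", "row", "col", "drug_a", "conc_a",
            "drug_b", "conc_b", "raw_signal", "is_control")]
}

#' Write a well table back to plate CSV
#'
#' Inverse of [read_plate()] under the same layout: a write-then-read round
#' trip preserves all well fields.
#'
#' @param wells Well table as returned by [read_plate()].
#' @param path Output CSV path.
#' @param layout_config Column mapping, as in [read_plate()].
#' @return `path`, invisibly.
#' @export
write_plate <- function(wells, path, layout_config = default_layout()) {
  layout <- utils::modifyList(default_layout(), as.list(layout_config))
  out <- data.frame(
    wells$plate_id, wells$well, wells$drug_a, wells$conc_a,
    wells$drug_b, wells$conc_b, wells$raw_signal,
    stringsAsFactors = FALSE
  )
  names(out) <- unlist(layout[c("plate_id", "well", "drug_a", "conc_a",
                                "drug_b", "conc_b", "signal")])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Normalize raw signals to the no-drug controls
#'
#' Viability of each well is its raw signal divided by the mean raw signal of
#' the control (no-drug) wells, so the control mean maps to viability 1.
#' Values above 1 (drug-induced increases in metabolic rate) are retained.
#'
#' @param wells Well table from [read_plate()].
#' @return The well table with a `viability` column appended.
#' @export
normalize_to_control <- function(wells) {
  controls <- wells$raw_signal[wells$is_control]
  if (length(controls) == 0) {
    stop("no control (no-drug) wells present; cannot normalize")
  }
  ctrl_mean <- mean(controls)
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop("control mean signal is zero or non-finite; cannot normalize")
  }
  wells$viability <- wells$raw_signal / ctrl_mean
  wells
}

#' Build a single-agent geometric dilution series
#'
#' Concentrations follow `top_conc / dilution^(0:(n_points-1))`, the standard
#' serial-dilution design (e.g. a 13-point, three-fold series from 10 uM).
#'
#' @param drug Drug identifier.
#' @param top_conc Highest concentration, uM (> 0).
#' @param n_points Number of doses (>= 2).
#' @param dilution Fold-dilution between consecutive doses (> 1).
#' @return A `dose_series` object: list with `drug`, `concentrations`
#'   (strictly decreasing), `n_points`, `dilution_factor`.
#' @export
build_single_agent_series <- function(drug, top_conc, n_points, dilution) {
  if (!is.finite(top_conc) || top_conc <= 0) stop("top_conc must be > 0")
  if (n_points < 2) stop("n_points must be >= 2")
  if (!is.finite(dilution) || dilution <= 1) stop("dilution must be > 1")
  conc <- top_conc / dilution^(seq_len(n_points) - 1)
  structure(
    list(drug = drug, concentrations = conc, n_points = as.integer(n_points),
         dilution_factor = dilution),
    class = "dose_series"
  )
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf("<dose_series> %s: %d doses, %g-fold, %.4g to %.4g uM\n",
              x$drug, x$n_points, x$dilution_factor,
              max(x$concentrations), min(x$concentrations)))
  invisible(x)
}

#' Build a 7-dose combination axis
#'
#' The combination matrices use 7 doses per axis. With
#' `grid_axes = "with_zero"` (the default) the axis is a zero dose plus six
#' three-fold dilutions from the top dose, so the single-agent margins are
#' embedded in the grid; `"all_nonzero"` gives seven nonzero dilutions.
#'
#' @param top_conc Highest concentration, uM.
#' @param dilution Fold-dilution (default 3).
#' @param grid_axes `"with_zero"` or `"all_nonzero"`.
#' @return Numeric vector of 7 doses in increasing order.
#' @export
build_combination_axis <- function(top_conc, dilution = 3,
                                   grid_axes = c("with_zero", "all_nonzero")) {
  grid_axes <- match.arg(grid_axes)
  if (!is.finite(top_conc) || top_conc <= 0) stop("top_conc must be > 0")
  if (grid_axes == "with_zero") {
    c(0, top_conc / dilution^(5:0))
  } else {
    top_conc / dilution^(6:0)
  }
}

#' Construct a combination-grid object
#'
#' @param drug_a,drug_b Drug identifiers.
#' @param doses_a,doses_b Dose vectors (uM, increasing, length 7 by design
#'   but any length >= 2 is accepted).
#' @param viabilities Matrix of normalized viabilities, rows indexed by
#'   `doses_a`, columns by `doses_b`.
#' @return A `combination_grid` object.
#' @export
combination_grid <- function(drug_a, drug_b, doses_a, doses_b, viabilities) {
  viabilities <- as.matrix(viabilities)
  if (nrow(viabilities) != length(doses_a) ||
      ncol(viabilities) != length(doses_b)) {
    stop("viability matrix dimensions do not match dose axes")
  }
  if (is.unsorted(doses_a) || is.unsorted(doses_b)) {
    stop("dose axes must be increasing")
  }
  if (any(!is.finite(viabilities)) || any(viabilities < 0)) {
    stop("viabilities must be finite and non-negative")
  }
  dimnames(viabilities) <- list(format(doses_a, trim = TRUE),
                                format(doses_b, trim = TRUE))
  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         doses_a = as.numeric(doses_a), doses_b = as.numeric(doses_b),
         viabilities = viabilities),
    class = "combination_grid"
  )
}

#' @export
print.combination_grid <- function(x, ...) {
  cat(sprintf("<combination_grid> %s x %s: %d x %d doses\n",
              x$drug_a, x$drug_b, length(x$doses_a), length(x$doses_b)))
  invisible(x)
}

#' Assemble a combination grid from normalized wells
#'
#' Collects all wells of one drug pair (including the zero-dose margins and
#' the double-zero control cell) into a dose-indexed viability matrix.
#' Replicate wells at the same dose pair are averaged with the arithmetic
#' mean. Viabilities above `cap` are truncated to guard against outliers;
#' stimulation above 1 below the cap is retained.
#'
#' @param wells Normalized well table ([normalize_to_control()]) restricted
#'   to one drug pair; zero-dose wells may carry NA drug identifiers.
#' @param drug_a,drug_b Drug identifiers for the two axes.
#' @param cap Upper truncation for viabilities (default 2).
#' @return A [combination_grid()].
#' @export
assemble_combination_grid <- function(wells, drug_a, drug_b, cap = 2) {
  if (!"viability" %in% names(wells)) {
    stop("wells must be normalized first (missing viability column)")
  }
  on_a <- (is.na(wells$drug_a) & wells$conc_a == 0) |
    (!is.na(wells$drug_a) & wells$drug_a == drug_a)
  on_b <- (is.na(wells$drug_b) & wells$conc_b == 0) |
    (!is.na(wells$drug_b) & wells$drug_b == drug_b)
  w <- wells[on_a & on_b, , drop = FALSE]
  if (nrow(w) == 0) stop("no wells found for pair ", drug_a, " x ", drug_b)
  doses_a <- sort(unique(w$conc_a))
  doses_b <- sort(unique(w$conc_b))
  full <- expand.grid(conc_a = doses_a, conc_b = doses_b)
  key <- function(a, b) paste(format(a, digits = 12), format(b, digits = 12))
  have <- key(w$conc_a, w$conc_b)
  need <- key(full$conc_a, full$conc_b)
  missing <- !(need %in% have)
  if (any(missing)) {
    miss <- full[missing, , drop = FALSE]
    stop("incomplete grid; missing dose pair(s): ",
         paste(sprintf("(%g, %g)", miss$conc_a, miss$conc_b), collapse = ", "))
  }
  agg <- tapply(w$viability, list(factor(key(w$conc_a, w$conc_b), levels = need)),
                mean)
  mat <- matrix(pmin(as.numeric(agg), cap),
                nrow = length(doses_a), ncol = length(doses_b))
  combination_grid(drug_a, drug_b, doses_a, doses_b, mat)
}
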