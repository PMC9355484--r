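# Flat CSV dialect for gas-analyzer style exports.
#
# Canonical (post-mapping) columns:
#   metadata : cultivar, treatment, block, plant
#   gas      : A, gs, E, Ci, Ca, Q, Tleaf, RH (optional)
#   fluor    : Fo, Fm, Fs, Fmp, Fop (optional)
# Vendor exports are adapted with a column_map (canonical -> file name) and
# per-column unit_scales, both loadable from YAML via read_config().

.mandatory_cols <- c("cultivar", "treatment", "block", "plant",
                     "A", "gs", "E", "Ci", "Ca", "Q", "Tleaf",
                     "Fo", "Fm", "Fs", "Fmp")
.optional_cols <- c("Fop", "RH")
.numeric_cols <- c("A", "gs", "E", "Ci", "Ca", "Q", "Tleaf",
                   "Fo", "Fm", "Fs", "Fmp", "Fop", "RH")

#' Read a gas-analyzer style CSV table
#'
#' Reads a flat CSV with one steady-state observation per row: gas-exchange
#' and raw fluorescence values keyed by (cultivar, treatment, block, plant).
#' Unmapped columns are retained untouched as opaque extras.
#'
#' @param path CSV file with a header row.
#' @param column_map optional named character vector mapping canonical names
#'   (see Details) to the file's column names.
#' @param unit_scales optional named numeric vector of multipliers applied to
#'   canonical numeric columns after reading (e.g. `c(E = 1000)` to convert a
#'   file in mol m⁻² s⁻¹ to the package's mmol convention).
#'
#' @details Mandatory canonical columns: cultivar, treatment, block, plant,
#' A, gs, E, Ci, Ca, Q, Tleaf, Fo, Fm, Fs, Fmp. Optional: Fop (minimal
#' light-adapted fluorescence; when absent it can be estimated downstream
#' with [estimate_fo_prime()]) and RH.
#'
#' @return data.frame of class `gas_table` with canonical column names, one
#'   row per observation; attribute `"read_log"` records rows accepted.
#' @export
read_gas_table <- function(path, column_map = NULL, unit_scales = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty file (header only): ", path)

  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (src %in% names(df)) names(df)[names(df) == src] <- canon
    }
  }
  missing <- setdiff(.mandatory_cols, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))

  present_num <- intersect(.numeric_cols, names(df))
  for (col in present_num) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & trimws(v) != "")
      if (length(bad))
        stop("non-numeric value in column '", col, "' at data row ",
             bad[1])
      v <- parsed
    }
    df[[col]] <- v
  }
  if (!is.null(unit_scales)) {
    for (col in intersect(names(unit_scales), present_num))
      df[[col]] <- df[[col]] * unit_scales[[col]]
  }
  df$block <- as.integer(df$block)
  df$plant <- as.integer(df$plant)
  attr(df, "read_log") <- sprintf("read_gas_table: %s rows=%d accepted=%d",
                                  basename(path), nrow(df), nrow(df))
  class(df) <- c("gas_table", class(df))
  df
}

#' Validate a gas-exchange record against its type invariants
#'
#' Validation is total: it returns a character vector of violated rules
#' (empty when the record is admissible) and never raises.
#'
#' @param record list or one-row data.frame with fields `gs`, `ca`, `ci`,
#'   `q`, `e` and optionally `rh` (case-insensitive names accepted).
#' @return character vector of violation descriptions, possibly empty.
#' @export
validate_gas_record <- function(record) {
  r <- .lower_fields(record)
  out <- character()
  chk <- function(cond, msg) if (isTRUE(!cond)) msg else NULL
  out <- c(out,
           chk(is.null(r$gs) || r$gs > 0, "gs > 0"),
           chk(is.null(r$ca) || r$ca > 0, "ca > 0"),
           chk(is.null(r$ci) || r$ci >= 0, "ci >= 0"),
           chk(is.null(r$q) || r$q >= 0, "q >= 0"),
           chk(is.null(r$e) || r$e >= 0, "e >= 0"),
           chk(is.null(r$rh) || (r$rh > 0 && r$rh < 1), "rh in (0,1)"))
  out
}

#' Validate a raw fluorescence record against its type invariants
#'
#' Checks the ordering constraints on the raw F-levels of one quenching
#' measurement: 0 < Fo < Fm and Fo′ ≤ Fs ≤ Fm′ ≤ Fm (Fo′ only when present),
#' plus the admissible ranges of the absorptance and PSII-fraction constants.
#' Total: returns findings, never raises.
#'
#' @param record list or one-row data.frame with `fo`, `fm`, `fs`,
#'   `fm_prime` (or `fmp`), optional `fo_prime`/`fop`, `alpha`, `f_psii`.
#' @return character vector of violation descriptions, possibly empty.
#' @export
validate_fluor_record <- function(record) {
  r <- .lower_fields(record)
  fmp <- r$fm_prime %||% r$fmp
  fop <- r$fo_prime %||% r$fop
  out <- character()
  chk <- function(cond, msg) if (isTRUE(!cond)) msg else NULL
  out <- c(out,
           chk(is.null(r$fo) || r$fo > 0, "fo > 0"),
           chk(is.null(r$fo) || is.null(r$fm) || r$fo < r$fm, "fo < fm"),
           chk(is.null(fop) || is.null(r$fs) || fop <= r$fs, "fo_prime <= fs"),
           chk(is.null(r$fs) || is.null(fmp) || r$fs <= fmp, "fs <= fm_prime"),
           chk(is.null(fmp) || is.null(r$fm) || fmp <= r$fm, "fm_prime <= fm"),
           chk(is.null(r$alpha) || (r$alpha > 0 && r$alpha <= 1),
               "alpha in (0,1]"),
           chk(is.null(r$f_psii) || (r$f_psii > 0 && r$f_psii <= 1),
               "f_psii in (0,1]"))
  out
}

.lower_fields <- function(record) {
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  names(record) <- tolower(names(record))
  lapply(record, function(x) if (is.numeric(x) && length(x) == 1) x else x)
}

#' Write a set of result tables to CSV files
#'
#' One CSV per table, named `<name>.csv` under `dir`, with stable column
#' order and numeric values preserved to full double precision (15
#' significant digits), so a write/read round trip is the identity for all
#' practical purposes.
#'
#' @param tables non-empty named list of data.frames.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report_table <- function(tables, dir) {
  if (!length(tables)) stop("no tables to write")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 15,
                                                     format = "g"))
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
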