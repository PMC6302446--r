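#' Cap growth fractions at 1
#'
#' Relative growth fractions from combination screens occasionally exceed 1
#' (apparent growth enhancement); most such values are considered artifacts
#' and are capped at 1 before any downstream aggregation. Values below -1
#' (more than total lethality) are impossible and rejected.
#'
#' @param g Numeric vector of growth fractions; each must be >= -1.
#' @return `pmin(g, 1)`; values <= 1 are returned unchanged. `NA` passes
#'   through.
#' @examples
#' cap_growth(c(1.3, 0.5, -1))
#' @export
cap_growth <- function(g) {
  if (!is.numeric(g)) stop("'g' must be numeric")
  bad <- which(g < -1)
  if (length(bad)) {
    stop(sprintf("invalid growth measurement < -1 at position(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  pmin(g, 1)
}

#' Construct and validate a screen record table
#'
#' A screen record is one dosed measurement of the growth fraction for a
#' (cell line, drug A, drug B) tuple. Single-agent measurements have
#' `drug_b` and `dose_b_idx` both `NA`.
#'
#' @param cell_id,drug_a Character identifiers (whitespace-trimmed).
#' @param drug_b Character identifier or `NA` for single-agent records.
#' @param dose_a_idx,dose_b_idx Non-negative integer dose-level indices;
#'   `dose_b_idx` must be `NA` exactly when `drug_b` is.
#' @param growth Numeric growth fraction, >= -1 (values > 1 permitted before
#'   capping).
#' @param qc_pass Logical quality-control flag (supplied by the screen; the
#'   QC rule itself is not recomputed here).
#' @return A `data.frame` with class `screen_records`.
#' @export
screen_records <- function(cell_id, drug_a, drug_b = NA_character_,
                           dose_a_idx = 0L, dose_b_idx = NA_integer_,
                           growth, qc_pass = TRUE) {
  df <- data.frame(
    cell_id = trimws(as.character(cell_id)),
    drug_a = trimws(as.character(drug_a)),
    drug_b = trimws(as.character(drug_b)),
    dose_a_idx = as.integer(dose_a_idx),
    dose_b_idx = as.integer(dose_b_idx),
    growth = as.numeric(growth),
    qc_pass = as.logical(qc_pass),
    stringsAsFactors = FALSE
  )
  df$drug_b[!nzchar(df$drug_b) | is.na(df$drug_b)] <- NA_character_
  validate_screen_records(df)
}

validate_screen_records <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("cell_id", "drug_a", "drug_b", "dose_a_idx", "dose_b_idx",
              "growth", "qc_pass")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("missing screen record column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$growth < -1, na.rm = TRUE)) {
    stop("invalid measurement: growth < -1")
  }
  single <- is.na(df$drug_b)
  if (any(single & !is.na(df$dose_b_idx))) {
    stop("single-agent records must have dose_b_idx absent")
  }
  if (any(!single & is.na(df$dose_b_idx))) {
    stop("pair records must carry a dose_b_idx")
  }
  if (any(stats::na.omit(c(df$dose_a_idx, df$dose_b_idx)) < 0)) {
    stop("dose indices must be >= 0")
  }
  class(df) <- c("screen_records", "data.frame")
  df
}

#' Filter screen records by QC flag, drug whitelist, and cell blacklist
#'
#' Mirrors the subsetting step that narrows a raw screen to the analyzable
#' experiments: drop records failing the screen's quality control, restrict
#' to drugs with available descriptors, and exclude problematic cell lines.
#'
#' @param records A `screen_records` data frame.
#' @param require_qc If `TRUE`, keep only records with `qc_pass`.
#' @param allowed_drugs Optional character vector; if given, both `drug_a`
#'   and (when present) `drug_b` must be in it.
#' @param excluded_cells Optional character vector of cell ids to drop.
#' @return The filtered `screen_records` (possibly empty).
#' @export
filter_records <- function(records, require_qc = FALSE,
                           allowed_drugs = NULL, excluded_cells = NULL) {
  records <- validate_screen_records(records)
  keep <- rep(TRUE, nrow(records))
  if (require_qc) keep <- keep & records$qc_pass
  if (!is.null(allowed_drugs)) {
    keep <- keep & records$drug_a %in% allowed_drugs &
      (is.na(records$drug_b) | records$drug_b %in% allowed_drugs)
  }
  if (!is.null(excluded_cells)) {
    keep <- keep & !(records$cell_id %in% excluded_cells)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate dosed records to per-tuple minimum growth (MinComboGrowth)
#'
#' Groups records by (cell, drug A, drug B) and keeps the lowest capped
#' growth fraction seen at any dose combination for that tuple: the best
#' growth inhibition achieved across the dose grid. Dose indices are only
#' used for duplicate detection, never as features.
#'
#' @param records A `screen_records` data frame. Growth is capped at 1
#'   before aggregation.
#' @param on_conflict How to treat duplicate (tuple, dose pair) rows with
#'   conflicting growth: `"min"` (default, keep the minimum, consistent with
#'   the min-over-doses target) or `"error"`.
#' @return A `response_table` data frame with columns `cell_id`, `drug_a`,
#'   `drug_b` (`NA` for single agents), and `min_growth` in \[-1, 1\], one
#'   row per distinct tuple.
#' @export
aggregate_min_growth <- function(records, on_conflict = c("min", "error")) {
  on_conflict <- match.arg(on_conflict)
  records <- validate_screen_records(records)
  records$growth <- cap_growth(records$growth)
  if (on_conflict == "error" && nrow(records)) {
    dose_key <- paste(records$cell_id, records$drug_a, records$drug_b,
                      records$dose_a_idx, records$dose_b_idx, sep = "\r")
    rng <- tapply(records$growth, dose_key, function(x) diff(range(x)))
    if (any(rng > 0)) {
      stop("conflicting growth for duplicate dosed measurement(s): ",
           paste(utils::head(names(rng)[rng > 0], 3L), collapse = "; "))
    }
  }
  if (!nrow(records)) {
    return(response_table(character(), character(), character(), numeric()))
  }
  key <- paste(records$cell_id, records$drug_a, records$drug_b, sep = "\r")
  first <- !duplicated(key)
  mins <- tapply(records$growth, key, min)
  out <- response_table(
    cell_id = records$cell_id[first],
    drug_a = records$drug_a[first],
    drug_b = records$drug_b[first],
    min_growth = as.numeric(mins[key[first]])
  )
  out
}

#' Construct a response table of per-tuple minimum growth targets
#'
#' @param cell_id,drug_a,drug_b Identifiers (`drug_b` `NA` for singles).
#' @param min_growth Numeric in \[-1, 1\].
#' @return A `response_table` data frame.
#' @export
response_table <- function(cell_id, drug_a, drug_b, min_growth) {
  df <- data.frame(cell_id = as.character(cell_id),
                   drug_a = as.character(drug_a),
                   drug_b = as.character(drug_b),
                   min_growth = as.numeric(min_growth),
                   stringsAsFactors = FALSE)
  if (any(df$min_growth < -1 | df$min_growth > 1, na.rm = TRUE)) {
    stop("min_growth must lie in [-1, 1] (cap growth before aggregating)")
  }
  key <- paste(df$cell_id, df$drug_a, df$drug_b, sep = "\r")
  if (anyDuplicated(key)) stop("response table has duplicate tuples")
  rownames(df) <- NULL
  class(df) <- c("response_table", "data.frame")
  df
}

# Delimited I/O ---------------------------------------------------------

# comma/tab autodetect on the header line
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read a combination screen table from delimited text
#'
#' Expects a header row with columns `CELL, DRUG_A, DRUG_B, DOSE_A, DOSE_B,
#' GROWTH, QC`; the separator (comma or tab) is autodetected. An empty
#' `DRUG_B`/`DOSE_B` marks a single-agent record. Identifiers are treated as
#' opaque strings and whitespace-trimmed.
#'
#' @param path File path.
#' @return A validated `screen_records` data frame.
#' @export
read_screen <- function(path) {
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), strip.white = TRUE)
  needed <- c("CELL", "DRUG_A", "DRUG_B", "DOSE_A", "DOSE_B", "GROWTH", "QC")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) stop("screen file lacks column(s): ",
                         paste(miss, collapse = ", "))
  screen_records(
    cell_id = raw$CELL, drug_a = raw$DRUG_A, drug_b = raw$DRUG_B,
    dose_a_idx = suppressWarnings(as.integer(raw$DOSE_A)),
    dose_b_idx = suppressWarnings(as.integer(raw$DOSE_B)),
    growth = as.numeric(raw$GROWTH),
    qc_pass = as.logical(raw$QC) |
      (!is.na(raw$QC) & raw$QC %in% c("1", "T"))
  )
}

#' Write a combination screen table as delimited text
#'
#' @param records A `screen_records` data frame.
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @export
write_screen <- function(records, path, sep = ",") {
  records <- validate_screen_records(records)
  out <- data.frame(CELL = records$cell_id, DRUG_A = records$drug_a,
                    DRUG_B = records$drug_b, DOSE_A = records$dose_a_idx,
                    DOSE_B = records$dose_b_idx, GROWTH = records$growth,
                    QC = records$qc_pass)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
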