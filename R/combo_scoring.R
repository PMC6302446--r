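#' Modified expected growth fraction for a drug combination
#'
#' The additivity reference against which combination benefit is scored.
#' With `y_a`, `y_b` the lowest single-agent growth fractions of the two
#' drugs on a cell line, the expected combination growth is
#' \deqn{z = \min(y_A, y_B)}{z = min(y_a, y_b)} if either single-agent
#' growth is <= 0 (a fully inhibitory drug cannot be improved upon
#' multiplicatively), and otherwise the product of the two growths each
#' truncated at 1, \eqn{\min(y_A,1)\cdot\min(y_B,1)}.
#'
#' @param y_a,y_b Numeric vectors of single-agent minimum growth fractions,
#'   each >= -1 (recycled to a common length).
#' @return Numeric vector of expected combination growth fractions.
#' @examples
#' expected_growth(0.5, 0.6)   # 0.30, product branch
#' expected_growth(-0.2, 0.5)  # -0.2, min branch
#' @export
expected_growth <- function(y_a, y_b) {
  if (any(y_a < -1, na.rm = TRUE) || any(y_b < -1, na.rm = TRUE)) {
    stop("single-agent growth fractions must be >= -1")
  }
  n <- max(length(y_a), length(y_b))
  y_a <- rep_len(y_a, n)
  y_b <- rep_len(y_b, n)
  ifelse(y_a <= 0 | y_b <= 0,
         pmin(y_a, y_b),
         pmin(y_a, 1) * pmin(y_b, 1))
}

#' BestComboScore: observed minus expected growth, in percentage points
#'
#' Scores a drug pair on a cell line by comparing the lowest growth fraction
#' observed at any dose combination (`y_ab`, MinComboGrowth) with the
#' modified expected growth from the two single agents:
#' \deqn{C = (y_{AB} - z_{AB}) \times 100.}{C = (y_ab - z_ab) * 100.}
#' Negative scores indicate greater-than-expected inhibition (enhanced
#' combination activity).
#'
#' @param y_ab Pair minimum growth fraction (capped at 1).
#' @param y_a,y_b Single-agent minimum growth fractions.
#' @return Numeric score in growth-percentage units.
#' @examples
#' best_combo_score(0.2, 0.5, 0.6)  # -10
#' @export
best_combo_score <- function(y_ab, y_a, y_b) {
  if (any(y_ab < -1, na.rm = TRUE)) stop("y_ab must be >= -1")
  (y_ab - expected_growth(y_a, y_b)) * 100
}

#' Canonical pair key
#'
#' Pairs are stored as screened (ordered); rankings and set comparisons use
#' an unordered canonical key so that (A, B) and (B, A) collapse.
#'
#' @param drug_a,drug_b Character vectors.
#' @param ordered If `TRUE`, keep the screened order.
#' @return Character keys `"<first>|<second>"`.
#' @export
pair_key <- function(drug_a, drug_b, ordered = FALSE) {
  if (ordered) return(paste(drug_a, drug_b, sep = "|"))
  paste(pmin(drug_a, drug_b), pmax(drug_a, drug_b), sep = "|")
}

#' Score every pair tuple of a response table
#'
#' Joins each pair row of a response table with the two matching
#' single-agent rows of the same cell line and computes the expected growth
#' and BestComboScore. Pairs lacking a single-agent measurement for either
#' drug are unscorable; real screens have gaps, so these default to being
#' skipped with a warning.
#'
#' @param responses A `response_table` containing both pair and single-agent
#'   rows.
#' @param on_missing `"skip"` (default; drop unscorable pairs with a
#'   warning) or `"error"`.
#' @return A `combo_score_table` data frame with columns `cell_id`,
#'   `drug_a`, `drug_b`, `y_ab`, `y_a`, `y_b`, `z_ab`, `c_ab`.
#' @export
score_table <- function(responses, on_missing = c("skip", "error")) {
  on_missing <- match.arg(on_missing)
  stopifnot(is.data.frame(responses))
  pairs <- responses[!is.na(responses$drug_b), , drop = FALSE]
  singles <- responses[is.na(responses$drug_b), , drop = FALSE]
  empty <- data.frame(cell_id = character(), drug_a = character(),
                      drug_b = character(), y_ab = numeric(),
                      y_a = numeric(), y_b = numeric(), z_ab = numeric(),
                      c_ab = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("combo_score_table", "data.frame")
  if (!nrow(pairs)) return(empty)

  skey <- paste(singles$cell_id, singles$drug_a, sep = "\r")
  y_a <- singles$min_growth[match(paste(pairs$cell_id, pairs$drug_a,
                                        sep = "\r"), skey)]
  y_b <- singles$min_growth[match(paste(pairs$cell_id, pairs$drug_b,
                                        sep = "\r"), skey)]
  unscorable <- is.na(y_a) | is.na(y_b)
  if (any(unscorable)) {
    what <- paste0(pairs$cell_id[unscorable], ":",
                   pair_key(pairs$drug_a[unscorable],
                            pairs$drug_b[unscorable], ordered = TRUE))
    if (on_missing == "error") {
      stop("missing single-agent response for pair(s): ",
           paste(utils::head(what, 5L), collapse = ", "))
    }
    warning(sprintf("skipping %d unscorable pair(s) lacking single-agent rows (e.g. %s)",
                    sum(unscorable), what[1L]))
  }
  keep <- !unscorable
  z <- expected_growth(y_a[keep], y_b[keep])
  out <- data.frame(cell_id = pairs$cell_id[keep],
                    drug_a = pairs$drug_a[keep],
                    drug_b = pairs$drug_b[keep],
                    y_ab = pairs$min_growth[keep],
                    y_a = y_a[keep], y_b = y_b[keep],
                    z_ab = z,
                    c_ab = (pairs$min_growth[keep] - z) * 100,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("combo_score_table", "data.frame")
  out
}

#' Write a combo score table as delimited text
#'
#' @param scores A `combo_score_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_combo_scores <- function(scores, path, sep = ",") {
  out <- data.frame(CELL = scores$cell_id, DRUG_A = scores$drug_a,
                    DRUG_B = scores$drug_b, Y_AB = scores$y_ab,
                    Y_A = scores$y_a, Y_B = scores$y_b, Z_AB = scores$z_ab,
                    BEST_COMBO_SCORE = scores$c_ab)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
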