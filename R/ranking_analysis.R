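#' Top-K drug pairs for a cell line by BestComboScore
#'
#' "Best" means most negative score: growth furthest below the additivity
#' expectation, i.e. strongest enhanced activity. Ties break
#' lexicographically on the pair key for determinism.
#'
#' @param scores A `combo_score_table`.
#' @param cell_id Cell line identifier (must be present in `scores`).
#' @param k List length (default 100); fewer available pairs give a
#'   shorter list.
#' @param unordered Collapse (A, B)/(B, A) to one canonical key (default);
#'   `FALSE` keeps pairs as screened.
#' @return Character vector of up to `k` pair keys, strongest enhancement
#'   first.
#' @export
top_k_pairs <- function(scores, cell_id, k = 100L, unordered = TRUE) {
  rows <- scores[scores$cell_id == cell_id, , drop = FALSE]
  if (!nrow(rows)) stop("unknown cell line: ", cell_id)
  key <- pair_key(rows$drug_a, rows$drug_b, ordered = !unordered)
  if (unordered && anyDuplicated(key)) {
    best <- tapply(rows$c_ab, key, min)
    key <- names(best)
    score <- as.numeric(best)
  } else {
    score <- rows$c_ab
  }
  ord <- order(score, key)
  utils::head(key[ord], k)
}

#' Membership difference between a true and a predicted top-K list
#'
#' Counts how many members of the true list are absent from the predicted
#' list (an unordered set comparison): 0 for identical lists, up to K for
#' disjoint ones.
#'
#' @param list_true,list_pred Character vectors of pair keys for the same
#'   cell line and K.
#' @return Integer count of missed members.
#' @export
top_list_difference <- function(list_true, list_pred) {
  length(setdiff(list_true, list_pred))
}

#' Pool per-cell top lists and rank pairs by frequency
#'
#' The virtual-screening view: pairs appearing in the top list of many
#' cell lines are broadly promising. Ties break lexicographically.
#'
#' @param top_lists List of character vectors (one top-K list per cell
#'   line).
#' @param n Number of leading pairs to return (default 10).
#' @return Character vector of pair keys, most frequent first.
#' @export
pooled_frequency_ranking <- function(top_lists, n = 10L) {
  stopifnot(length(top_lists) >= 1)
  counts <- table(unlist(top_lists, use.names = FALSE))
  keys <- names(counts)
  ord <- order(-as.integer(counts), keys)
  utils::head(keys[ord], n)
}

#' Per-cell-line summary of prediction error and combination effect
#'
#' Aggregates pooled out-of-fold predictions along the cell-line axis:
#' mean and standard deviation of the growth prediction error
#' (predicted - experimental), a 95% confidence interval for the mean
#' error, and (when a score table is supplied) the mean BestComboScore
#' over that cell's pairs.
#'
#' @param oof Out-of-fold prediction table from [cross_validate()].
#' @param scores Optional `combo_score_table` to attach mean scores.
#' @return Data frame with one row per cell line: `cell_id`, `n`,
#'   `mean_error`, `sd_error` (`NA` with fewer than 2 observations),
#'   `ci_lo`, `ci_hi`, and `mean_combo_score` when scores are given.
#' @export
per_cell_error_summary <- function(oof, scores = NULL) {
  err <- oof$y_pred - oof$y_true
  cells <- sort(unique(oof$cell_id))
  out <- do.call(rbind, lapply(cells, function(cl) {
    e <- err[oof$cell_id == cl]
    n <- length(e)
    sd_e <- if (n >= 2) stats::sd(e) else NA_real_
    se <- if (n >= 2) sd_e / sqrt(n) else NA_real_
    data.frame(cell_id = cl, n = n, mean_error = mean(e), sd_error = sd_e,
               ci_lo = mean(e) - 1.96 * se, ci_hi = mean(e) + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(scores)) {
    ms <- tapply(scores$c_ab, scores$cell_id, mean)
    out$mean_combo_score <- as.numeric(ms[out$cell_id])
  }
  rownames(out) <- NULL
  out
}

#' Drug-by-drug matrix of mean prediction error
#'
#' Flattens out-of-fold errors onto the drug-pair plane: entry (A, B) is
#' the mean (predicted - experimental) growth over all cell lines for that
#' pair, mirrored into (B, A). Diagonal entries hold the single-agent
#' errors. Cells with no observations are `NA`.
#'
#' @param oof Out-of-fold prediction table (single-agent rows have
#'   `drug_b = NA`).
#' @return `list(mean = matrix, n = matrix)` of mean errors and
#'   observation counts, drugs in sorted order.
#' @export
pair_error_matrix <- function(oof) {
  drugs <- sort(unique(c(oof$drug_a, stats::na.omit(oof$drug_b))))
  m <- matrix(NA_real_, length(drugs), length(drugs),
              dimnames = list(drugs, drugs))
  cnt <- matrix(0L, length(drugs), length(drugs),
                dimnames = list(drugs, drugs))
  if (!nrow(oof)) return(list(mean = m, n = cnt))
  err <- oof$y_pred - oof$y_true
  b_eff <- ifelse(is.na(oof$drug_b), oof$drug_a, oof$drug_b)
  key <- paste(pmin(oof$drug_a, b_eff), pmax(oof$drug_a, b_eff), sep = "\r")
  means <- tapply(err, key, mean)
  ns <- tapply(err, key, length)
  parts <- strsplit(names(means), "\r", fixed = TRUE)
  for (i in seq_along(means)) {
    a <- parts[[i]][1]
    b <- parts[[i]][2]
    m[a, b] <- m[b, a] <- means[[i]]
    cnt[a, b] <- cnt[b, a] <- ns[[i]]
  }
  list(mean = m, n = cnt)
}

#' Order drugs by hierarchical clustering of their row vectors
#'
#' Heatmap row/column ordering: agglomerative clustering (average linkage)
#' under correlation distance, `1 - Pearson(row_i, row_j)`. Rows with zero
#' variance have undefined correlation; their distances default to 1 (no
#' similarity) with a message.
#'
#' @param m Numeric drug-by-drug (or drug-by-anything) matrix with
#'   rownames; `NA`s are tolerated via pairwise-complete correlation.
#' @return Character vector: the dendrogram leaf order of the row ids.
#' @export
cluster_order <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2, !is.null(rownames(m)))
  cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  if (anyNA(cc)) {
    message("undefined correlation for constant/disjoint rows; distance set to 1")
    cc[is.na(cc)] <- 0
  }
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  rownames(m)[hc$order]
}
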