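#' Construct a feature matrix
#'
#' A feature matrix holds named entities (cell lines or drugs) in rows and
#' named features in columns, with `NA` marking missing cells. A state tag
#' vector records which preprocessing steps have been applied, so that e.g.
#' a log transform cannot be applied twice or to drug descriptors by
#' accident.
#'
#' @param values Numeric matrix with non-empty, unique `rownames` and
#'   `colnames`.
#' @param state Character vector of applied-step tags, a subset of
#'   `c("raw", "log_transformed", "imputed", "scaled")`.
#' @return The matrix with class `feature_matrix` and a `state` attribute.
#' @export
feature_matrix <- function(values, state = "raw") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("feature matrix needs row and column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate row ids")
  if (anyDuplicated(colnames(values))) stop("duplicate feature names")
  known <- c("raw", "log_transformed", "imputed", "scaled")
  if (!all(state %in% known)) stop("unknown state tag")
  structure(values, state = state,
            class = c("feature_matrix", class(values)))
}

fm_state <- function(m) attr(m, "state") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

fm_retag <- function(m, template, add = NULL) {
  feature_matrix(m, state = union(fm_state(template), add))
}

#' Elementwise log(x + 1) transform
#'
#' Applied to abundance-type assays (e.g. protein abundance) whose upstream
#' sources were not already log-transformed. Inputs that arrive
#' pre-transformed should be declared as such (tag `log_transformed` at
#' construction) rather than sniffed; drug descriptors are never
#' transformed.
#'
#' @param m A `feature_matrix` with non-negative present values and no
#'   `log_transformed` tag.
#' @return The transformed matrix, missing cells preserved, state tagged.
#' @export
log1p_transform <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  if ("log_transformed" %in% fm_state(m)) {
    stop("matrix is already log-transformed")
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value at row '%s', column '%s': log(x+1) needs x >= 0",
                 rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  }
  out <- log1p(unclass(m))
  fm_retag(out, m, add = "log_transformed")
}

#' Drop descriptor columns that are mostly missing
#'
#' Columns whose fraction of missing rows is at least `missing_frac` carry
#' too little information to impute and are removed (a column at exactly
#' the threshold is dropped). Column order is otherwise preserved.
#'
#' @param m A `feature_matrix`.
#' @param missing_frac Threshold in (0, 1\]; default 0.9.
#' @return The filtered matrix; dropped column names are reported via
#'   `message()` and attached as attribute `dropped`.
#' @export
filter_sparse_columns <- function(m, missing_frac = 0.9) {
  stopifnot(inherits(m, "feature_matrix"),
            missing_frac > 0, missing_frac <= 1)
  frac <- colMeans(is.na(m))
  drop <- frac >= missing_frac
  if (any(drop)) {
    message(sprintf("dropping %d column(s) with >= %.0f%% missing: %s",
                    sum(drop), 100 * missing_frac,
                    paste(utils::head(colnames(m)[drop], 10L),
                          collapse = ", ")))
  }
  out <- unclass(m)[, !drop, drop = FALSE]
  out <- fm_retag(out, m)
  attr(out, "dropped") <- colnames(m)[drop]
  out
}

#' Mean-impute missing values per column
#'
#' Missing cells are replaced by the column mean over the fitting rows.
#' The fitted means are returned so held-out rows can be transformed with
#' training-set statistics (no leakage); passing `means` applies a previous
#' fit instead of fitting fresh.
#'
#' @param m A `feature_matrix`.
#' @param means Optional named numeric vector of previously fitted column
#'   means (transform-only use).
#' @return `list(matrix = imputed feature_matrix, means = named numeric)`.
#' @export
mean_impute <- function(m, means = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- unclass(m)
  if (is.null(means)) {
    means <- colMeans(vals, na.rm = TRUE)
    if (any(is.nan(means))) {
      stop("all-missing column(s) on fitting set (filter sparse columns first): ",
           paste(utils::head(colnames(vals)[is.nan(means)], 5L),
                 collapse = ", "))
    }
  } else {
    if (is.null(names(means)) || !all(colnames(vals) %in% names(means))) {
      stop("supplied means must be named and cover every column")
    }
    means <- means[colnames(vals)]
  }
  na_idx <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(na_idx)) vals[na_idx] <- means[na_idx[, 2]]
  list(matrix = fm_retag(vals, m, add = "imputed"), means = means)
}

#' Min-max scale each column to \[0, 1\]
#'
#' Applies `x -> (x - min) / (max - min)` per column using fitting-set
#' bounds. Constant columns map to 0 (degenerate range). When transforming
#' held-out rows with previously fitted bounds, values falling outside the
#' fitted range are clipped to \[0, 1\] to preserve the contract.
#'
#' @param m A `feature_matrix` without missing values (impute first).
#' @param bounds Optional `list(min = , max = )` of named numeric vectors
#'   from a previous fit.
#' @return `list(matrix = scaled feature_matrix, bounds = list(min, max))`.
#' @export
minmax_scale <- function(m, bounds = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- unclass(m)
  if (anyNA(vals)) stop("matrix has missing values; impute before scaling")
  if (is.null(bounds)) {
    bounds <- list(min = apply(vals, 2, min), max = apply(vals, 2, max))
  } else {
    bounds <- list(min = bounds$min[colnames(vals)],
                   max = bounds$max[colnames(vals)])
    if (anyNA(bounds$min) || anyNA(bounds$max)) {
      stop("supplied bounds must cover every column")
    }
  }
  rng <- bounds$max - bounds$min
  scaled <- sweep(vals, 2, bounds$min, "-")
  nz <- rng > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, rng[nz], "/")
  scaled[, !nz] <- 0
  scaled <- pmin(pmax(scaled, 0), 1)
  list(matrix = fm_retag(scaled, m, add = "scaled"), bounds = bounds)
}

#' Full preprocessing pipeline: filter, impute, scale
#'
#' Canonical order for descriptor and omics matrices. By default statistics
#' are fitted on the rows supplied; pass `fit = <previous result>` to
#' transform held-out rows with training-fold statistics instead
#' (leakage-safe cross-validation), or fit once on the full matrix to
#' mirror a whole-dataset preprocessing convention.
#'
#' @param m A `feature_matrix`.
#' @param missing_frac Sparse-column threshold (see
#'   [filter_sparse_columns()]); applied only when fitting.
#' @param fit Optional result of a previous `preprocess_features()` call;
#'   its column set, means and bounds are reused.
#' @return `list(matrix, columns, means, bounds)`; `matrix` has no missing
#'   values and all entries in \[0, 1\].
#' @export
preprocess_features <- function(m, missing_frac = 0.9, fit = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  if (is.null(fit)) {
    m <- filter_sparse_columns(m, missing_frac)
    imp <- mean_impute(m)
    sc <- minmax_scale(imp$matrix)
    list(matrix = sc$matrix, columns = colnames(sc$matrix),
         means = imp$means, bounds = sc$bounds)
  } else {
    keep <- intersect(fit$columns, colnames(m))
    if (!setequal(keep, fit$columns)) {
      stop("matrix lacks fitted column(s)")
    }
    sub <- feature_matrix(unclass(m)[, fit$columns, drop = FALSE],
                          state = fm_state(m))
    imp <- mean_impute(sub, means = fit$means)
    sc <- minmax_scale(imp$matrix, bounds = fit$bounds)
    list(matrix = sc$matrix, columns = fit$columns,
         means = fit$means, bounds = fit$bounds)
  }
}

#' Identifier-only entity encodings for ablation experiments
#'
#' Replaces real feature matrices with information-free stand-ins to test
#' whether assays add predictive power beyond entity identity: `one_hot`
#' gives each entity a unit indicator vector; `noise` gives each entity a
#' fixed random uniform \[0, 1\] vector of width `noise_dim`, reproducible
#' from the seed (the same entity always receives the same vector).
#'
#' @param ids Character vector of distinct entity identifiers.
#' @param mode `"one_hot"` or `"noise"`.
#' @param noise_dim Width of noise vectors (default 500).
#' @param seed Integer seed for noise generation.
#' @return A `feature_matrix` with rows in the order of `ids`.
#' @export
encode_entities <- function(ids, mode = c("one_hot", "noise"),
                            noise_dim = 500L, seed = 0L) {
  mode <- match.arg(mode)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("entity ids must be distinct")
  if (mode == "one_hot") {
    vals <- diag(length(ids))
    dimnames(vals) <- list(ids, paste0("onehot_", ids))
  } else {
    stopifnot(noise_dim >= 1)
    vals <- withr::with_seed(seed, {
      matrix(stats::runif(length(ids) * noise_dim), nrow = length(ids),
             dimnames = list(ids, paste0("noise_", seq_len(noise_dim))))
    })
  }
  feature_matrix(vals, state = c("raw", "imputed", "scaled"))
}

#' Read a feature matrix from delimited text
#'
#' First column holds row ids, header row holds feature names; empty
#' strings or `NA` tokens mark missing values. Separator autodetected
#' (comma or tab).
#'
#' @param path File path.
#' @param state State tags to attach (declare e.g. `log_transformed` for
#'   sources distributed pre-transformed).
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, state = "raw") {
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, na.strings = c("", "NA"),
                           strip.white = TRUE)
  feature_matrix(as.matrix(raw), state = state)
}

#' Write a feature matrix as delimited text
#'
#' @param m A `feature_matrix`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_feature_matrix <- function(m, path, sep = ",") {
  df <- data.frame(ID = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
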