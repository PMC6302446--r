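#' Assemble a modeling dataset from responses and feature matrices
#'
#' Joins a response table of per-tuple minimum-growth targets with
#' preprocessed cell-line feature matrices and a drug descriptor matrix,
#' producing the input structure consumed by the network. Single-agent
#' rows replicate the drug's descriptors into both slots.
#'
#' @param responses A `response_table`.
#' @param cell_features Named list of `feature_matrix` objects (rownames =
#'   cell ids), one per assay.
#' @param drug_features A `feature_matrix` of drug descriptors (rownames =
#'   drug ids).
#' @param drop_missing Drop response rows whose cell or drugs lack feature
#'   rows (with a warning) instead of erroring.
#' @return `list(x = list(cell, drug_a, drug_b), y, keys)` where `keys` is
#'   a data frame of (cell_id, drug_a, drug_b) aligned with `y`.
#' @export
assemble_dataset <- function(responses, cell_features, drug_features,
                             drop_missing = FALSE) {
  stopifnot(is.data.frame(responses), is.list(cell_features),
            length(cell_features) >= 1, !is.null(names(cell_features)))
  drug_b_eff <- ifelse(is.na(responses$drug_b), responses$drug_a,
                       responses$drug_b)
  ok <- rep(TRUE, nrow(responses))
  for (m in cell_features) ok <- ok & responses$cell_id %in% rownames(m)
  ok <- ok & responses$drug_a %in% rownames(drug_features) &
    drug_b_eff %in% rownames(drug_features)
  if (any(!ok)) {
    msg <- sprintf("%d response row(s) lack feature rows", sum(!ok))
    if (!drop_missing) stop(msg, "; set drop_missing = TRUE to skip them")
    warning(msg, "; dropped")
    responses <- responses[ok, , drop = FALSE]
    drug_b_eff <- drug_b_eff[ok]
  }
  cell <- lapply(cell_features, function(m) {
    unclass(m)[responses$cell_id, , drop = FALSE]
  })
  list(
    x = list(cell = cell,
             drug_a = unclass(drug_features)[responses$drug_a, ,
                                             drop = FALSE],
             drug_b = unclass(drug_features)[drug_b_eff, , drop = FALSE]),
    y = responses$min_growth,
    keys = data.frame(cell_id = responses$cell_id,
                      drug_a = responses$drug_a,
                      drug_b = responses$drug_b,
                      stringsAsFactors = FALSE)
  )
}

subset_dataset <- function(data, idx) {
  list(x = subset_input(data$x, idx), y = data$y[idx],
       keys = data$keys[idx, , drop = FALSE])
}

#' Stratified k-fold assignment for regression targets
#'
#' Bins the continuous targets into `bins` classes and deals each bin's
#' rows round-robin across the `k` folds, so per-fold class counts match
#' the global counts within one sample per class. This mirrors stratified
#' cross-validation for regression: fold loss estimates are not distorted
#' by uneven draws from a skewed response distribution.
#'
#' @param targets Numeric vector.
#' @param k Number of folds (>= 2).
#' @param bins Number of stratification classes.
#' @param seed Integer seed (shuffling within bins).
#' @param binning `"width"` (default): classes are equal-width intervals
#'   over the observed target range; `"frequency"`: equal-frequency
#'   (quantile) classes.
#' @return `list(fold, bin)`: integer vectors in `1..k` and `1..bins`
#'   aligned with `targets`.
#' @export
stratified_kfold <- function(targets, k = 5L, bins = 5L, seed = 1L,
                             binning = c("width", "frequency")) {
  binning <- match.arg(binning)
  n <- length(targets)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop(sprintf("need at least k = %d rows, got %d", k, n))
  if (binning == "width") {
    breaks <- seq(min(targets), max(targets), length.out = bins + 1L)
  } else {
    breaks <- stats::quantile(targets, probs = seq(0, 1, length.out = bins + 1L))
  }
  breaks <- unique(breaks)
  if (length(breaks) < 2) {         # constant targets: one class
    bin <- rep(1L, n)
  } else {
    bin <- as.integer(cut(targets, breaks = breaks, include.lowest = TRUE))
  }
  fold <- integer(n)
  withr::with_seed(seed, {
    for (b in unique(bin)) {
      idx <- which(bin == b)
      idx <- idx[sample.int(length(idx))]
      offset <- sample.int(k, 1L) - 1L
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    }
  })
  list(fold = fold, bin = bin)
}

#' Regression metrics for growth prediction
#'
#' Standard definitions: mean squared error, mean absolute error,
#' coefficient of determination `r2 = 1 - SS_res / SS_tot` (allowed to be
#' negative for predictors worse than the mean), and Pearson and Spearman
#' correlations. With constant truth the variance-based metrics are
#' undefined and reported as `NA`; MSE and MAE are still computed.
#'
#' @param y_true,y_pred Numeric vectors of equal nonzero length.
#' @return A `metric_report` list: `mse`, `mae`, `r2`, `pearson`,
#'   `spearman`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n == 0 || length(y_pred) != n) {
    stop("y_true and y_pred must have equal nonzero length")
  }
  resid <- y_pred - y_true
  mse <- mean(resid^2)
  mae <- mean(abs(resid))
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    r2 <- pearson <- spearman <- NA_real_
  } else {
    r2 <- 1 - sum(resid^2) / ss_tot
    pearson <- if (stats::sd(y_pred) == 0) NA_real_ else
      stats::cor(y_true, y_pred)
    spearman <- if (stats::sd(y_pred) == 0) NA_real_ else
      stats::cor(y_true, y_pred, method = "spearman")
  }
  structure(list(mse = mse, mae = mae, r2 = r2, pearson = pearson,
                 spearman = spearman), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("MSE %.4f  MAE %.4f  R2 %.4f  r %.4f  rho %.4f\n",
              x$mse, x$mae, x$r2, x$pearson, x$spearman))
  invisible(x)
}

#' Random-pair baseline: guessing from the response distribution
#'
#' The floor any informed model must beat: each "prediction" is an
#' independent draw from the empirical target distribution itself. For any
#' non-degenerate distribution the expected `r2` of this scheme is -1
#' (the expected squared difference of two independent draws is twice the
#' variance), so a model near `r2 = 0` has learned only the mean and one
#' near 1 has learned the response surface.
#'
#' @param targets Numeric vector of observed targets (>= 2 distinct values
#'   for a defined `r2`).
#' @param n_draws Number of random (truth, guess) pairs to sample, with
#'   replacement.
#' @param seed Integer seed.
#' @return A `metric_report` over the sampled pairs.
#' @export
random_pair_baseline <- function(targets, n_draws = 50000L, seed = 1L) {
  stopifnot(length(targets) >= 2, n_draws >= 1)
  withr::with_seed(seed, {
    y <- sample(targets, n_draws, replace = TRUE)
    guess <- sample(targets, n_draws, replace = TRUE)
    compute_metrics(y, guess)
  })
}

#' Stratified k-fold cross-validation of the growth model
#'
#' Treats each (cell, drug A, drug B) measurement as an independent data
#' point, stratifies folds on the binned target, trains one model per
#' fold, and predicts every row exactly once out-of-fold. Pooled
#' out-of-fold predictions support downstream ranking and error analyses.
#'
#' @param data Dataset from [assemble_dataset()].
#' @param config A [model_config()].
#' @param tcfg A [training_config()].
#' @param k,bins,binning Fold and stratification settings
#'   (see [stratified_kfold()]).
#' @param seed Integer seed for fold assignment and per-fold model seeds.
#' @param weights Optional per-row training loss weights (see
#'   [train_growth_model()]); subset per fold alongside the rows.
#' @param bag Number of independently seeded models trained per fold;
#'   their predictions are averaged. Bagging cancels a good part of the
#'   seed-to-seed prediction variance, which sharpens downstream rankings;
#'   1 (default) trains a single model per fold.
#' @return `list(fold_metrics, mean_metrics, oof)`: per-fold and averaged
#'   `metric_report`s plus the pooled out-of-fold prediction table
#'   (`cell_id, drug_a, drug_b, y_true, y_pred, fold`).
#' @export
cross_validate <- function(data, config = model_config(),
                           tcfg = training_config(), k = 5L, bins = 5L,
                           seed = 1L, binning = "width", bag = 1L,
                           weights = NULL) {
  stopifnot(bag >= 1)
  strat <- stratified_kfold(data$y, k = k, bins = bins, seed = seed,
                            binning = binning)
  feature_dims <- list(
    cell = vapply(data$x$cell, ncol, integer(1)),
    drug = ncol(data$x$drug_a)
  )
  oof <- data$keys
  oof$y_true <- data$y
  oof$y_pred <- NA_real_
  oof$fold <- strat$fold
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(strat$fold == f)
    train_idx <- which(strat$fold != f)
    res <- tryCatch({
      x_train <- subset_input(data$x, train_idx)
      x_test <- subset_input(data$x, test_idx)
      preds <- vapply(seq_len(bag), function(b) {
        s <- seed + 1000L * f + b
        tcfg_b <- tcfg
        tcfg_b$seed <- tcfg$seed + 1000L * f + b
        model <- build_growth_model(config, feature_dims, seed = s)
        fit <- train_growth_model(model, x_train, data$y[train_idx],
                                  tcfg_b, weights = weights[train_idx])
        predict(fit$model, x_test)
      }, numeric(length(test_idx)))
      rowMeans(matrix(preds, ncol = bag))
    }, error = function(e) {
      stop(sprintf("training failed in fold %d: %s", f, conditionMessage(e)))
    })
    oof$y_pred[test_idx] <- res
    fold_metrics[[f]] <- compute_metrics(data$y[test_idx], res)
  }
  mean_metrics <- as.list(colMeans(do.call(
    rbind, lapply(fold_metrics, function(m) unlist(m)))))
  class(mean_metrics) <- "metric_report"
  list(fold_metrics = fold_metrics, mean_metrics = mean_metrics, oof = oof)
}

#' Write pooled out-of-fold predictions as delimited text
#'
#' @param oof The `oof` table from [cross_validate()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_oof_predictions <- function(oof, path, sep = ",") {
  out <- data.frame(CELL = oof$cell_id, DRUG_A = oof$drug_a,
                    DRUG_B = oof$drug_b, Y_TRUE = oof$y_true,
                    Y_PRED = oof$y_pred, FOLD = oof$fold)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
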