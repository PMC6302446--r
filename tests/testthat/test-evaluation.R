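test_that("stratified folds deal each bin evenly across folds", {
  # 10 targets in 2 well-separated clusters of 5, k = 5: every fold gets
  # exactly one row from each cluster
  targets <- c(seq(0, 0.04, length.out = 5), seq(1, 1.04, length.out = 5))
  s <- stratified_kfold(targets, k = 5, bins = 2, seed = 1)
  tab <- table(s$fold, s$bin)
  expect_true(all(tab == 1))
  expect_setequal(s$fold, 1:5)
})

test_that("degenerate targets still give balanced folds; k > n errors", {
  s <- stratified_kfold(rep(0.5, 11), k = 5, seed = 2)
  expect_lte(diff(range(table(s$fold))), 1)
  expect_error(stratified_kfold(1:3, k = 5), "at least")
  expect_error(stratified_kfold(1:10, k = 1), "k must be")
})

test_that("per-bin per-fold proportions hold within one sample (property)", {
  for (i in 1:200) {
    n <- sample(20:150, 1)
    targets <- stats::rnorm(n)
    binning <- if (i %% 2) "width" else "frequency"
    s <- stratified_kfold(targets, k = 5, bins = 5, seed = i,
                          binning = binning)
    tab <- table(factor(s$fold, levels = 1:5), s$bin)
    expect_true(all(apply(tab, 2, function(x) diff(range(x)) <= 1)))
    expect_equal(sum(tab), n)  # folds partition the rows exactly
  }
})

test_that("fold assignment is reproducible from its seed", {
  t <- stats::runif(97)
  expect_identical(stratified_kfold(t, seed = 42),
                   stratified_kfold(t, seed = 42))
})

test_that("metrics follow the standard definitions", {
  y <- c(0.1, -0.4, 0.9, 0.3)
  perfect <- compute_metrics(y, y)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$pearson, 1)
  anti <- compute_metrics(c(0, 1), c(1, 0))
  expect_equal(anti$mse, 1)
  expect_equal(anti$mae, 1)
  expect_equal(anti$r2, -3)
  flat <- compute_metrics(c(1, 1, 1), c(0.9, 1, 1.1))
  expect_true(is.na(flat$r2))
  expect_gt(flat$mse, 0)
})

test_that("metrics agree with direct-formula oracles on random vectors", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      y <- stats::rnorm(50)
      p <- stats::rnorm(50)
    })
    m <- compute_metrics(y, p)
    expect_equal(m$mse, sum((y - p)^2) / 50, tolerance = 1e-10)
    expect_equal(m$mae, sum(abs(y - p)) / 50, tolerance = 1e-10)
    expect_equal(m$r2, 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
    expect_equal(m$pearson, stats::cor(y, p), tolerance = 1e-10)
    expect_equal(m$spearman, stats::cor(rank(y), rank(p)),
                 tolerance = 1e-10)
  }
})

test_that("random-pair baseline MAE matches exhaustive pair enumeration", {
  withr::with_seed(30, targets <- stats::runif(150, -1, 1))
  # expected |y - y'| over independent draws = mean over all n^2 pairs
  exhaustive <- mean(abs(outer(targets, targets, "-")))
  b <- random_pair_baseline(targets, n_draws = 50000, seed = 1)
  expect_equal(b$mae, exhaustive, tolerance = 0.03)
  # two-point equiprobable distribution: mae -> 0.5
  b2 <- random_pair_baseline(rep(c(0, 1), 100), n_draws = 50000, seed = 2)
  expect_equal(b2$mae, 0.5, tolerance = 0.02)
  expect_identical(unclass(random_pair_baseline(targets, 1000, seed = 9)),
                   unclass(random_pair_baseline(targets, 1000, seed = 9)))
})

test_that("cross-validation predicts every row exactly once out-of-fold", {
  # perfect-memorization toy: the target itself is a feature
  withr::with_seed(31, {
    n <- 150
    y <- stats::runif(n, -1, 1)
    ds <- list(x = list(cell = list(assay = cbind(y, matrix(
                 stats::runif(n * 3), n))),
               drug_a = matrix(stats::runif(n * 4), n),
               drug_b = matrix(stats::runif(n * 4), n)),
               y = y,
               keys = data.frame(cell_id = sprintf("C%d", seq_len(n)),
                                 drug_a = "A", drug_b = "B"))
  })
  cv <- cross_validate(ds,
                       model_config(encoder_layers = c(16, 16),
                                    tower_layers = c(16, 16, 16)),
                       training_config(epochs = 60, batch_size = 16,
                                       seed = 1),
                       k = 5, seed = 1)
  expect_equal(nrow(cv$oof), 150)
  expect_false(anyNA(cv$oof$y_pred))
  expect_setequal(cv$oof$fold, 1:5)
  pooled <- compute_metrics(cv$oof$y_true, cv$oof$y_pred)
  expect_gt(pooled$r2, 0.9)
})

test_that("out-of-fold predictions write with the documented columns", {
  oof <- data.frame(cell_id = "C1", drug_a = "A", drug_b = "B",
                    y_true = 0.2, y_pred = 0.25, fold = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_oof_predictions(oof, path)
  back <- utils::read.csv(path)
  expect_named(back, c("CELL", "DRUG_A", "DRUG_B", "Y_TRUE", "Y_PRED",
                       "FOLD"))
})
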