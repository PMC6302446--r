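tiny_dims <- list(cell = c(assay = 4L), drug = 5L)

test_that("configuration rules: residual widths, zero feature types", {
  cfg <- model_config(tower_layers = c(8, 8, 8), residual = TRUE)
  m <- build_growth_model(cfg, tiny_dims, seed = 1)
  # skips exist between the equal-width adjacent tower layers
  expect_false(m$tower[[1]]$skip)  # tower input is wider than 8
  expect_true(m$tower[[2]]$skip)
  expect_true(m$tower[[3]]$skip)
  expect_error(model_config(tower_layers = c(8, 4), residual = TRUE),
               "residual")
  expect_error(build_growth_model(cfg, list(cell = NULL, drug = 5)),
               "configuration error")
  expect_gt(m$n_params, 0)
})

test_that("weight sharing: exactly one drug encoder serves both slots", {
  m <- build_growth_model(tiny_model_config(), tiny_dims, seed = 1)
  x <- tiny_inputs(6)
  fw <- comboscreen:::model_forward(m, x)
  # same parameters applied to both slots: feeding slot B's descriptors
  # through slot A's path gives slot B's encoding
  swapped <- x
  swapped$drug_a <- x$drug_b
  fw2 <- comboscreen:::model_forward(m, swapped)
  expect_equal(fw2$enc_a$out, fw$enc_b$out)
})

test_that("predictions are finite, batch-order invariant, and duplicate-consistent", {
  m <- build_growth_model(tiny_model_config(), tiny_dims, seed = 2)
  x <- tiny_inputs(10, seed = 3)
  p <- predict(m, x)
  expect_length(p, 10)
  expect_true(all(is.finite(p)))
  perm <- sample(10)
  expect_equal(predict(m, comboscreen:::subset_input(x, perm)), p[perm],
               tolerance = 1e-12)
  dup <- comboscreen:::subset_input(x, c(1, 1))
  pd <- predict(m, dup)
  expect_equal(pd[1], pd[2])
  bad <- x
  bad$drug_a <- x$drug_a[, 1:3]
  expect_error(predict(m, bad), "width mismatch")
})

test_that("slot-averaged inference is drug-order symmetric; summed encodings exactly so", {
  x <- tiny_inputs(100, seed = 4)
  swapped <- x
  swapped$drug_a <- x$drug_b
  swapped$drug_b <- x$drug_a
  m <- build_growth_model(tiny_model_config(), tiny_dims, seed = 5)
  expect_lt(max(abs(predict(m, x) - predict(m, swapped))), 1e-6)
  # the single ordered pass is NOT symmetric (shared weights alone do not
  # make concatenation order-invariant)
  expect_gt(max(abs(predict(m, x, slot_average = FALSE) -
                      predict(m, swapped, slot_average = FALSE))), 1e-8)
  for (mode in c("sum", "sum_prod")) {
    ms <- build_growth_model(tiny_model_config(symmetrize = mode),
                             tiny_dims, seed = 5)
    expect_equal(predict(ms, x, slot_average = FALSE),
                 predict(ms, swapped, slot_average = FALSE))
  }
})

test_that("single-drug prediction replicates descriptors into both slots", {
  m <- build_growth_model(tiny_model_config(), tiny_dims, seed = 6)
  x <- tiny_inputs(8, seed = 7)
  single <- predict_single_drug(m, x$cell, x$drug_a)
  both <- predict(m, list(cell = x$cell, drug_a = x$drug_a,
                          drug_b = x$drug_a))
  expect_identical(single, both)
  # identical descriptor vectors give identical single-agent predictions
  same <- x$drug_a[c(1, 1), , drop = FALSE]
  ps <- predict_single_drug(m, comboscreen:::subset_input(x, c(1, 1))$cell,
                            same)
  expect_equal(ps[1], ps[2])
  expect_error(predict_single_drug(m, x$cell, x$drug_a[, 1:2]), "mismatch")
})

test_that("analytic gradients match central finite differences", {
  for (mode in c("none", "sum", "sum_prod")) {
  cfg <- model_config(encoder_layers = c(3, 3), tower_layers = c(4, 4),
                      residual = TRUE, symmetrize = mode)
  dims <- list(cell = c(a1 = 4L, a2 = 3L), drug = 5L)
  m <- build_growth_model(cfg, dims, seed = 8)
  withr::with_seed(9, {
    x <- list(cell = list(a1 = matrix(stats::rnorm(24), 6),
                          a2 = matrix(stats::rnorm(18), 6)),
              drug_a = matrix(stats::rnorm(30), 6),
              drug_b = matrix(stats::rnorm(30), 6))
    y <- stats::rnorm(6)
  })
  loss_at <- function(model) {
    fw <- comboscreen:::model_forward(model, x)
    mean((fw$yhat - y)^2)
  }
  fw <- comboscreen:::model_forward(m, x)
  gr <- comboscreen:::model_backward(m, x, fw, 2 * (fw$yhat - y) / 6)
  eps <- 1e-6
  check_entry <- function(get, set, analytic) {
    num <- (loss_at(set(m, get(m) + eps)) -
              loss_at(set(m, get(m) - eps))) / (2 * eps)
    expect_lt(abs(analytic - num), 1e-6 + 1e-4 * abs(num))
  }
  # a tower weight
  check_entry(function(mo) mo$tower[[2]]$W[2, 3],
              function(mo, v) { mo$tower[[2]]$W[2, 3] <- v; mo },
              gr$tower[[2]]$W[2, 3])
  # an encoder weight
  check_entry(function(mo) mo$encoders$a2[[1]]$W[1, 2],
              function(mo, v) { mo$encoders$a2[[1]]$W[1, 2] <- v; mo },
              gr$encoders$a2[[1]]$W[1, 2])
  # a shared drug-encoder weight: gradient must sum both slot passes
  check_entry(function(mo) mo$drug_encoder[[1]]$W[3, 1],
              function(mo, v) { mo$drug_encoder[[1]]$W[3, 1] <- v; mo },
              gr$drug_encoder[[1]]$W[3, 1])
  # a bias and the output weight
  check_entry(function(mo) mo$tower[[1]]$b[2],
              function(mo, v) { mo$tower[[1]]$b[2] <- v; mo },
              gr$tower[[1]]$b[2])
  check_entry(function(mo) mo$out$W[1, 1],
              function(mo, v) { mo$out$W[1, 1] <- v; mo },
              gr$out$W[1, 1])
  }
})

test_that("training reduces MSE on a learnable synthetic set", {
  withr::with_seed(10, {
    n <- 200
    x <- list(cell = list(assay = matrix(stats::runif(n * 4), n)),
              drug_a = matrix(stats::runif(n * 5), n),
              drug_b = matrix(stats::runif(n * 5), n))
    y <- 0.8 * x$cell$assay[, 1] - 0.5 * (x$drug_a[, 2] + x$drug_b[, 2]) / 2
  })
  m <- build_growth_model(tiny_model_config(), tiny_dims, seed = 11)
  fit <- train_growth_model(m, x, y, training_config(epochs = 30, seed = 1))
  expect_lt(utils::tail(fit$history$train_mse, 1),
            fit$history$train_mse[1])
  expect_equal(nrow(fit$history), 30)
})

test_that("learning rate zero leaves parameters unchanged with flat history", {
  m <- build_growth_model(tiny_model_config(), tiny_dims, seed = 12)
  x <- tiny_inputs(40, seed = 13)
  y <- rep(0.2, 40)
  fit <- train_growth_model(m, x, y,
                            training_config(epochs = 5, base_lr = 0,
                                            reduce_on_plateau = NULL,
                                            seed = 2))
  expect_identical(fit$model$tower, m$tower)
  expect_identical(fit$model$out, m$out)
  expect_equal(diff(range(fit$history$train_mse)), 0, tolerance = 1e-12)
})

test_that("training is repeatable from identical seeds", {
  x <- tiny_inputs(60, seed = 14)
  y <- withr::with_seed(15, stats::runif(60, -1, 1))
  run <- function() {
    m <- build_growth_model(tiny_model_config(), tiny_dims, seed = 16)
    train_growth_model(m, x, y, training_config(epochs = 8, seed = 3))
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$tower, f2$model$tower)
})

test_that("loss weights are normalized and zero-weight rows do not steer training", {
  x <- tiny_inputs(40, seed = 30)
  y <- withr::with_seed(31, stats::runif(40, -1, 1))
  tcfg <- training_config(epochs = 5, seed = 5)
  base <- function() build_growth_model(tiny_model_config(), tiny_dims,
                                        seed = 32)
  f_plain <- train_growth_model(base(), x, y, tcfg)
  # uniform weights of any scale are equivalent to no weights
  f_scaled <- train_growth_model(base(), x, y, tcfg,
                                 weights = rep(7, 40))
  expect_identical(f_plain$model$tower, f_scaled$model$tower)
  # rows with zero weight contribute no gradient: corrupting them does
  # not change the fitted parameters
  y_bad <- y
  y_bad[1:5] <- 1
  w <- rep(1, 40)
  w[1:5] <- 0
  f_zero <- train_growth_model(base(), x, y_bad, tcfg, weights = w)
  f_ref <- train_growth_model(base(), x, y, tcfg, weights = w)
  expect_identical(f_zero$model$tower, f_ref$model$tower)
  expect_error(train_growth_model(base(), x, y, tcfg, weights = rep(0, 40)))
})

test_that("non-finite loss aborts with a diagnostic", {
  m <- build_growth_model(tiny_model_config(), tiny_dims, seed = 17)
  x <- tiny_inputs(20, seed = 18)
  expect_error(
    train_growth_model(m, x, rep(0.5, 20),
                       training_config(epochs = 5, base_lr = 1e80,
                                       seed = 4)),
    "non-finite")
})

test_that("deep residual towers train stably", {
  withr::with_seed(20, {
    n <- 150
    x <- list(cell = list(assay = matrix(stats::runif(n * 4), n)),
              drug_a = matrix(stats::runif(n * 5), n),
              drug_b = matrix(stats::runif(n * 5), n))
    y <- sin(3 * x$cell$assay[, 1]) * x$drug_a[, 1]
  })
  cfg <- model_config(encoder_layers = c(8, 8),
                      tower_layers = rep(16L, 12), residual = TRUE)
  m <- build_growth_model(cfg, tiny_dims, seed = 1)
  fit <- train_growth_model(m, x, y, training_config(epochs = 25, seed = 1))
  expect_true(all(is.finite(fit$history$train_mse)))
  expect_lt(utils::tail(fit$history$train_mse, 1),
            0.25 * fit$history$train_mse[1])
  # activation variance stays bounded at init despite 12 stacked skips
  fw <- comboscreen:::model_forward(m, x)
  expect_lt(stats::var(fw$yhat), 100 * stats::var(y))
})

test_that("checkpoints round-trip weights and configuration", {
  m <- build_growth_model(tiny_model_config(), tiny_dims, seed = 21)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$tower, m$tower)
  x <- tiny_inputs(5, seed = 22)
  expect_identical(predict(back, x), predict(m, x))
})
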