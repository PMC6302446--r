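#' Model configuration for the two-level response network
#'
#' The network has two levels trained jointly: per-feature-type encoder
#' submodels (one feedforward stack per omics assay plus a single drug
#' descriptor encoder whose weights are shared between the two drug slots),
#' and a growth-prediction tower that consumes the concatenated encodings
#' and emits a scalar growth fraction. Adjacent layers of equal width are
#' linked by residual skip connections when `residual = TRUE`.
#'
#' @param encoder_layers Integer vector of encoder hidden widths (applied
#'   to every feature-type encoder), or a named list with one vector per
#'   input name to size them individually. Guidance at full scale is two or
#'   more hidden layers of > 1000 neurons; the defaults here are
#'   test-scale.
#' @param tower_layers Integer vector of growth-tower hidden widths
#'   (guidance: three or more layers).
#' @param residual Link equal-width adjacent hidden layers with additive
#'   skips. Requesting residual connections in a stack whose adjacent
#'   hidden widths differ is a configuration error: equal-width (rather
#'   than pyramid) stacks are preferred precisely so the skips exist.
#' @param activation Hidden nonlinearity; only `"relu"` is provided.
#' @param dropout Dropout probability in \[0, 1) applied to hidden
#'   activations during training (inverted dropout); 0 disables.
#' @param symmetrize How the two drug encodings enter the tower:
#'   `"none"` (plain ordered concatenation, the default),
#'   `"sum"` (elementwise sum of the two encodings, order-invariant by
#'   construction), `"sum_prod"` (the sum next to the elementwise
#'   product; also order-invariant, and the product term hands the tower a
#'   ready-made pair-conjunction feature, which helps it learn
#'   pair-specific interaction effects), or `"interact"` (`"sum_prod"`
#'   plus elementwise products of the pooled cell encoding with each
#'   drug-sum coordinate; requires all encoder output widths equal). The
#'   product blocks reflect the multiplicative structure of combination
#'   response — growth under two agents is expected multiplicative in the
#'   single-agent growths, each a cell-by-drug interaction.
#' @return A `model_config` list.
#' @export
model_config <- function(encoder_layers = c(64L, 64L),
                         tower_layers = c(64L, 64L, 64L),
                         residual = TRUE,
                         activation = "relu",
                         dropout = 0,
                         symmetrize = c("none", "sum", "sum_prod",
                                        "interact")) {
  symmetrize <- match.arg(symmetrize)
  activation <- match.arg(activation, "relu")
  stopifnot(dropout >= 0, dropout < 1)
  check_widths <- function(w, what) {
    w <- as.integer(w)
    if (!length(w) || any(w < 1L)) stop(what, " widths must be positive")
    if (residual && length(w) > 1L && any(diff(w) != 0L)) {
      stop("residual connections require equal adjacent widths in ", what,
           " (got ", paste(w, collapse = ","), ")")
    }
    w
  }
  if (is.list(encoder_layers)) {
    encoder_layers <- lapply(encoder_layers, check_widths, "encoder")
  } else {
    encoder_layers <- check_widths(encoder_layers, "encoder")
  }
  structure(list(encoder_layers = encoder_layers,
                 tower_layers = check_widths(tower_layers, "tower"),
                 residual = residual, activation = activation,
                 dropout = dropout, symmetrize = symmetrize),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs Number of passes over the training set (full-scale
#'   guidance is at least 100; test-scale runs use far fewer).
#' @param batch_size Minibatch size.
#' @param optimizer Only `"adam"` is provided (the recommended optimizer).
#' @param base_lr Base learning rate.
#' @param reduce_on_plateau `c(factor, patience)`: multiply the learning
#'   rate by `factor` when the monitored loss has not improved for
#'   `patience` epochs (improves validation loss); `NULL` disables.
#' @param warmup_epochs Linear learning-rate ramp from 0 over this many
#'   initial epochs (useful with large batches); 0 disables.
#' @param val_frac Fraction of rows held out inside `train_growth_model()`
#'   to monitor validation loss; 0 monitors training loss instead.
#' @param seed Integer seed controlling shuffling and dropout; together
#'   with the build seed it makes runs repeatable.
#' @return A `training_config` list. The optimized loss is always mean
#'   squared error.
#' @export
training_config <- function(epochs = 30L, batch_size = 32L,
                            optimizer = "adam", base_lr = 1e-3,
                            reduce_on_plateau = c(0.5, 5),
                            warmup_epochs = 0L, val_frac = 0,
                            seed = 1L) {
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(epochs >= 1, batch_size >= 1, base_lr >= 0,
            warmup_epochs >= 0, val_frac >= 0, val_frac < 1)
  if (!is.null(reduce_on_plateau)) {
    stopifnot(length(reduce_on_plateau) == 2,
              reduce_on_plateau[1] > 0, reduce_on_plateau[1] < 1,
              reduce_on_plateau[2] >= 1)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer, base_lr = base_lr,
                 reduce_on_plateau = reduce_on_plateau,
                 warmup_epochs = as.integer(warmup_epochs),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "training_config")
}

# -- dense stacks -------------------------------------------------------

# He (fan-in) initialization; biases start at zero. Layers feeding a
# residual skip get a down-scaled branch init so activation variance stays
# bounded as skips accumulate (one-layer blocks double variance under
# plain He init, which cripples deep towers early in training).
init_stack <- function(d_in, widths, residual) {
  layers <- vector("list", length(widths))
  prev <- d_in
  for (i in seq_along(widths)) {
    w <- widths[i]
    skip <- residual && prev == w
    gain <- if (skip) sqrt(2 / prev) / 4 else sqrt(2 / prev)
    layers[[i]] <- list(
      W = matrix(stats::rnorm(prev * w, sd = gain), prev, w),
      b = numeric(w),
      skip = skip
    )
    prev <- w
  }
  layers
}

relu <- function(z) (z > 0) * z

# forward pass through a dense stack; returns output and caches for backprop
stack_forward <- function(layers, X, dropout = 0, train = FALSE) {
  caches <- vector("list", length(layers))
  H <- X
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    Z <- H %*% l$W
    Z <- Z + rep(l$b, each = nrow(Z))
    A <- relu(Z)
    if (l$skip) A <- A + H
    mask <- NULL
    if (train && dropout > 0) {
      mask <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A))
      A <- A * mask / (1 - dropout)
    }
    caches[[i]] <- list(H_in = H, Z = Z, mask = mask)
    H <- A
  }
  list(out = H, caches = caches)
}

# backprop through a dense stack; G is dLoss/d(out)
stack_backward <- function(layers, caches, G, dropout = 0) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cache <- caches[[i]]
    if (!is.null(cache$mask)) G <- G * cache$mask / (1 - dropout)
    G_skip <- if (l$skip) G else 0
    dZ <- G * (cache$Z > 0)
    grads[[i]] <- list(W = crossprod(cache$H_in, dZ), b = colSums(dZ))
    G <- tcrossprod(dZ, l$W) + G_skip
  }
  list(grads = grads, G_in = G)
}

n_params_stack <- function(layers) {
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# -- model construction -------------------------------------------------

#' Build the two-level growth prediction network
#'
#' Instantiates encoder stacks for each configured cell feature type, a
#' single drug descriptor encoder serving both drug slots (all weights
#' shared by construction), and the growth tower over the concatenated
#' encodings.
#'
#' @param config A [model_config()].
#' @param feature_dims `list(cell = c(<assay> = width, ...), drug = width)`
#'   declaring the input width of every feature type. At least one cell
#'   feature type is required.
#' @param seed Integer seed for weight initialization.
#' @return A `combo_model` with a reported parameter count
#'   (`model$n_params`).
#' @export
build_growth_model <- function(config, feature_dims, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  cell_dims <- feature_dims$cell
  drug_dim <- feature_dims$drug
  if (is.null(cell_dims) || !length(cell_dims) || is.null(names(cell_dims))) {
    stop("configuration error: at least one named cell feature type is required")
  }
  if (is.null(drug_dim) || drug_dim < 1) {
    stop("configuration error: drug descriptor width required")
  }
  enc_widths <- function(name) {
    if (is.list(config$encoder_layers)) {
      w <- config$encoder_layers[[name]]
      if (is.null(w)) stop("no encoder widths configured for '", name, "'")
      w
    } else config$encoder_layers
  }
  withr::with_seed(seed, {
    encoders <- lapply(names(cell_dims), function(nm) {
      init_stack(cell_dims[[nm]], enc_widths(nm), config$residual)
    })
    names(encoders) <- names(cell_dims)
    drug_encoder <- init_stack(drug_dim, enc_widths("drug"),
                               config$residual)
    enc_out <- vapply(encoders, function(e) ncol(e[[length(e)]]$W),
                      numeric(1))
    drug_out <- ncol(drug_encoder[[length(drug_encoder)]]$W)
    drug_block <- switch(config$symmetrize,
                         sum = drug_out,
                         sum_prod = 2 * drug_out,
                         interact = 3 * drug_out,
                         none = 2 * drug_out)
    if (config$symmetrize == "interact" &&
        any(enc_out != drug_out)) {
      stop("symmetrize = 'interact' needs equal encoder output widths ",
           "for all feature types")
    }
    tower_in <- sum(enc_out) + drug_block
    tower <- init_stack(tower_in, config$tower_layers, config$residual)
    d_top <- utils::tail(config$tower_layers, 1)
    out_layer <- list(W = matrix(stats::rnorm(d_top, sd = sqrt(1 / d_top)),
                                 d_top, 1),
                      b = 0)
    model <- list(config = config, feature_dims = feature_dims,
                  encoders = encoders, drug_encoder = drug_encoder,
                  tower = tower, out = out_layer,
                  enc_out = enc_out, drug_out = drug_out)
    model$n_params <- sum(vapply(encoders, n_params_stack, numeric(1))) +
      n_params_stack(drug_encoder) + n_params_stack(tower) +
      length(out_layer$W) + 1
    class(model) <- "combo_model"
    model
  })
}

#' @export
print.combo_model <- function(x, ...) {
  cat("Two-level residual growth model\n")
  cat("  cell encoders:", paste(names(x$encoders), collapse = ", "), "\n")
  cat("  drug encoder : shared across both slots\n")
  cat("  symmetrize   :", x$config$symmetrize, "\n")
  cat("  parameters   :", format(x$n_params, big.mark = ","), "\n")
  invisible(x)
}

check_widths_match <- function(model, x) {
  cd <- model$feature_dims$cell
  for (nm in names(cd)) {
    m <- x$cell[[nm]]
    if (is.null(m)) stop("missing cell feature input '", nm, "'")
    if (ncol(m) != cd[[nm]]) {
      stop(sprintf("width mismatch for '%s': got %d, model expects %d",
                   nm, ncol(m), cd[[nm]]))
    }
  }
  for (slot in c("drug_a", "drug_b")) {
    if (ncol(x[[slot]]) != model$feature_dims$drug) {
      stop(sprintf("width mismatch for %s: got %d, model expects %d",
                   slot, ncol(x[[slot]]), model$feature_dims$drug))
    }
  }
  invisible(TRUE)
}

# single ordered forward pass; returns prediction and caches when training
model_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  p <- if (train) cfg$dropout else 0
  enc <- lapply(names(model$encoders), function(nm) {
    stack_forward(model$encoders[[nm]], x$cell[[nm]], p, train)
  })
  names(enc) <- names(model$encoders)
  enc_a <- stack_forward(model$drug_encoder, x$drug_a, p, train)
  enc_b <- stack_forward(model$drug_encoder, x$drug_b, p, train)
  cell_pool <- if (cfg$symmetrize == "interact") {
    Reduce(`+`, lapply(enc, `[[`, "out"))
  }
  drug_block <- switch(cfg$symmetrize,
                       sum = enc_a$out + enc_b$out,
                       sum_prod = cbind(enc_a$out + enc_b$out,
                                        enc_a$out * enc_b$out),
                       interact = cbind(enc_a$out + enc_b$out,
                                        enc_a$out * enc_b$out,
                                        cell_pool * (enc_a$out + enc_b$out)),
                       none = cbind(enc_a$out, enc_b$out))
  H <- do.call(cbind, c(lapply(enc, `[[`, "out"), list(drug_block)))
  tw <- stack_forward(model$tower, H, p, train)
  yhat <- as.numeric(tw$out %*% model$out$W + model$out$b)
  list(yhat = yhat, enc = enc, enc_a = enc_a, enc_b = enc_b,
       cell_pool = cell_pool, tower = tw)
}

# backprop; dy is dLoss/dyhat (length n). Returns gradients mirroring the
# parameter structure; the two drug-slot passes share one gradient (summed).
model_backward <- function(model, x, fw, dy) {
  cfg <- model$config
  p <- cfg$dropout
  dtop <- matrix(dy, ncol = 1)
  g_out <- list(W = crossprod(fw$tower$out, dtop), b = sum(dtop))
  G <- dtop %*% t(model$out$W)
  tw <- stack_backward(model$tower, fw$tower$caches, G, p)
  # split tower-input gradient into per-block column ranges
  offsets <- cumsum(c(0, model$enc_out))
  base <- offsets[length(offsets)]
  dblk <- function(j) {
    tw$G_in[, base + (j - 1L) * model$drug_out + seq_len(model$drug_out),
            drop = FALSE]
  }
  G_cell_extra <- NULL
  if (cfg$symmetrize == "sum") {
    Ga <- Gb <- dblk(1)
  } else if (cfg$symmetrize == "sum_prod") {
    Gs <- dblk(1)
    Gp <- dblk(2)
    Ga <- Gs + Gp * fw$enc_b$out
    Gb <- Gs + Gp * fw$enc_a$out
  } else if (cfg$symmetrize == "interact") {
    Gs <- dblk(1)
    Gp <- dblk(2)
    Gi <- dblk(3)
    sum_ab <- fw$enc_a$out + fw$enc_b$out
    Ga <- Gs + Gp * fw$enc_b$out + Gi * fw$cell_pool
    Gb <- Gs + Gp * fw$enc_a$out + Gi * fw$cell_pool
    G_cell_extra <- Gi * sum_ab    # flows into every cell encoder's pool
  } else {
    Ga <- dblk(1)
    Gb <- dblk(2)
  }
  g_enc <- vector("list", length(model$encoders))
  names(g_enc) <- names(model$encoders)
  for (i in seq_along(model$encoders)) {
    cols <- (offsets[i] + 1):offsets[i + 1]
    G_i <- tw$G_in[, cols, drop = FALSE]
    if (!is.null(G_cell_extra)) G_i <- G_i + G_cell_extra
    bk <- stack_backward(model$encoders[[i]], fw$enc[[i]]$caches, G_i, p)
    g_enc[[i]] <- bk$grads
  }
  bka <- stack_backward(model$drug_encoder, fw$enc_a$caches, Ga, p)
  bkb <- stack_backward(model$drug_encoder, fw$enc_b$caches, Gb, p)
  g_drug <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   bka$grads, bkb$grads, SIMPLIFY = FALSE)
  list(encoders = g_enc, drug_encoder = g_drug, tower = tw$grads,
       out = g_out)
}

# -- Adam ---------------------------------------------------------------

adam_init_stack <- function(layers) {
  lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

# in-place Adam step over every layer of a stack; layers and state must be
# uniquely referenced (the training loop duplicates the model up front)
adam_step_stack <- function(layers, grads, state, lr, t,
                            b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    s <- state[[i]]
    adam_update(layers[[i]]$W, s$mW, s$vW, g$W, lr, corr1, corr2,
                b1, b2, eps)
    adam_update(layers[[i]]$b, s$mb, s$vb, g$b, lr, corr1, corr2,
                b1, b2, eps)
  }
  invisible(NULL)
}

# -- training -----------------------------------------------------------

subset_input <- function(x, idx) {
  list(cell = lapply(x$cell, function(m) m[idx, , drop = FALSE]),
       drug_a = x$drug_a[idx, , drop = FALSE],
       drug_b = x$drug_b[idx, , drop = FALSE])
}

#' Train the growth model by minibatch Adam on mean squared error
#'
#' @param model A `combo_model` from [build_growth_model()].
#' @param x Input list `list(cell = list(<assay matrices>), drug_a, drug_b)`
#'   with one row per sample; single-agent samples carry the same
#'   descriptor row in both drug slots.
#' @param y Numeric targets (minimum growth fractions in \[-1, 1\]).
#' @param tcfg A [training_config()].
#' @param x_val,y_val Optional explicit validation set; otherwise
#'   `tcfg$val_frac` rows are split off when positive.
#' @param weights Optional non-negative per-row loss weights (weighted
#'   MSE, normalized to mean 1). Useful when some rows anchor many
#'   downstream quantities — e.g. single-agent responses, which enter the
#'   expected-growth reference of every pair score involving that drug.
#' @return `list(model, history)` where `history` is a data frame of
#'   per-epoch learning rate and train/validation MSE. Training aborts with
#'   a diagnostic if the loss becomes non-finite. Runs are repeatable given
#'   identical seeds (single-threaded deterministic execution).
#' @export
train_growth_model <- function(model, x, y, tcfg = training_config(),
                               x_val = NULL, y_val = NULL,
                               weights = NULL) {
  stopifnot(inherits(model, "combo_model"),
            inherits(tcfg, "training_config"))
  check_widths_match(model, x)
  n <- length(y)
  stopifnot(nrow(x$drug_a) == n)
  if (is.null(weights)) {
    weights <- rep(1, n)
  } else {
    stopifnot(length(weights) == n, all(weights >= 0), any(weights > 0))
    weights <- weights / mean(weights)
  }
  withr::with_seed(tcfg$seed, {
    if (is.null(x_val) && tcfg$val_frac > 0) {
      n_val <- max(1L, floor(tcfg$val_frac * n))
      vidx <- sample.int(n, n_val)
      x_val <- subset_input(x, vidx)
      y_val <- y[vidx]
      x <- subset_input(x, -vidx)
      y <- y[-vidx]
      weights <- weights[-vidx]
      n <- length(y)
    }
    # parameters are updated in place during training; duplicate them so
    # the caller's model object is left untouched
    model[c("encoders", "drug_encoder", "tower", "out")] <-
      unserialize(serialize(
        model[c("encoders", "drug_encoder", "tower", "out")], NULL))
    opt <- list(encoders = lapply(model$encoders, adam_init_stack),
                drug_encoder = adam_init_stack(model$drug_encoder),
                tower = adam_init_stack(model$tower),
                out = list(mW = model$out$W * 0, vW = model$out$W * 0,
                           mb = model$out$b * 0, vb = model$out$b * 0))
    history <- data.frame(epoch = integer(), lr = numeric(),
                          train_mse = numeric(), val_mse = numeric())
    lr_now <- tcfg$base_lr
    best_monitor <- Inf
    stale <- 0L
    step <- 0L
    for (epoch in seq_len(tcfg$epochs)) {
      lr_eff <- lr_now
      if (tcfg$warmup_epochs > 0 && epoch <= tcfg$warmup_epochs) {
        lr_eff <- lr_now * epoch / tcfg$warmup_epochs
      }
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / tcfg$batch_size))
      sse <- 0
      for (bi in batches) {
        xb <- subset_input(x, bi)
        fw <- model_forward(model, xb, train = TRUE)
        resid <- fw$yhat - y[bi]
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d (lr=%g); reduce the learning rate",
                       epoch, lr_eff))
        }
        sse <- sse + sum(resid^2)
        step <- step + 1L
        if (lr_eff > 0) {
          gr <- model_backward(model, xb, fw,
                               2 * weights[bi] * resid / length(bi))
          for (nm in names(model$encoders)) {
            adam_step_stack(model$encoders[[nm]], gr$encoders[[nm]],
                            opt$encoders[[nm]], lr_eff, step)
          }
          adam_step_stack(model$drug_encoder, gr$drug_encoder,
                          opt$drug_encoder, lr_eff, step)
          adam_step_stack(model$tower, gr$tower, opt$tower, lr_eff, step)
          c1 <- 1 - 0.9^step
          c2 <- 1 - 0.999^step
          adam_update(model$out$W, opt$out$mW, opt$out$vW, gr$out$W,
                      lr_eff, c1, c2, 0.9, 0.999, 1e-8)
          adam_update(model$out$b, opt$out$mb, opt$out$vb,
                      as.numeric(gr$out$b), lr_eff, c1, c2, 0.9, 0.999,
                      1e-8)
        }
      }
      train_mse <- sse / n
      val_mse <- NA_real_
      if (!is.null(x_val)) {
        pv <- model_forward(model, x_val)$yhat
        val_mse <- mean((pv - y_val)^2)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, lr = lr_eff,
                                  train_mse = train_mse, val_mse = val_mse))
      if (!is.null(tcfg$reduce_on_plateau)) {
        monitor <- if (!is.null(x_val)) val_mse else train_mse
        if (monitor < best_monitor - 1e-12) {
          best_monitor <- monitor
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= tcfg$reduce_on_plateau[2]) {
            lr_now <- lr_now * tcfg$reduce_on_plateau[1]
            stale <- 0L
          }
        }
      }
    }
    list(model = model, history = history)
  })
}

#' Predict growth fractions for (cell, drug A, drug B) inputs
#'
#' With ordered concatenation (`symmetrize = "none"`) a single forward pass
#' is not exactly invariant to swapping the drug slots even though the
#' encoder weights are shared; the default inference mode therefore
#' averages the predictions of both slot orderings, which is symmetric by
#' construction. With `symmetrize = "sum"` or `"sum_prod"` a single pass
#' is already order-invariant.
#'
#' @param object A `combo_model`.
#' @param x Input list as in [train_growth_model()].
#' @param slot_average Average predictions over both drug-slot orderings
#'   (default `TRUE`; ignored under `symmetrize = "sum"`).
#' @param ... Unused.
#' @return Numeric vector of predicted growth fractions, one per row.
#' @export
predict.combo_model <- function(object, x, slot_average = TRUE, ...) {
  check_widths_match(object, x)
  p1 <- model_forward(object, x)$yhat
  if (!slot_average || object$config$symmetrize != "none") return(p1)
  swapped <- x
  swapped$drug_a <- x$drug_b
  swapped$drug_b <- x$drug_a
  p2 <- model_forward(object, swapped)$yhat
  (p1 + p2) / 2
}

#' Predict single-agent growth
#'
#' Single-drug experiments are accommodated by replicating the same
#' descriptor vector into both drug slots; this helper does exactly that,
#' so `predict_single_drug(m, cell, d)` equals
#' `predict(m, cell, d, d)` exactly.
#'
#' @param model A `combo_model`.
#' @param cell Named list of cell feature matrices.
#' @param drug Drug descriptor matrix (one row per sample).
#' @return Numeric vector of predicted growth fractions.
#' @export
predict_single_drug <- function(model, cell, drug) {
  predict(model, list(cell = cell, drug_a = drug, drug_b = drug))
}

#' Save / load a model checkpoint
#'
#' Stores the weights, model configuration, and any attached preprocessing
#' state in a single archive.
#'
#' @param model A `combo_model`.
#' @param path Checkpoint path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "combo_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "combo_model"))
  model
}
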