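# Small builders shared across test files. Heavier artifacts (the default
# synthetic screen and its cross-validated predictions) are computed once
# per test run and memoized here.

make_records <- function(growth, cell = "C1", drug_a = "A", drug_b = "B",
                         dose_a = seq_along(growth), dose_b = 1L,
                         qc = TRUE) {
  screen_records(cell_id = cell, drug_a = drug_a, drug_b = drug_b,
                 dose_a_idx = dose_a, dose_b_idx = dose_b,
                 growth = growth, qc_pass = qc)
}

# random dosed record multiset for property tests
random_records <- function(n, n_cells = 3, n_drugs = 4, seed = 1) {
  withr::with_seed(seed, {
    single <- stats::runif(n) < 0.3
    drug_b <- ifelse(single, NA_character_,
                     sprintf("D%d", sample.int(n_drugs, n, replace = TRUE)))
    screen_records(
      cell_id = sprintf("C%d", sample.int(n_cells, n, replace = TRUE)),
      drug_a = sprintf("D%d", sample.int(n_drugs, n, replace = TRUE)),
      drug_b = drug_b,
      dose_a_idx = sample.int(3, n, replace = TRUE),
      dose_b_idx = ifelse(single, NA_integer_,
                          sample.int(3, n, replace = TRUE)),
      growth = stats::runif(n, -1, 1.2),
      qc_pass = stats::runif(n) < 0.9)
  })
}

tiny_feature_matrix <- function(vals, state = "raw") {
  m <- as.matrix(vals)
  if (is.null(rownames(m))) rownames(m) <- sprintf("r%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  feature_matrix(m, state = state)
}

# a tiny trainable input set: n rows with random features
tiny_inputs <- function(n, d_cell = 4, d_drug = 5, seed = 1) {
  withr::with_seed(seed, {
    list(cell = list(assay = matrix(stats::runif(n * d_cell), n)),
         drug_a = matrix(stats::runif(n * d_drug), n),
         drug_b = matrix(stats::runif(n * d_drug), n))
  })
}

tiny_model_config <- function(...) {
  model_config(encoder_layers = c(8L, 8L), tower_layers = c(8L, 8L, 8L), ...)
}

# -- memoized heavy artifacts -------------------------------------------

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_env)) {
    assign(name, force(expr), .fixture_env)
  }
  get(name, .fixture_env)
}

# the default synthetic screen used by the acceptance-level checks
default_sim <- function() memo("default_sim", simulate_screen(sim_config(seed = 7)))

default_dataset <- function() {
  memo("default_dataset", {
    sim <- default_sim()
    resp <- aggregate_min_growth(filter_records(sim$records,
                                                require_qc = TRUE))
    cell_feats <- lapply(sim$entities$cell,
                         function(m) preprocess_features(m)$matrix)
    drug_feats <- suppressMessages(
      preprocess_features(sim$entities$drug)$matrix)
    ds <- assemble_dataset(resp, cell_feats, drug_feats)
    ds$responses <- resp
    ds
  })
}

# cross-validated predictions of the virtual-screening model (wider and
# longer-trained than the smoke models, with the interaction-feature merge
# and a 2-model bag per fold; shared by the ranking checks)
screening_cv <- function() {
  memo("screening_cv", {
    ds <- default_dataset()
    cross_validate(
      ds,
      model_config(encoder_layers = c(160L, 160L),
                   tower_layers = c(160L, 160L, 160L),
                   residual = FALSE, symmetrize = "interact"),
      training_config(epochs = 120L, base_lr = 2e-3, batch_size = 64L,
                      reduce_on_plateau = c(0.5, 8), seed = 1L),
      k = 5L, seed = 1L, bag = 2L)
  })
}
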