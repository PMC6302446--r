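#' Configuration for the synthetic combination screen generator
#'
#' The generator emulates the shapes and statistical character of a
#' pairwise combination screen against a cell-line panel: latent cell and
#' drug factors project to omics assays and drug descriptors; single
#' agents are measured on monotone-decreasing dose curves at 3 or 5
#' concentrations; pairs are measured on 3x3 or 5x3 dose grids whose base
#' response is the multiplicative (truncated-product) expectation of the
#' single-agent responses, so that non-synergistic pairs have
#' BestComboScore near 0 by construction; a configured fraction of pairs
#' receives an additional planted synergy offset. Raw growth values can
#' slightly exceed 1 (exercising the cap) and the marginal distribution is
#' skewed toward nonresponse.
#'
#' @param n_cells,n_drugs Panel sizes.
#' @param latent_dim Width of the latent cell/drug factors.
#' @param omics Named integer vector of assay widths (cell feature
#'   matrices to emit).
#' @param descriptor_dim Drug descriptor width.
#' @param missing_col_frac Fraction of descriptor columns masked to >= 90%
#'   missing (exercising the sparse-column filter).
#' @param missing_cell_rate Background missing rate in remaining
#'   descriptor columns.
#' @param noise_sd Measurement noise standard deviation on growth
#'   fractions.
#' @param qc_fail_rate Fraction of records flagged as failing QC.
#' @param synergy_frac Fraction of unordered drug pairs planted as
#'   synergistic.
#' @param synergy_strength Growth-fraction offset (< 0) added to planted
#'   pairs at full dose; its BestComboScore equals `100 * synergy_strength`
#'   in the noise-free limit.
#' @param seed Root seed; identical config + seed gives identical output
#'   (named substreams for entities, screen layout, and noise).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 20L, n_drugs = 15L, latent_dim = 3L,
                       omics = c(expression = 40L, microrna = 20L,
                                 proteome = 30L),
                       descriptor_dim = 60L, missing_col_frac = 0.15,
                       missing_cell_rate = 0.02, noise_sd = 0.05,
                       qc_fail_rate = 0.02, synergy_frac = 0.1,
                       synergy_strength = -0.35, seed = 1L) {
  stopifnot(n_cells >= 2, n_drugs >= 2, latent_dim >= 1,
            length(omics) >= 1, !is.null(names(omics)),
            descriptor_dim >= 1, missing_col_frac >= 0,
            missing_col_frac <= 1, noise_sd >= 0,
            synergy_frac >= 0, synergy_frac <= 1, synergy_strength <= 0)
  if (any(omics < latent_dim) || descriptor_dim < latent_dim) {
    stop("feature widths must be >= latent_dim")
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_drugs = as.integer(n_drugs),
                 latent_dim = as.integer(latent_dim),
                 omics = omics, descriptor_dim = as.integer(descriptor_dim),
                 missing_col_frac = missing_col_frac,
                 missing_cell_rate = missing_cell_rate,
                 noise_sd = noise_sd, qc_fail_rate = qc_fail_rate,
                 synergy_frac = synergy_frac,
                 synergy_strength = synergy_strength,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# named substreams off the root seed keep modules independently reproducible
sub_seed <- function(cfg, stream) {
  offset <- c(entities = 101L, layout = 211L, noise = 307L)[[stream]]
  (cfg$seed * 1009L + offset) %% .Machine$integer.max
}

#' Generate latent-factor cell and drug feature matrices
#'
#' Latent cell factors project through assay-specific random loadings
#' (plus assay noise) to each omics matrix; latent drug factors project to
#' descriptors whose columns get heterogeneous scales (descriptors in real
#' screens range from binary fingerprints to molecular weights in the
#' hundreds). A configured fraction of descriptor columns is masked to at
#' least 90% missing, and a low background missing rate is sprinkled over
#' the rest.
#'
#' @param cfg A [sim_config()].
#' @return `list(cell = named list of feature_matrix, drug =
#'   feature_matrix, latents = list(U, V))`.
#' @export
generate_entities <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(sub_seed(cfg, "entities"), {
    cells <- sprintf("CELL_%02d", seq_len(cfg$n_cells))
    drugs <- sprintf("DRUG_%02d", seq_len(cfg$n_drugs))
    U <- matrix(stats::rnorm(cfg$n_cells * cfg$latent_dim), cfg$n_cells,
                dimnames = list(cells, NULL))
    V <- matrix(stats::rnorm(cfg$n_drugs * cfg$latent_dim), cfg$n_drugs,
                dimnames = list(drugs, NULL))
    cell_mats <- lapply(names(cfg$omics), function(assay) {
      w <- cfg$omics[[assay]]
      L <- matrix(stats::rnorm(cfg$latent_dim * w), cfg$latent_dim, w)
      X <- U %*% L + 0.3 * stats::rnorm(cfg$n_cells * w)
      colnames(X) <- sprintf("%s_f%03d", assay, seq_len(w))
      feature_matrix(X, state = c("raw", "log_transformed"))
    })
    names(cell_mats) <- names(cfg$omics)
    Ld <- matrix(stats::rnorm(cfg$latent_dim * cfg$descriptor_dim),
                 cfg$latent_dim, cfg$descriptor_dim)
    D <- V %*% Ld + 0.2 * stats::rnorm(cfg$n_drugs * cfg$descriptor_dim)
    scales <- 10^stats::runif(cfg$descriptor_dim, -1, 2)
    D <- sweep(D, 2, scales, "*")
    colnames(D) <- sprintf("desc_%03d", seq_len(cfg$descriptor_dim))
    n_masked <- round(cfg$missing_col_frac * cfg$descriptor_dim)
    masked_cols <- sample.int(cfg$descriptor_dim, n_masked)
    for (j in masked_cols) {
      D[sample.int(cfg$n_drugs, ceiling(0.9 * cfg$n_drugs)), j] <- NA
    }
    if (cfg$missing_cell_rate > 0) {
      other <- setdiff(seq_len(cfg$descriptor_dim), masked_cols)
      holes <- which(matrix(stats::runif(cfg$n_drugs * length(other)),
                            cfg$n_drugs) < cfg$missing_cell_rate,
                     arr.ind = TRUE)
      if (nrow(holes)) D[cbind(holes[, 1], other[holes[, 2]])] <- NA
    }
    list(cell = cell_mats, drug = feature_matrix(D),
         latents = list(U = U, V = V))
  })
}

# per-(cell, drug) maximal kill probability; skewed toward weak response
potency_matrix <- function(cfg, latents) {
  S <- latents$U %*% t(latents$V)
  Z <- (S - mean(S)) / stats::sd(S)
  E <- stats::plogis(1.4 * Z - 1.1)
  dimnames(E) <- list(rownames(latents$U), rownames(latents$V))
  E
}

# noise-free single-agent growth at dose fraction f in (0, 1]
single_growth <- function(e, f) 1 - 2 * e * f

#' Generate a dosed combination screen with known ground truth
#'
#' Emits raw dosed records (singles at 3 or 5 concentrations per drug,
#' pairs on 3x3 or 5x3 grids), plus the noise-free ground truth: the
#' per-tuple minimum-growth response table, the per-(cell, pair) true
#' BestComboScore table, and the planted synergistic pair labels.
#'
#' @param cfg A [sim_config()].
#' @param entities Output of [generate_entities()] for the same config.
#' @return `list(records, truth = list(response, scores, synergy_pairs))`.
#' @export
generate_screen <- function(cfg, entities) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- rownames(entities$latents$U)
  drugs <- rownames(entities$latents$V)
  E <- potency_matrix(cfg, entities$latents)

  layout <- withr::with_seed(sub_seed(cfg, "layout"), {
    n_dose <- sample(c(3L, 5L), cfg$n_drugs, replace = TRUE)
    names(n_dose) <- drugs
    pairs <- t(utils::combn(drugs, 2L))
    n_syn <- floor(cfg$synergy_frac * nrow(pairs))
    syn_idx <- if (n_syn > 0) sample.int(nrow(pairs), n_syn) else integer()
    list(n_dose = n_dose, pairs = pairs, syn_idx = syn_idx)
  })
  syn_key <- pair_key(layout$pairs[layout$syn_idx, 1],
                      layout$pairs[layout$syn_idx, 2])

  withr::with_seed(sub_seed(cfg, "noise"), {
    rec <- list()
    # single agents: each drug at its 3 or 5 concentrations, all cells
    for (d in drugs) {
      Td <- layout$n_dose[[d]]
      for (t in seq_len(Td)) {
        g <- single_growth(E[, d], t / Td) +
          stats::rnorm(length(cells), sd = cfg$noise_sd)
        rec[[length(rec) + 1L]] <- data.frame(
          cell_id = cells, drug_a = d, drug_b = NA_character_,
          dose_a_idx = t, dose_b_idx = NA_integer_,
          growth = pmax(g, -1), stringsAsFactors = FALSE)
      }
    }
    # pairs: TA x 3 grids; dose fractions span each drug's full curve so
    # the grid minimum matches the single-agent minima exactly
    for (p in seq_len(nrow(layout$pairs))) {
      a <- layout$pairs[p, 1]
      b <- layout$pairs[p, 2]
      syn <- if (pair_key(a, b) %in% syn_key) cfg$synergy_strength else 0
      Ta <- layout$n_dose[[a]]
      Tb <- 3L
      for (i in seq_len(Ta)) {
        for (j in seq_len(Tb)) {
          fa <- i / Ta
          fb <- j / Tb
          base <- expected_growth(single_growth(E[, a], fa),
                                  single_growth(E[, b], fb)) +
            syn * fa * fb
          g <- base + stats::rnorm(length(cells), sd = cfg$noise_sd)
          rec[[length(rec) + 1L]] <- data.frame(
            cell_id = cells, drug_a = a, drug_b = b,
            dose_a_idx = i, dose_b_idx = j,
            growth = pmax(g, -1), stringsAsFactors = FALSE)
        }
      }
    }
    records <- do.call(rbind, rec)
    records$qc_pass <- stats::runif(nrow(records)) >= cfg$qc_fail_rate
    records <- validate_screen_records(records)

    # noise-free truth: dose-grid minima sit at the full-dose corner
    y_single <- single_growth(E, 1)            # cells x drugs
    truth_single <- data.frame(
      cell_id = rep(cells, times = length(drugs)),
      drug_a = rep(drugs, each = length(cells)),
      drug_b = NA_character_,
      min_growth = as.numeric(y_single), stringsAsFactors = FALSE)
    truth_pairs <- do.call(rbind, lapply(seq_len(nrow(layout$pairs)),
                                         function(p) {
      a <- layout$pairs[p, 1]
      b <- layout$pairs[p, 2]
      syn <- if (pair_key(a, b) %in% syn_key) cfg$synergy_strength else 0
      data.frame(cell_id = cells, drug_a = a, drug_b = b,
                 min_growth = pmax(
                   expected_growth(y_single[, a], y_single[, b]) + syn, -1),
                 stringsAsFactors = FALSE)
    }))
    truth <- response_table(
      cell_id = c(truth_single$cell_id, truth_pairs$cell_id),
      drug_a = c(truth_single$drug_a, truth_pairs$drug_a),
      drug_b = c(truth_single$drug_b, truth_pairs$drug_b),
      min_growth = c(truth_single$min_growth, truth_pairs$min_growth))
    scores <- score_table(truth)
    list(records = records,
         truth = list(response = truth, scores = scores,
                      synergy_pairs = syn_key))
  })
}

#' One-call synthetic screen: entities plus dosed records and truth
#'
#' @param cfg A [sim_config()].
#' @return `list(config, entities, records, truth)` with class
#'   `synthetic_screen`.
#' @export
simulate_screen <- function(cfg = sim_config()) {
  entities <- generate_entities(cfg)
  screen <- generate_screen(cfg, entities)
  structure(list(config = cfg, entities = entities,
                 records = screen$records, truth = screen$truth),
            class = "synthetic_screen")
}

#' Write a complete synthetic fixture directory
#'
#' Emits the same delimited formats the readers consume: `screen.csv`,
#' one `features_<assay>.csv` per omics assay, `descriptors.csv`, and the
#' ground-truth `truth_response.csv` / `truth_scores.csv` /
#' `truth_synergy.csv`.
#'
#' @param sim A `synthetic_screen` from [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_screen_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_screen(sim$records, file.path(dir, "screen.csv"))
  for (assay in names(sim$entities$cell)) {
    write_feature_matrix(sim$entities$cell[[assay]],
                         file.path(dir, sprintf("features_%s.csv", assay)))
  }
  write_feature_matrix(sim$entities$drug, file.path(dir, "descriptors.csv"))
  resp <- sim$truth$response
  utils::write.table(
    data.frame(CELL = resp$cell_id, DRUG_A = resp$drug_a,
               DRUG_B = resp$drug_b, MIN_GROWTH = resp$min_growth),
    file.path(dir, "truth_response.csv"), sep = ",", row.names = FALSE,
    quote = FALSE, na = "")
  write_combo_scores(sim$truth$scores, file.path(dir, "truth_scores.csv"))
  writeLines(sim$truth$synergy_pairs, file.path(dir, "truth_synergy.csv"))
  invisible(dir)
}
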