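mini_scores <- function() {
  data.frame(cell_id = rep("C1", 3),
             drug_a = c("A", "A", "B"), drug_b = c("B", "C", "C"),
             c_ab = c(-50, -10, 5), stringsAsFactors = FALSE)
}

test_that("top-k pairs ranks most negative scores first", {
  expect_equal(top_k_pairs(mini_scores(), "C1", k = 2), c("A|B", "A|C"))
  expect_equal(top_k_pairs(mini_scores(), "C1", k = 10),
               c("A|B", "A|C", "B|C"))
  expect_error(top_k_pairs(mini_scores(), "C9"), "unknown cell")
})

test_that("exact score ties break lexicographically on pair key", {
  sc <- data.frame(cell_id = "C1", drug_a = c("B", "A", "A"),
                   drug_b = c("C", "D", "B"), c_ab = c(-5, -5, -5))
  expect_equal(top_k_pairs(sc, "C1", k = 3), c("A|B", "A|D", "B|C"))
})

test_that("ordered duplicates collapse to the better unordered score", {
  sc <- data.frame(cell_id = "C1", drug_a = c("A", "B"),
                   drug_b = c("B", "A"), c_ab = c(-10, -40))
  expect_equal(top_k_pairs(sc, "C1", k = 1), "A|B")
  # and the collapsed score is the minimum of the two orders
  expect_equal(top_k_pairs(sc, "C1", k = 2), "A|B")
  ordered <- top_k_pairs(sc, "C1", k = 2, unordered = FALSE)
  expect_equal(ordered, c("B|A", "A|B"))
})

test_that("top-list difference counts missed members, bounded by K", {
  l1 <- c("A|B", "A|C", "B|C")
  expect_equal(top_list_difference(l1, l1), 0)
  expect_equal(top_list_difference(l1, c("X|Y", "X|Z", "Y|Z")), 3)
  expect_equal(top_list_difference(l1, c("A|B", "A|C", "X|Y")), 1)
  # definitional case: 100-lists sharing 80 members differ by 20
  big_true <- sprintf("T|%03d", 1:100)
  big_pred <- c(big_true[1:80], sprintf("P|%03d", 1:20))
  expect_equal(top_list_difference(big_true, big_pred), 20)
})

test_that("pooled frequency ranking orders by list count, ties lexicographic", {
  lists <- list(c("A|B", "C|D"), c("A|B", "E|F"), c("A|B", "C|D"))
  pooled <- pooled_frequency_ranking(lists, n = 3)
  expect_equal(pooled[1], "A|B")
  expect_equal(pooled[2], "C|D")
  expect_equal(pooled[3], "E|F")
  # permutation invariance over list order
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(length(lists)))
    expect_equal(pooled_frequency_ranking(lists[perm], n = 3), pooled)
  }
  # tie counts break lexicographically
  tied <- pooled_frequency_ranking(list(c("B|C", "A|D")), n = 2)
  expect_equal(tied, c("A|D", "B|C"))
})

test_that("per-cell error summary aggregates mean, sd and CI", {
  oof <- data.frame(cell_id = rep(c("C1", "C2"), c(4, 1)),
                    drug_a = "A", drug_b = "B",
                    y_true = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    y_pred = c(0.2, 0.3, 0.4, 0.5, 0.6))
  s <- per_cell_error_summary(oof)
  expect_equal(s$mean_error, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(s$sd_error[1], 0, tolerance = 1e-12)
  expect_true(is.na(s$sd_error[2]))  # single observation: sd undefined
  sc <- data.frame(cell_id = c("C1", "C2"), drug_a = "A", drug_b = "B",
                   c_ab = c(-20, -5))
  s2 <- per_cell_error_summary(oof, sc)
  expect_equal(s2$mean_combo_score, c(-20, -5))
})

test_that("per-cell mean errors center near zero for unbiased predictions", {
  withr::with_seed(40, {
    oof <- data.frame(cell_id = rep(sprintf("C%d", 1:10), each = 100),
                      drug_a = "A", drug_b = "B",
                      y_true = stats::runif(1000))
    oof$y_pred <- oof$y_true + stats::rnorm(1000, sd = 0.1)
  })
  s <- per_cell_error_summary(oof)
  expect_true(all(abs(s$mean_error) < 0.05))
  expect_true(all(s$ci_lo < 0.02 & s$ci_hi > -0.02))
})

test_that("pair error matrix averages per pair, diagonal holds singles", {
  oof <- data.frame(cell_id = c("C1", "C2", "C1", "C1"),
                    drug_a = c("A", "A", "A", "B"),
                    drug_b = c("B", "B", NA, NA),
                    y_true = c(0.1, 0.2, 0.5, 0.3),
                    y_pred = c(0.2, 0.4, 0.4, 0.3))
  pe <- pair_error_matrix(oof)
  expect_equal(pe$mean["A", "B"], mean(c(0.1, 0.2)))
  expect_equal(pe$mean["B", "A"], pe$mean["A", "B"])  # symmetric
  expect_equal(pe$mean["A", "A"], -0.1)  # single-agent error on diagonal
  expect_equal(pe$mean["B", "B"], 0)
  expect_equal(pe$n["A", "B"], 2L)
  empty <- pair_error_matrix(oof[0, ])
  expect_equal(dim(empty$mean), c(0L, 0L))
})

test_that("cluster order places correlated drugs adjacent", {
  base <- c(1, 2, 3, 4, 5)
  m <- rbind(d1 = base + 0.01, d2 = rev(base), d3 = base)
  ord <- cluster_order(m)
  # the two positively correlated rows pair first under 1 - cor distance
  pos <- match(c("d1", "d3"), ord)
  expect_equal(abs(diff(pos)), 1)
  expect_equal(sort(ord), c("d1", "d2", "d3"))
  # two rows: deterministic order
  expect_equal(cluster_order(m[1:2, ]), cluster_order(m[1:2, ]))
  # constant row: correlation undefined, distance defaults with a message
  mc <- rbind(d1 = base, d2 = base, flat = rep(1, 5))
  expect_message(ordc <- cluster_order(mc), "undefined correlation")
  expect_setequal(ordc, c("d1", "d2", "flat"))
})
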