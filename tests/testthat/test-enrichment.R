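test_that("hypergeom_pvalue matches boundary cases and enumeration", {
  expect_identical(hypergeom_pvalue(0, 3, 4, 10), 1.0)
  expect_identical(hypergeom_pvalue(5, 5, 5, 5), 1.0)
  expect_equal(hypergeom_pvalue(2, 3, 3, 10), oracle_hypergeom(2, 3, 3, 10),
               tolerance = 1e-12)
  expect_error(hypergeom_pvalue(4, 3, 5, 10), "impossible")
  expect_error(hypergeom_pvalue(1, 11, 5, 10), "impossible")

  # non-increasing in k
  p <- vapply(0:4, hypergeom_pvalue, numeric(1), K = 6, n = 4, U = 20)
  expect_true(all(diff(p) <= 0))
})

test_that("percent_genes_per_term uses half-up rounding to two decimals", {
  expect_identical(percent_genes_per_term(3, 100), 3.00)
  expect_identical(percent_genes_per_term(3, 41), 7.32)
  expect_identical(percent_genes_per_term(5, 5), 100.00)
  expect_identical(percent_genes_per_term(1, 8), 12.5)
  # half-up, not banker's: 3/800 = 0.375% -> 0.38
  expect_identical(percent_genes_per_term(3, 800), 0.38)
  expect_error(percent_genes_per_term(0, 5), "1 <= k")
  expect_error(percent_genes_per_term(1, 0), "positive")
})

test_that("enrich ranks a perfectly matching term first and respects alpha", {
  genes <- sprintf("g%04d", 1:1000)
  query <- genes[1:6]
  sets <- c(list(match = query),
            generate_annotations(genes, 30, 10, 60, seed = 5)$sets)
  ann <- annotation_table(sets, universe = genes)
  rows <- enrich(query, ann, all = TRUE)
  expect_identical(rows$term_id[1], "match")
  expect_identical(rows$overlap[1], 6L)
  expect_identical(rows$percent_gt[1], 100.00)
  expect_true(all(rows$adjusted_p >= rows$p_value))
  expect_true(all(diff(rows$p_value) >= 0))

  sig <- enrich(query, ann, alpha = 0.05)
  expect_true(all(sig$adjusted_p < 0.05))
  expect_true("match" %in% sig$term_id)

  # Holm agrees with p.adjust and is monotone in the raw p
  expect_equal(rows$adjusted_p,
               unname(p.adjust(rows$p_value, "holm")), tolerance = 1e-12)

  # saturated query: every term certain to overlap, all p = 1
  small <- annotation_table(list(t1 = c("a", "b"), t2 = c("b", "c")))
  sat <- enrich(c("a", "b", "c"), small, all = TRUE)
  expect_true(all(sat$p_value == 1))

  # disjoint terms emit no row; genes outside the universe warn
  expect_identical(nrow(enrich("a", annotation_table(list(t = "b"),
                                                     universe = c("a", "b")),
                               all = TRUE)), 0L)
  expect_warning(enrich(c("a", "zz"), small, all = TRUE), "outside")
  expect_error(suppressWarnings(enrich("zz", small)), "no query genes")
})

test_that("membership counts follow the published fixture", {
  fx <- table2_fixture()
  counts <- membership_counts(fx$rows, fx$query)
  # counts implied by the printed table (its G/T column sums to 106,
  # consistent with these six values)
  expect_identical(unname(counts["MAPK3"]), 34L)
  expect_identical(unname(counts["AKT1"]), 32L)
  expect_identical(unname(counts["SRC"]), 22L)
  expect_identical(unname(counts["TP53"]), 17L)
  expect_identical(unname(counts["GAPDH"]), 1L)
  expect_identical(unname(counts["ALB"]), 0L)
  expect_identical(sum(counts), sum(fx$rows$gt))

  none <- membership_counts(fx$rows[0, ], fx$query)
  expect_true(all(none == 0L))
})

test_that("kappa_score is a symmetric chance-corrected agreement", {
  u <- paste0("g", 1:10)
  expect_identical(kappa_score(c("g1", "g2"), c("g1", "g2"), u), 1)
  expect_lt(kappa_score(u[1:5], u[6:10], u), 0)
  expect_equal(kappa_score(c("g1", "g2"), c("g2", "g3"), u), 0.375,
               tolerance = 1e-12)
  expect_equal(kappa_score(c("g2", "g3"), c("g1", "g2"), u), 0.375,
               tolerance = 1e-12)
  # relabelling the universe leaves kappa unchanged
  relab <- setNames(paste0("x", 10:1), u)
  expect_equal(kappa_score(unname(relab[c("g1", "g2")]),
                           unname(relab[c("g2", "g3")]), unname(relab)),
               0.375, tolerance = 1e-12)
  # both constant and equal -> defined as 1
  expect_identical(kappa_score(u, u, u), 1)
  expect_error(kappa_score("g1", "g1", "g1"), "at least two")
  expect_error(kappa_score("zz", "g1", u), "subsets")
})

test_that("cluster_terms separates the HIF-1 row of the fixture at 0.4", {
  fx <- table2_fixture()
  cl <- cluster_terms(fx$rows, threshold = 0.4, universe = fx$query)
  expect_length(cl, 34L)
  hif <- cl[["HIF-1 signaling pathway"]]
  expect_identical(sum(cl == hif), 1L)
  expect_identical(length(unique(cl[names(cl) != "HIF-1 signaling pathway"])),
                   1L)

  single <- data.frame(term_id = "t1", p_value = 0.01)
  single$genes <- list(c("a", "b"))
  expect_identical(unname(cluster_terms(single, universe = letters[1:4])), 1L)

  twin <- data.frame(term_id = c("t1", "t2"), p_value = c(0.01, 0.02))
  twin$genes <- list(c("a", "b"), c("a", "b"))
  expect_identical(unname(cluster_terms(twin, universe = letters[1:4])),
                   c(1L, 1L))
})

# Exact null rejection rate of the right-tailed hypergeometric test at
# level alpha: P(p < alpha) = P(X >= k_crit), the tail at the smallest k
# whose tail drops below alpha. Discreteness makes this < alpha.
exact_null_rate <- function(K, n, U, alpha = 0.05) {
  k <- 0:min(K, n)
  tails <- phyper(k - 1, K, U - K, n, lower.tail = FALSE)
  crit <- which(tails < alpha)[1]
  if (is.na(crit)) 0 else tails[crit]
}

test_that("null enrichment matches its exact type-I rate and is valid", {
  genes <- sprintf("g%03d", 1:200)
  n_sims <- 500L
  n_terms <- 20L
  hits <- 0L
  expected <- 0
  total <- 0L
  set.seed(99)
  for (i in seq_len(n_sims)) {
    ann <- generate_annotations(genes, n_terms, 10, 40, seed = i)
    query <- sample(genes, 10)
    rows <- enrich(query, ann, all = TRUE)
    hits <- hits + sum(rows$p_value < 0.05)
    expected <- expected +
      sum(vapply(lengths(ann$sets), exact_null_rate, numeric(1),
                 n = 10, U = 200))
    total <- total + n_terms
  }
  rate <- hits / total
  expected_rate <- expected / total
  se <- sqrt(expected_rate * (1 - expected_rate) / total)
  # empirical rate agrees with the analytically exact expectation, and the
  # test is valid (never anti-conservative)
  expect_lt(abs(rate - expected_rate), 3 * se)
  expect_lte(expected_rate, 0.05)
})
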