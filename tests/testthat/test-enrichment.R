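test_that("expected counts and fold enrichment reproduce published arithmetic", {
  expect_equal(round(expected_count(34, 914, 38), 1), 1.4)
  expect_equal(expected_count(0, 914, 38), 0)
  expect_equal(codonsel:::display_round(expected_count(50, 1231, 54)), 2.2)
  expect_equal(codonsel:::display_round(fold_enrichment(7, 34, 914, 38)), 5.0)
  expect_equal(codonsel:::display_round(fold_enrichment(8, 50, 1231, 54)), 3.6)
  expect_equal(fold_enrichment(3, 21, 1229, 21) * expected_count(21, 1229, 21), 3)
  expect_equal(fold_enrichment(2, 2, 10, 5), 2 / 1)
  expect_error(expected_count(5, 0, 3), "positive")
})

test_that("the unrounded-expectation rule is what reproduces 8.4-fold", {
  # dividing by the rounded expectation would give 3 / 0.4 = 7.5, not the
  # published 8.4; the fold must use the full-precision expectation
  E <- expected_count(21, 1229, 21)
  expect_equal(codonsel:::display_round(3 / E), 8.4)
  expect_equal(round(3 / round(E, 1), 1), 7.5)
})

test_that("one-tailed Fisher tails reproduce reconstructed 2x2 tables", {
  expect_equal(round(fisher_one_tailed(1, 13, 954, 39), 2), 0.42)
  expect_equal(round(fisher_one_tailed(1, 28, 954, 39), 2), 0.69)
  expect_equal(fisher_one_tailed(0, 14, 1285, 56), 1.0)
  # over- and under-representation share the observed table's probability
  for (O in 0:5) {
    p_over <- fisher_one_tailed(O, 9, 100, 12)
    p_under <- fisher_one_tailed(O, 9, 100, 12, "under")
    expect_gte(p_over + p_under, 1)
  }
  # cross-check against stats::fisher.test on one table
  ft <- stats::fisher.test(matrix(c(7, 31, 27, 849), 2, 2,
                                  byrow = TRUE), alternative = "greater")
  expect_equal(fisher_one_tailed(7, 34, 914, 38), ft$p.value, tolerance = 1e-10)
  expect_error(fisher_one_tailed(6, 5, 100, 10), "inconsistent")
})

test_that("binomial over-representation matches published process p-values", {
  expect_equal(round(binomial_overrep(3, 11, 1209, 53), 3), 0.013)
  expect_equal(round(binomial_overrep(2, 9, 894, 35), 3), 0.048)
  expect_equal(round(binomial_overrep(1, 1, 1209, 53), 3), 0.043)
  expect_equal(binomial_overrep(0, 10, 100, 5), 1.0)
  # for small K/N the binomial tail dominates its Poisson approximation's
  # complement only loosely; sanity-bound the two against each other
  p_binom <- binomial_overrep(2, 5, 1000, 50)
  p_pois <- stats::ppois(1, 50 * 5 / 1000, lower.tail = FALSE)
  expect_equal(p_binom, p_pois, tolerance = 0.05)
})

test_that("EASE penalization is conservative and matches its own oracle", {
  expect_equal(ease_score(1, 10, 500, 20), 1)
  expect_equal(ease_score(0, 10, 500, 20), 1)
  set.seed(5)
  for (i in 1:25) {
    N <- sample(50:300, 1)
    K <- sample(1:30, 1)
    n <- sample(1:40, 1)
    O <- sample(0:min(K, n), 1)
    p_f <- fisher_one_tailed(O, K, N, n)
    p_e <- ease_score(O, K, N, n)
    expect_gte(p_e, p_f - 1e-12)
    if (O >= 1) {
      # direct hypergeometric summation on the adjusted count
      tail <- sum(stats::dhyper((O - 1):min(K, n), K, N - K, n))
      expect_equal(p_e, tail, tolerance = 1e-10)
    }
  }
})

test_that("enrichment tables count conservatively and rank planted signal", {
  genes <- sprintf("g%03d", 1:200)
  ann <- simulate_annotations(genes, c(catP = 25, catA = 25, catB = 40),
                              planted = "catP", enrichment_factor = 8,
                              candidate_set = genes[1:25], seed = 77)
  tab <- enrich_table(genes[1:25], genes, ann)
  expect_s3_class(tab, "enrichment_table")
  # conservation: per-category observed counts match the annotation table
  for (k in seq_len(nrow(tab))) {
    cat_k <- tab$category[k]
    expect_equal(tab$O[k], sum(vapply(genes[1:25], function(g)
      cat_k %in% ann[[g]], logical(1))))
    expect_equal(tab$K[k], sum(vapply(genes, function(g)
      cat_k %in% ann[[g]], logical(1))))
  }
  expect_equal(tab$category[1], "catP")

  # candidates == background gives fold enrichment 1 everywhere
  tab_all <- enrich_table(genes, genes, ann)
  expect_true(all(abs(tab_all$FE - 1) < 1e-12))
  # a category absent from candidates scores p = 1 under over-representation
  ann2 <- ann
  ann2[["g200"]] <- c(ann2[["g200"]], "catZ")
  tabz <- enrich_table(genes[1:25], genes, ann2)
  expect_equal(tabz$p[tabz$category == "catZ"], 1.0)
  expect_error(enrich_table(c("nope"), genes, ann), "not in background")
})

test_that("grouped-term unions are tested as ordinary Fisher tables", {
  genes <- sprintf("g%02d", 1:50)
  ann <- stats::setNames(rep(list(character(0)), 50), genes)
  for (g in genes[1:10]) ann[[g]] <- "wingA"
  for (g in genes[11:15]) ann[[g]] <- "wingB"
  res <- grouped_term_test(c("wingA", "wingB"), genes[1:10], genes, ann)
  expect_equal(res$K, 15L)
  expect_equal(res$O, 10L)
  expect_equal(res$p, fisher_one_tailed(10, 15, 50, 10))
})
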