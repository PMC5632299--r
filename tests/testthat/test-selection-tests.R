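test_that("BH adjustment follows the step-up definition", {
  r <- bh_adjust(0.04, alpha = 0.05)
  expect_equal(r$p_adjusted, 0.04)
  expect_true(r$significant)
  expect_false(any(bh_adjust(rep(1, 5))$significant))
  # hand-applied step-up on four p-values
  r4 <- bh_adjust(c(0.01, 0.02, 0.03, 0.8), alpha = 0.05)
  expect_equal(r4$p_adjusted, c(0.04, 0.04, 0.04, 0.8))
  expect_equal(r4$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_true(all(bh_adjust(runif(20))$p_adjusted >= runif(0)))
})

test_that("BH significance is monotone under lowering any raw p-value", {
  set.seed(31)
  for (i in 1:25) {
    p <- runif(12)
    before <- bh_adjust(p)$significant
    j <- sample(12, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    after <- bh_adjust(p2)$significant
    expect_true(all(after[before]))   # no flag elsewhere is lost
  }
})

test_that("pooled-branch rate test is label-symmetric and detects relaxation", {
  tr3 <- small_comparison_tree()
  aln <- simulate_codon_alignment(tr3, list(type = "branch", kappa = 2,
                                            omega = c(0.02, 0.08, 0.02)),
                                  1000, seed = 55)
  res <- branch_rates_test(aln, tr3, estimate_scale = FALSE, seed = 1)
  expect_equal(res$direction, "flightless")
  expect_lt(res$p_raw, 0.05)
  expect_true(res$relaxed_call)
  expect_gte(res$lnL_alt, res$lnL_null - 1e-6)

  # swapping the flightless/flying labels flips direction, same statistic
  swapped <- tr3$edge.class
  swapped[tr3$edge.class == 1L] <- 2L
  swapped[tr3$edge.class == 2L] <- 1L
  tr_swap <- labeled_tree(tr3, swapped)
  res_swap <- branch_rates_test(aln, tr_swap, estimate_scale = FALSE, seed = 1)
  expect_equal(res_swap$lrt, res$lrt, tolerance = 1e-6)
  expect_equal(res_swap$direction, "flying")
})

test_that("a no-improvement alternative yields a clamped LRT and p = 1", {
  tr <- small_comparison_tree()
  aln <- simulate_codon_alignment(tr, list(type = "branch", kappa = 2, omega = 0.1),
                                  200, seed = 4)
  fit <- fit_codon_model(aln, tr, "M0", n_restarts = 1L, seed = 1)
  tab <- anova(fit, fit)
  expect_equal(tab$lrt, 0)
  expect_equal(tab$p, 1)
})

test_that("branch-site test calls positive selection when it is simulated", {
  tr <- small_panel_tree(ntaxa = 8, seed = 23)
  # strong episodic signal on the foreground branch
  alt_model <- list(type = "branch_site", kappa = 2, omega0 = 0.05, omega2 = 8,
                    p0 = 0.6, p1 = 0.1)
  null_model <- list(type = "branch_site", kappa = 2, omega0 = 0.05, omega2 = 1,
                     p0 = 0.6, p1 = 0.1)
  hits_alt <- hits_null <- logical(15)
  for (i in 1:15) {
    a_alt <- simulate_codon_alignment(tr, alt_model, 300, seed = 900 + i)
    a_null <- simulate_codon_alignment(tr, null_model, 300, seed = 1900 + i)
    r_alt <- branch_site_test(a_alt, tr, estimate_scale = FALSE, seed = i)
    r_null <- branch_site_test(a_null, tr, estimate_scale = FALSE, seed = i)
    hits_alt[i] <- r_alt$p_raw < 0.05 && r_alt$positive_call
    hits_null[i] <- r_null$p_raw < 0.05 && r_null$positive_call
  }
  expect_gt(mean(hits_alt), mean(hits_null))
  expect_gt(mean(hits_alt), 0.5)
})

test_that("branch-site type-I error stays at or below nominal alpha", {
  # null calibration of the A vs A1 test at desk scale; the chi-square(1)
  # reference is conservative at the omega2 = 1 boundary, so the rejection
  # rate may fall well below alpha but must not exceed the binomial margin
  tr <- small_panel_tree(ntaxa = 6, seed = 11)
  m <- list(type = "branch_site", kappa = 2, omega0 = 0.1, omega2 = 1,
            p0 = 0.8, p1 = 0.1)
  n_rep <- 200L
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    aln <- simulate_codon_alignment(tr, m, 150, seed = 5000 + i)
    rej[i] <- branch_site_test(aln, tr, estimate_scale = FALSE, seed = i)$p_raw < 0.05
  }
  margin <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(rej), 0.05 + margin)
})

test_that("the boundary mixture halves the chi-square p-value", {
  tr <- small_panel_tree(ntaxa = 6, seed = 11)
  aln <- simulate_codon_alignment(tr, list(type = "branch_site", kappa = 2,
                                           omega0 = 0.1, omega2 = 3,
                                           p0 = 0.7, p1 = 0.1), 150, seed = 77)
  r_chi <- branch_site_test(aln, tr, estimate_scale = FALSE, seed = 1)
  r_mix <- branch_site_test(aln, tr, estimate_scale = FALSE, seed = 1,
                            null_dist = "mixture")
  if (r_chi$lrt > 0) expect_equal(r_mix$p_raw, r_chi$p_raw / 2)
  expect_equal(r_mix$lrt, r_chi$lrt)
})

test_that("collect_gene_tests assembles the per-gene table with BH columns", {
  tr <- small_comparison_tree()
  tests <- lapply(1:3, function(i) {
    aln <- simulate_codon_alignment(tr, list(type = "branch", kappa = 2,
                                             omega = c(0.05, 0.05, 0.05)),
                                    150, seed = 40 + i)
    branch_rates_test(aln, tr, gene = paste0("g", i), estimate_scale = FALSE,
                      seed = i)
  })
  tab <- collect_gene_tests(tests, alpha = 0.05)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$p_bh >= tab$p_raw - 1e-12))
  expect_true(all(tab$lrt >= 0))
  expect_true(all(tab$significant == (tab$p_bh <= 0.05)))
  expect_true(all(c("omega_class0", "omega_class1", "omega_class2") %in% names(tab)))
})
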