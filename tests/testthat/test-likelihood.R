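test_that("pruning equals brute-force enumeration on random small instances", {
  skip_if_not_installed("Matrix")
  oc <- oracle_code()
  set.seed(101)
  for (rep in 1:12) {
    inst <- random_oracle_instance(oc)
    omega <- runif(1, 0.05, 3)
    ll <- log_likelihood(inst$alignment, inst$tree, kappa = inst$kappa,
                         omega = omega, freqs = inst$freqs)
    bf <- oracle_loglik(inst$tree, oracle_tipstates(inst$alignment, inst$tree, oc),
                        inst$kappa, rep(omega, nrow(inst$tree$edge)), inst$freqs, oc)
    expect_equal(ll, bf, tolerance = 1e-8)
  }
})

test_that("branch-site mixture likelihood matches a per-class oracle mixture", {
  skip_if_not_installed("Matrix")
  oc <- oracle_code()
  set.seed(202)
  tr <- ape::rcoal(4, tip.label = paste0("t", 1:4))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  cls <- integer(nrow(tr$edge)); cls[2] <- 1L
  ltr <- labeled_tree(tr, cls)
  seqs <- setNames(vapply(1:4, function(i)
    paste(sample(oc$codons, 2, replace = TRUE), collapse = ""), character(1)),
    tr$tip.label)
  aln <- codon_alignment(seqs)
  f <- rep(1 / 61, 61)
  pars <- list(omega0 = 0.2, omega2 = 3, p0 = 0.6, p1 = 0.2)
  ll <- log_likelihood(aln, ltr, kappa = 2, omega = pars, freqs = f,
                       model = "branch_site")
  # oracle: site likelihood = weighted sum of 4 per-class brute-force runs;
  # all classes share the conserved-class (omega0) normalization, expressed
  # here by stretching each edge by rate(omega)/rate(omega0)
  fg <- cls > 0
  omega_sets <- list(ifelse(fg, 0.2, 0.2), ifelse(fg, 1, 1),
                     ifelse(fg, 3, 0.2), ifelse(fg, 3, 1))
  probs <- c(0.6, 0.2, 0.2 * 0.75, 0.2 * 0.25)
  ts <- oracle_tipstates(aln, tr, oc)
  rho0 <- oracle_rate(2, 0.2, f, oc)
  per_site <- sapply(1:2, function(s) {
    liks <- vapply(omega_sets, function(om) {
      tr_c <- tr
      rates <- vapply(om, function(w) oracle_rate(2, w, f, oc), numeric(1))
      tr_c$edge.length <- tr$edge.length * rates / rho0
      exp(oracle_loglik(tr_c, ts[, s, drop = FALSE], 2, om, f, oc))
    }, numeric(1))
    log(sum(probs * liks))
  })
  expect_equal(ll, sum(per_site), tolerance = 1e-8)
})

test_that("degenerate branch-site mixtures collapse to single-class models", {
  aln <- tiny_alignment()
  tr <- read_labeled_tree(text = "((A#1:0.1,B:0.1):0.05,C:0.2);")
  f <- rep(1 / 61, 61)
  ll_mix <- log_likelihood(aln, tr, 2, list(omega0 = 0.3, omega2 = 4, p0 = 1, p1 = 0),
                           freqs = f, model = "branch_site")
  ll_single <- log_likelihood(aln, tr, 2, omega = c(0.3, 0.3), freqs = f)
  expect_equal(ll_mix, ll_single, tolerance = 1e-10)
})

test_that("likelihood is invariant to root placement for reversible models", {
  set.seed(9)
  tr <- ape::rcoal(6, tip.label = paste0("t", 1:6))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  aln <- simulate_codon_alignment(tr, list(type = "branch", kappa = 2, omega = 0.2),
                                  40, seed = 1)
  f <- codon_frequencies(aln, "F3x4")
  ll_rooted <- log_likelihood(aln, tr, 2, 0.2, freqs = f)
  ll_unrooted <- log_likelihood(aln, ape::unroot(tr), 2, 0.2, freqs = f)
  tr2 <- ape::root(ape::unroot(tr), outgroup = "t3", resolve.root = TRUE)
  ll_reroot <- log_likelihood(aln, tr2, 2, 0.2, freqs = f)
  expect_equal(ll_rooted, ll_unrooted, tolerance = 1e-8)
  expect_equal(ll_rooted, ll_reroot, tolerance = 1e-8)
})

test_that("ambiguous codons act as missing data", {
  f <- rep(1 / 61, 61)
  tr <- tiny_tree()
  a_full <- codon_alignment(c(A = "ATGGCT", B = "ATGGCA", C = "ATGGGA"))
  a_miss <- codon_alignment(c(A = "ATGNNT", B = "ATGGCA", C = "ATGGGA"))
  # site 2 of A is ambiguous -> its tip partial is all ones, so the site-2
  # likelihood must equal the likelihood with A absent at that site
  ll_miss <- log_likelihood(a_miss, tr, 2, 0.3, freqs = f)
  a_bc_only <- codon_alignment(c(B = "GCA", C = "GGA"))
  ll_site1 <- log_likelihood(codon_alignment(c(A = "ATG", B = "ATG", C = "ATG")),
                             tr, 2, 0.3, freqs = f)
  ll_site2_bc <- log_likelihood(a_bc_only, tr, 2, 0.3, freqs = f)
  expect_equal(ll_miss, ll_site1 + ll_site2_bc, tolerance = 1e-8)
  # a gap codon behaves identically to N-ambiguity
  a_gap <- codon_alignment(c(A = "ATG---", B = "ATGGCA", C = "ATGGGA"))
  expect_equal(log_likelihood(a_gap, tr, 2, 0.3, freqs = f), ll_miss,
               tolerance = 1e-12)
})

test_that("taxa mismatches are rejected", {
  aln <- codon_alignment(c(A = "ATG", B = "ATG", Z = "ATG"))
  expect_error(log_likelihood(aln, tiny_tree(), 2, 0.2, freqs = rep(1 / 61, 61)),
               "absent from tree")
})
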