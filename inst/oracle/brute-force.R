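# Independent likelihood oracle: brute-force enumeration of internal-node
# codon assignments, with its own naive rate-matrix construction and a
# series-based matrix exponential (Matrix::expm), sharing no code with the
# pruning path it checks. Used by the test suite and the acceptance script.

oracle_code <- function() {
  nt <- c("T", "C", "A", "G")
  all64 <- as.vector(vapply(nt, function(a)
    vapply(nt, function(b) paste0(a, b, nt), character(4)), character(16)))
  aa <- vapply(all64, function(cdn)
    seqinr::translate(strsplit(cdn, "")[[1]], numcode = 1), character(1))
  list(codons = all64[aa != "*"], aa = aa[aa != "*"])
}

# naive GY94 generator: explicit double loop over codon pairs
oracle_Q <- function(kappa, omega, freqs, oc = oracle_code(), normalize = TRUE) {
  ns <- length(oc$codons)
  Q <- matrix(0, ns, ns)
  is_transition <- function(x, y)
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    ci <- strsplit(oc$codons[i], "")[[1]]
    cj <- strsplit(oc$codons[j], "")[[1]]
    d <- which(ci != cj)
    if (length(d) != 1L) next
    r <- freqs[j]
    if (is_transition(ci[d], cj[d])) r <- r * kappa
    if (oc$aa[i] != oc$aa[j]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  if (normalize) Q / sum(freqs * -diag(Q)) else Q
}

oracle_rate <- function(kappa, omega, freqs, oc = oracle_code()) {
  sum(freqs * -diag(oracle_Q(kappa, omega, freqs, oc, normalize = FALSE)))
}

oracle_P <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# Brute-force log-likelihood by summation over all internal-node codon
# assignments. `omega_edge` gives one omega per row of tree$edge; `tipstate`
# is an ntip x nsites matrix of codon indices (0 = missing).
oracle_loglik <- function(tree, tipstate, kappa, omega_edge, freqs,
                          oc = oracle_code()) {
  ns <- length(oc$codons)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    oracle_P(oracle_Q(kappa, omega_edge[e], freqs, oc), tree$edge.length[e]))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  combos <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))  # 61^nint x nint
  int_state <- function(node, cmb) cmb[, node - ntip]
  total <- 0
  for (s in seq_len(ncol(tipstate))) {
    w <- freqs[int_state(root, combos)]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      ps <- int_state(par, combos)
      if (ch <= ntip) {
        st <- tipstate[ch, s]
        w <- w * (if (st == 0L) 1 else Ps[[e]][cbind(ps, st)])
      } else {
        w <- w * Ps[[e]][cbind(ps, int_state(ch, combos))]
      }
    }
    total <- total + log(sum(w))
  }
  total
}

# convert an alignment to the oracle's tip-state matrix (tree tip order)
oracle_tipstates <- function(alignment, tree, oc = oracle_code()) {
  ntip <- length(tree$tip.label)
  out <- matrix(0L, ntip, alignment$sites)
  for (tx in alignment$taxa) {
    st <- match(alignment$codons[[tx]], oc$codons)
    st[!grepl("^[ACGT]{3}$", alignment$codons[[tx]])] <- NA
    st[is.na(st)] <- 0L
    out[match(tx, tree$tip.label), ] <- st
  }
  out
}

# random small instance for oracle comparisons
random_oracle_instance <- function(oc = oracle_code()) {
  nleaf <- sample(3:4, 1)
  nsites <- sample(1:3, 1)
  tr <- ape::rcoal(nleaf, tip.label = paste0("t", seq_len(nleaf)))
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.6)
  kappa <- runif(1, 0.5, 5)
  freqs <- as.numeric(rdirichlet_one(length(oc$codons)))
  seqs <- vapply(seq_len(nleaf), function(i)
    paste(sample(oc$codons, nsites, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- tr$tip.label
  list(tree = tr, alignment = codon_alignment(seqs), kappa = kappa, freqs = freqs,
       nsites = nsites)
}

rdirichlet_one <- function(k, alpha = 5) {
  g <- rgamma(k, alpha)
  g / sum(g)
}
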