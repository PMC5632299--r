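#' Goldman-Yang codon rate matrix
#'
#' Builds the instantaneous rate matrix of the GY94 codon model over the sense
#' codons of a genetic code. Off-diagonal rates are zero for multi-nucleotide
#' changes and proportional to the target codon frequency otherwise, with a
#' factor kappa for transitions and omega for nonsynonymous changes. The
#' matrix is scaled so the expected number of substitutions per codon per unit
#' branch length equals one at the stationary distribution.
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS), >= 0.
#' @param freqs stationary codon frequencies over the sense codons (sums to 1).
#' @param code genetic code name passed to [genetic_code()].
#' @param scale if `TRUE` (default) normalize to one expected substitution per
#'   unit time; the selection tests always use scaled matrices.
#' @return A square rate matrix with `dimnames` the sense codons and rows
#'   summing to zero.
#' @export
build_rate_matrix <- function(kappa, omega, freqs, code = "standard", scale = TRUE) {
  gc <- genetic_code(code)
  ns <- length(gc$codons)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a single positive number")
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0)
    stop("omega must be a single nonnegative number")
  freqs <- validate_freqs(freqs, ns)
  ch <- gc$change
  syn <- gc$aa[ch$i] == gc$aa[ch$j]
  rate <- freqs[ch$j]
  rate <- rate * ifelse(ch$transition, kappa, 1)
  rate <- rate * ifelse(syn, 1, omega)
  Q <- matrix(0, ns, ns, dimnames = list(gc$codons, gc$codons))
  Q[cbind(ch$i, ch$j)] <- rate
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(freqs * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# expected substitutions per unit time of the unnormalized GY94 generator
codon_rate <- function(kappa, omega, freqs, code = "standard") {
  Q <- build_rate_matrix(kappa, omega, freqs, code = code, scale = FALSE)
  -sum(freqs * diag(Q))
}

validate_freqs <- function(freqs, ns) {
  if (length(freqs) != ns || any(!is.finite(freqs)) || any(freqs < 0))
    stop("freqs must be ", ns, " finite nonnegative values")
  s <- sum(freqs)
  if (abs(s - 1) > 1e-6) stop("freqs must sum to 1")
  freqs / s
}

#' Spectral decomposition of a reversible codon generator
#'
#' Symmetrizes the reversible generator with the stationary frequencies and
#' eigendecomposes it, so transition probability matrices for any branch
#' length come from a single diagonalization. The symmetric eigenproblem is
#' numerically stable for every parameter combination the model admits.
#'
#' @param Q scaled rate matrix from [build_rate_matrix()].
#' @param freqs the stationary frequencies used to build `Q`.
#' @return list with `values`, and the row/column transforms `left`
#'   (`D^{1/2} U`) and `right` (`U^T D^{-1/2}`) such that
#'   `P(t) = t(left * exp(values t)) ...`; consumed by [transition_probabilities()]
#'   and the compiled pruning core.
#' @export
decompose_generator <- function(Q, freqs) {
  ns <- nrow(Q)
  freqs <- validate_freqs(freqs, ns)
  # guard zero frequencies (possible under empirical F3x4): floor and rescale
  f <- pmax(freqs, 1e-12)
  sq <- sqrt(f)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       U1 = e$vectors / sq,        # D^{-1/2} U : 61 x 61
       U2 = t(e$vectors * sq))     # U^T D^{1/2}
}

#' Transition probabilities of a codon model
#'
#' @param Q rate matrix (or a decomposition from [decompose_generator()]).
#' @param t branch length in expected substitutions per codon, >= 0.
#' @param freqs stationary frequencies matching `Q` (ignored when `Q` is
#'   already a decomposition).
#' @return stochastic matrix `P(t)`; rows sum to 1, tiny negative round-off
#'   clamped to zero.
#' @export
transition_probabilities <- function(Q, t, freqs = NULL) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) stop("t must be a single value >= 0")
  dec <- if (is.matrix(Q)) {
    if (is.null(freqs)) stop("freqs required when Q is a matrix")
    decompose_generator(Q, freqs)
  } else Q
  P <- dec$U1 %*% (exp(dec$values * t) * dec$U2)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Empirical codon frequency models
#'
#' Computes the stationary codon frequency vector from alignment data under
#' the `"equal"`, `"F1x4"` (nucleotide frequencies pooled over positions) or
#' `"F3x4"` (position-specific nucleotide frequencies) conventions. Stop
#' codons are excluded and the vector renormalized over sense codons; a small
#' floor keeps unobserved codons usable in the reversible decomposition.
#'
#' @param alignment a `codon_alignment`.
#' @param model one of `"F3x4"`, `"F1x4"`, `"equal"`.
#' @param code genetic code name.
#' @return named frequency vector over the sense codons.
#' @export
codon_frequencies <- function(alignment, model = c("F3x4", "F1x4", "equal"),
                              code = "standard") {
  model <- match.arg(model)
  gc <- genetic_code(code)
  ns <- length(gc$codons)
  if (model == "equal") return(stats::setNames(rep(1 / ns, ns), gc$codons))
  cods <- unlist(alignment$codons, use.names = FALSE)
  cods <- cods[is_unambiguous_codon(cods)]
  if (length(cods) == 0L) return(stats::setNames(rep(1 / ns, ns), gc$codons))
  mat <- do.call(rbind, strsplit(cods, ""))
  nt <- c("T", "C", "A", "G")
  cm <- do.call(rbind, strsplit(gc$codons, ""))
  if (model == "F1x4") {
    p <- table(factor(as.vector(mat), levels = nt))
    p <- as.numeric(p) / sum(p)
    names(p) <- nt
    f <- p[cm[, 1]] * p[cm[, 2]] * p[cm[, 3]]
  } else {
    f <- rep(1, ns)
    for (pos in 1:3) {
      p <- table(factor(mat[, pos], levels = nt))
      p <- as.numeric(p) / sum(p)
      names(p) <- nt
      f <- f * p[cm[, pos]]
    }
  }
  f <- pmax(f, 1e-8)
  stats::setNames(f / sum(f), gc$codons)
}
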