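#' @useDynLib codonsel, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Precompute everything the pruning core needs that does not depend on model
# parameters: postorder edge table, per-edge classes, tip state matrix with
# site patterns collapsed to unique columns (weights), codon indexing.
prepare_pruning <- function(alignment, tree, code = attr(alignment, "code")) {
  stopifnot(inherits(alignment, "codon_alignment"), inherits(tree, "phylo"))
  gc <- genetic_code(code)
  miss <- setdiff(alignment$taxa, tree$tip.label)
  if (length(miss)) stop("alignment taxa absent from tree: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  nsite <- alignment$sites
  states <- matrix(0L, ntip, nsite)
  for (tx in alignment$taxa) {
    cods <- alignment$codons[[tx]]
    st <- match(cods, gc$codons)          # NA for ambiguity/gap codons
    st[!is_unambiguous_codon(cods)] <- NA_integer_
    st[is.na(st)] <- 0L                   # fully missing data
    states[match(tx, tree$tip.label), ] <- st
  }
  key <- apply(states, 2, paste, collapse = ",")
  ux <- !duplicated(key)
  wts <- as.vector(table(factor(key, levels = key[ux])))
  patterns <- states[, ux, drop = FALSE]

  perm <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  edges <- tree$edge[perm, , drop = FALSE]
  lens <- tree$edge.length[perm]
  ecls <- if (!is.null(tree$edge.class)) tree$edge.class[perm] else integer(length(perm))
  list(patterns = patterns, wts = wts, edges = edges, lens = lens,
       edge.class = ecls, nnode = ntip + tree$Nnode, ntip = ntip,
       nsite = nsite, code = code, gc = gc)
}

# Per-pattern, per-site-class log-likelihoods. `omega_edge_class` is an
# nedge x nclass matrix of omega values (rows follow prep$edges); identical
# omegas share one eigendecomposition and cached P matrices.
#
# Scaling conventions: with `ref_omega = NULL` every omega's generator is
# normalized to one expected substitution per unit branch length (per-branch
# models: each branch's length is measured under its own process). With a
# `ref_omega`, all class generators share the single normalization of the
# reference-omega process, so site classes with larger omega evolve
# proportionally faster — the branch-site semantics, where selected sites
# accumulate more substitutions, not merely differently composed ones.
pattern_loglik <- function(prep, kappa, freqs, omega_edge_class, scale = 1,
                           ref_omega = NULL) {
  om <- as.matrix(omega_edge_class)
  uom <- sort(unique(as.vector(om)))
  rho <- if (is.null(ref_omega)) NULL else
    codon_rate(kappa, ref_omega, freqs, prep$code)
  eig <- lapply(uom, function(w) {
    Q <- if (is.null(rho))
      build_rate_matrix(kappa, w, freqs, code = prep$code)
    else
      build_rate_matrix(kappa, w, freqs, code = prep$code, scale = FALSE) / rho
    decompose_generator(Q, freqs)
  })
  idx <- matrix(match(as.vector(om), uom), nrow(om), ncol(om))
  .prune_loglik(prep$patterns, prep$edges, prep$lens * scale, idx, eig,
                as.numeric(freqs), prep$nnode)
}

# Collapse site-class log-likelihoods with mixture weights into total lnL.
mix_loglik <- function(ll, class_probs, wts) {
  if (ncol(ll) == 1L) return(sum(wts * ll[, 1]))
  mx <- apply(ll, 1, max)
  site <- mx + log(as.vector(exp(ll - mx) %*% class_probs))
  sum(wts * site)
}

# omega matrix builders ------------------------------------------------------

# single-class or per-branch-class model: one site class
omega_matrix_branch <- function(prep, omega_by_class) {
  matrix(omega_by_class[prep$edge.class + 1L], ncol = 1)
}

# branch-site model A structure: 4 site classes over (background, foreground)
#   class 1: (w0, w0)   class 2: (1, 1)   class 3: (w0, w2)   class 4: (1, w2)
omega_matrix_branch_site <- function(prep, omega0, omega2, foreground = NULL) {
  fg <- if (is.null(foreground)) prep$edge.class > 0L else foreground
  bg <- !fg
  m <- matrix(0, length(fg), 4)
  m[, 1] <- omega0
  m[, 2] <- 1
  m[, 3] <- ifelse(fg, omega2, omega0)
  m[, 4] <- ifelse(fg, omega2, 1)
  m
}

branch_site_probs <- function(p0, p1) {
  s <- p0 + p1
  r <- if (s > 0) p0 / s else 0.5
  c(p0, p1, (1 - s) * r, (1 - s) * (1 - r))
}

#' Codon-model log-likelihood
#'
#' Felsenstein pruning log-likelihood of an in-frame codon alignment on a
#' labeled tree under a GY94-style model: a single dN/dS ratio, one ratio per
#' branch class, or the 4-site-class branch-site mixture.
#'
#' @param alignment a `codon_alignment`.
#' @param tree a `labeled_tree` (or `phylo`, treated as one background class);
#'   branch lengths in expected substitutions per codon.
#' @param kappa transition/transversion ratio.
#' @param omega for the single/branch models a numeric vector giving the dN/dS
#'   ratio per branch class (class 0 first); for the branch-site model a list
#'   with `omega0`, `omega2`, `p0`, `p1`.
#' @param freqs codon frequency vector, or one of `"F3x4"`, `"F1x4"`,
#'   `"equal"` computed from the alignment.
#' @param model `"branch"` (default; covers the single-ratio case) or
#'   `"branch_site"`.
#' @return the log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(alignment, tree, kappa, omega, freqs = "F3x4",
                           model = c("branch", "branch_site")) {
  model <- match.arg(model)
  prep <- prepare_pruning(alignment, tree)
  if (is.character(freqs)) freqs <- codon_frequencies(alignment, freqs, prep$code)
  if (model == "branch") {
    nclass <- max(prep$edge.class) + 1L
    omega <- rep_len(as.numeric(omega), nclass)
    ll <- pattern_loglik(prep, kappa, freqs, omega_matrix_branch(prep, omega))
    mix_loglik(ll, 1, prep$wts)
  } else {
    ll <- pattern_loglik(prep, kappa, freqs,
                         omega_matrix_branch_site(prep, omega$omega0, omega$omega2),
                         ref_omega = omega$omega0)
    mix_loglik(ll, branch_site_probs(omega$p0, omega$p1), prep$wts)
  }
}
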