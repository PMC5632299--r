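#' Branch-site test of episodic positive selection
#'
#' Fits the branch-site alternative (model A: a fraction of sites may take
#' `omega2 >= 1` on the foreground branches) against its null (A1:
#' `omega2 = 1` fixed) and compares them by a likelihood-ratio test with one
#' degree of freedom. A positive-selection call additionally requires the
#' fitted `omega2 > 1` with a nonzero selected-site fraction, so a boundary
#' fit cannot be called positive even when the LRT is formally significant.
#'
#' @param alignment a `codon_alignment`.
#' @param tree a `labeled_tree`; foreground = branches with class > 0.
#' @param gene gene identifier carried into the result.
#' @param freqs codon frequency model or vector (see [fit_codon_model()]).
#' @param estimate_scale estimate one branch-length scale factor under M0
#'   first and hold it fixed in both nested fits (default), or trust the
#'   input branch lengths as-is.
#' @param null_dist `"chisq1"` (default; conservative at the boundary) or
#'   `"mixture"` for the 50:50 point-mass/chi-square boundary mixture.
#' @param n_restarts,seed multi-start control passed to [fit_codon_model()].
#' @return object of class `gene_test`: a list with `gene`, `kind`,
#'   `lnL_null`, `lnL_alt`, `lrt`, `df`, `p_raw`, `omega_by_class` (the
#'   branch-site parameter estimates), `positive_call`, `converged`, and the
#'   two fits.
#' @export
branch_site_test <- function(alignment, tree, gene = "gene", freqs = "F3x4",
                             estimate_scale = TRUE,
                             null_dist = c("chisq1", "mixture"),
                             n_restarts = 1L, seed = NULL) {
  null_dist <- match.arg(null_dist)
  if (!inherits(tree, "labeled_tree")) tree <- labeled_tree(tree)
  if (!any(tree$edge.class > 0L)) stop("tree has no foreground (class > 0) branches")
  base <- tree
  if (estimate_scale) {
    m0 <- fit_codon_model(alignment, tree, "M0", freqs = freqs,
                          branch_lengths = "scale", n_restarts = 1L, seed = seed)
    base$edge.length <- base$edge.length * m0$scale
  }
  null <- fit_codon_model(alignment, base, "branch_site", freqs = freqs,
                          fixed = list(omega2 = 1), branch_lengths = "fixed",
                          n_restarts = n_restarts, seed = seed)
  alt <- fit_codon_model(alignment, base, "branch_site", freqs = freqs,
                         branch_lengths = "fixed",
                         n_restarts = n_restarts, seed = seed)
  if (alt$lnL < null$lnL) {
    # restart the alternative from the null optimum (omega2 at its bound)
    alt2 <- fit_codon_model(alignment, base, "branch_site", freqs = freqs,
                            branch_lengths = "fixed", n_restarts = 1L, seed = seed,
                            inits = list(kappa = null$kappa,
                                         omega0 = null$omega[["omega0"]],
                                         omega2 = 1 + 1e-6))
    if (alt2$lnL > alt$lnL) alt <- alt2
  }
  lrt <- max(0, 2 * (alt$lnL - null$lnL))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (null_dist == "mixture") p <- if (lrt <= 0) 1 else 0.5 * p
  sel_frac <- 1 - (alt$p0 + alt$p1)
  res <- list(gene = gene, kind = "branch_site",
              lnL_null = null$lnL, lnL_alt = alt$lnL, lrt = lrt, df = 1L,
              p_raw = p,
              omega_by_class = c(alt$omega, p0 = alt$p0, p1 = alt$p1),
              positive_call = alt$omega[["omega2"]] > 1 + 1e-6 & sel_frac > 1e-8,
              direction = NA_character_,
              converged = null$converged && alt$converged,
              fit_null = null, fit_alt = alt)
  class(res) <- "gene_test"
  res
}

#' Pooled-branch dN/dS comparison (relaxed-selection test)
#'
#' Fits a 3-rate branch model (background / flightless / flying classes) and
#' a nested 2-rate model in which the two focal classes share one ratio, and
#' compares them by a 1-df likelihood-ratio test. The relaxed-selection
#' reading of a significant result — a higher ratio in the flightless class
#' with both focal ratios still below one — is recorded as a classification
#' field, not a different statistic.
#'
#' @param alignment a `codon_alignment`.
#' @param tree3 `labeled_tree` with classes 0 = background,
#'   `flightless_class`, `flying_class`.
#' @param tree2 optional 2-rate tree (identical topology/lengths, focal
#'   classes merged); derived from `tree3` when omitted.
#' @param gene gene identifier.
#' @param flightless_class,flying_class the class integers of the two pooled
#'   focal branch sets (defaults 1 and 2).
#' @param freqs,estimate_scale,n_restarts,seed as in [branch_site_test()].
#' @return a `gene_test` with `direction` (`"flightless"` or `"flying"`),
#'   `omega_by_class` from the 3-rate fit, and `relaxed_call` (significance is
#'   determined later, after multiplicity adjustment, via [bh_adjust()];
#'   `relaxed_call` here records only the direction-and-range condition).
#' @export
branch_rates_test <- function(alignment, tree3, tree2 = NULL, gene = "gene",
                              flightless_class = 1L, flying_class = 2L,
                              freqs = "F3x4", estimate_scale = TRUE,
                              n_restarts = 1L, seed = NULL) {
  if (!inherits(tree3, "labeled_tree")) tree3 <- labeled_tree(tree3)
  cls <- tree3$edge.class
  if (!any(cls == flightless_class) || !any(cls == flying_class))
    stop("tree3 must contain both focal branch classes")
  if (is.null(tree2)) {
    merged <- cls
    merged[cls == flying_class] <- flightless_class
    tree2 <- labeled_tree(tree3, merged)
  }
  base3 <- tree3; base2 <- tree2
  if (estimate_scale) {
    m0 <- fit_codon_model(alignment, tree3, "M0", freqs = freqs,
                          branch_lengths = "scale", n_restarts = 1L, seed = seed)
    base3$edge.length <- base3$edge.length * m0$scale
    base2$edge.length <- base2$edge.length * m0$scale
  }
  fit2 <- fit_codon_model(alignment, base2, "branch", freqs = freqs,
                          branch_lengths = "fixed", n_restarts = n_restarts, seed = seed)
  # map each 3-rate class to its pooled-fit omega for a nested warm start
  orig_classes <- seq_len(max(cls) + 1L) - 1L
  merged_of <- ifelse(orig_classes == flying_class, flightless_class, orig_classes)
  merged_levels <- sort(unique(ifelse(cls == flying_class, flightless_class, cls)))
  warm_omega <- unname(fit2$omega[match(merged_of, merged_levels)])
  fit3 <- fit_codon_model(alignment, base3, "branch", freqs = freqs,
                          branch_lengths = "fixed", n_restarts = n_restarts, seed = seed,
                          inits = list(kappa = fit2$kappa, omega = warm_omega))
  lrt <- max(0, 2 * (fit3$lnL - fit2$lnL))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  w_fl <- fit3$omega[[flightless_class + 1L]]
  w_fy <- fit3$omega[[flying_class + 1L]]
  res <- list(gene = gene, kind = "branch_rates",
              lnL_null = fit2$lnL, lnL_alt = fit3$lnL, lrt = lrt, df = 1L,
              p_raw = p, omega_by_class = fit3$omega,
              direction = if (w_fl > w_fy) "flightless" else "flying",
              relaxed_call = w_fl > w_fy && w_fl > 0 && w_fl < 1 && w_fy > 0 && w_fy < 1,
              positive_call = NA,
              converged = fit2$converged && fit3$converged,
              fit_null = fit2, fit_alt = fit3)
  class(res) <- "gene_test"
  res
}

#' @export
print.gene_test <- function(x, ...) {
  cat(sprintf("gene_test[%s] %s: 2dlnL = %.4f (df=%d), p = %.4g, direction = %s\n",
              x$kind, x$gene, x$lrt, x$df, x$p_raw,
              if (is.na(x$direction)) "-" else x$direction))
  invisible(x)
}

#' Collect per-gene test results into a table
#'
#' Row-binds `gene_test` objects and applies the Benjamini-Hochberg
#' correction across genes (one family per call, matching per-gene-set
#' families).
#'
#' @param tests list of `gene_test` objects.
#' @param alpha family-wise false-discovery level (default 0.05).
#' @return data.frame with columns gene, kind, lnL_null, lnL_alt, lrt, df,
#'   p_raw, p_bh, significant, direction and the per-class omega estimates.
#' @export
collect_gene_tests <- function(tests, alpha = 0.05) {
  df <- do.call(rbind, lapply(tests, function(t) {
    om <- t$omega_by_class
    data.frame(gene = t$gene, kind = t$kind, lnL_null = t$lnL_null,
               lnL_alt = t$lnL_alt, lrt = t$lrt, df = t$df, p_raw = t$p_raw,
               direction = if (is.na(t$direction)) NA_character_ else t$direction,
               converged = t$converged,
               t(stats::setNames(as.numeric(om), paste0("omega_", names(om)))),
               stringsAsFactors = FALSE)
  }))
  adj <- bh_adjust(df$p_raw, alpha = alpha)
  df$p_bh <- adj$p_adjusted
  df$significant <- adj$significant
  rownames(df) <- NULL
  df
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate control: the i-th smallest of m raw p-values
#' is adjusted to `min_{j >= i} m * p_(j) / j`, capped at 1; a gene is
#' flagged when its adjusted value is at most `alpha`.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha family-wise false-discovery level.
#' @return list with `p_adjusted` and logical `significant`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, significant = adj <= alpha)
}
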