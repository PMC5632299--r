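#' Simulate a complete flight-loss study to disk
#'
#' Writes a self-contained synthetic study through the same file formats the
#' readers consume: a pooled comparison tree whose terminal branches carry
#' flightless (class 1) and flying (class 2) labels, per-gene codon
#' alignments (FASTA) evolved under a branch model in which a subset of
#' "relaxed" genes has an elevated — but still purifying — dN/dS ratio on the
#' flightless branches, panel sub-trees for the replicated design, a trait
#' table, a gene-to-category annotation table with one planted enriched
#' category among the relaxed genes, and a manifest of every seed used.
#'
#' @param dir output directory (created if needed).
#' @param n_genes total genes (default 50).
#' @param n_relaxed genes simulated with the relaxed regime (default 5).
#' @param sites codon sites per gene (default 500).
#' @param n_flightless,n_flying flightless / flying terminal branches on the
#'   pooled tree and panel counts for the sub-tree design (defaults 11 and 9).
#' @param taxa_per_subtree taxa per panel sub-tree (default 14).
#' @param kappa transition/transversion ratio (default 2).
#' @param omega_background,omega_flying dN/dS on background and flying
#'   branches (defaults 0.05 and 0.02).
#' @param omega_relaxed flightless-branch dN/dS of relaxed genes (default 0.1;
#'   non-relaxed genes use `omega_flying` on flightless branches too).
#' @param n_categories,category_size annotation structure; the planted
#'   category over-samples relaxed genes by `enrichment_factor` (default 5).
#' @param enrichment_factor sampling odds multiplier for the planted category.
#' @param seed master seed; all per-gene seeds derive from it.
#' @return (invisibly) a list with the paths written, the planted gene and
#'   category ids, and the pooled `labeled_tree`.
#' @export
simulate_flight_study <- function(dir, n_genes = 50L, n_relaxed = 5L,
                                  sites = 500L,
                                  n_flightless = 11L, n_flying = 9L,
                                  taxa_per_subtree = 14L,
                                  kappa = 2, omega_background = 0.05,
                                  omega_flying = 0.02, omega_relaxed = 0.1,
                                  n_categories = 12L, category_size = 8L,
                                  enrichment_factor = 5,
                                  seed = 1L) {
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  tree <- with_seed(seed, pooled_comparison_tree(n_flightless, n_flying))
  write_labeled_tree(tree, file.path(dir, "tree.nwk"))
  traits <- data.frame(
    clade = tree$tip.label,
    state = c("flightless", "flying", "background")[
      tip_state_index(tree)],
    stringsAsFactors = FALSE)
  utils::write.table(traits, file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  genes <- sprintf("g%03d", seq_len(n_genes))
  relaxed <- genes[seq_len(n_relaxed)]
  gene_seeds <- seed + 1000L + seq_len(n_genes)
  for (i in seq_len(n_genes)) {
    om_fl <- if (genes[i] %in% relaxed) omega_relaxed else omega_flying
    model <- list(type = "branch", kappa = kappa,
                  omega = c(omega_background, om_fl, omega_flying))
    aln <- simulate_codon_alignment(tree, model, sites, seed = gene_seeds[i])
    write_codon_alignment(aln, file.path(dir, "genes", paste0(genes[i], ".fasta")))
  }

  scen <- make_flight_scenario(n_flightless, n_flying, taxa_per_subtree,
                               seed = seed + 7L)
  dir.create(file.path(dir, "panels"), showWarnings = FALSE)
  for (p in scen$panels)
    write_labeled_tree(p$tree, file.path(dir, "panels", paste0(p$id, "_", p$state, ".nwk")))

  cats <- sprintf("CAT%02d", seq_len(n_categories))
  cat_size <- min(category_size, max(1L, n_genes %/% 2L))
  # keep the per-member planting probability feasible on small studies
  eff_factor <- min(enrichment_factor, n_genes / max(1L, n_relaxed))
  ann <- simulate_annotations(genes,
                              stats::setNames(rep(cat_size, n_categories), cats),
                              planted = cats[1], enrichment_factor = eff_factor,
                              candidate_set = relaxed, seed = seed + 13L)
  write_annotations(ann, file.path(dir, "annotations.tsv"))

  manifest <- data.frame(item = c("master", "tree", "scenario", "annotations",
                                  paste0("gene_", genes)),
                         seed = c(seed, seed, seed + 7L, seed + 13L, gene_seeds))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(dir = dir, genes = genes, relaxed_genes = relaxed,
                 planted_category = cats[1], tree = tree,
                 annotations = ann, manifest = manifest))
}

# Pooled comparison tree: a coalescent backbone over flightless, flying and
# background tips, with classes on the terminal branches of the focal tips.
pooled_comparison_tree <- function(n_flightless, n_flying, n_background = 6L,
                                   branch_length_range = c(0.02, 0.3)) {
  n <- n_flightless + n_flying + n_background
  labels <- c(sprintf("FL%02d", seq_len(n_flightless)),
              sprintf("FY%02d", seq_len(n_flying)),
              sprintf("BG%02d", seq_len(n_background)))
  tr <- ape::rcoal(n, tip.label = sample(labels))
  tr$edge.length <- stats::runif(nrow(tr$edge), branch_length_range[1],
                                 branch_length_range[2])
  ntip <- length(tr$tip.label)
  cls <- integer(nrow(tr$edge))
  term <- tr$edge[, 2] <= ntip
  tipnames <- tr$tip.label[tr$edge[term, 2]]
  cls[term][startsWith(tipnames, "FL")] <- 1L
  cls[term][startsWith(tipnames, "FY")] <- 2L
  labeled_tree(tr, cls)
}

tip_state_index <- function(tree) {
  ifelse(startsWith(tree$tip.label, "FL"), 1L,
         ifelse(startsWith(tree$tip.label, "FY"), 2L, 3L))
}

#' Run the relaxed-selection analysis end to end
#'
#' Orchestrates the pooled-branch analysis on a study directory written by
#' [simulate_flight_study()] (or arranged the same way from real data): reads
#' every gene alignment, runs the 3-rate vs 2-rate likelihood-ratio test,
#' applies Benjamini-Hochberg control across genes, classifies candidates
#' (significantly higher dN/dS in the flightless class with both focal ratios
#' inside (0, 1)), runs the direction sign test over all genes, and tests the
#' candidate list for category over-representation. Per-gene failures are
#' recorded and skipped; the run fails only if no gene succeeds.
#'
#' @param dir study directory containing `genes/*.fasta`, `tree.nwk`, and
#'   `annotations.tsv`.
#' @param alpha family-wise false-discovery level (default 0.05).
#' @param method enrichment method (`"fisher"`, `"ease"`, `"binomial"`).
#' @param out_dir where to write the TSV result tables (default
#'   `file.path(dir, "results")`); `NULL` skips writing.
#' @param estimate_scale re-estimate a per-gene branch-length scale under M0
#'   before the nested fits (default `TRUE`; simulation studies whose trees
#'   carry the generating lengths can turn this off).
#' @param n_restarts,seed optimizer control for the per-gene fits.
#' @param verbose print one line per gene.
#' @return object of class `flight_pipeline_result`: list with `tests`
#'   (per-gene table), `candidates`, `sign_test`, `enrichment`, and `counts`
#'   (tested / converged / significant).
#' @export
run_flight_pipeline <- function(dir, alpha = 0.05, method = "fisher",
                                out_dir = file.path(dir, "results"),
                                estimate_scale = TRUE,
                                n_restarts = 1L, seed = 1L, verbose = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  gene_files <- sort(list.files(file.path(dir, "genes"), pattern = "\\.fasta$",
                                full.names = TRUE))
  if (!length(gene_files)) stop("no genes found in ", file.path(dir, "genes"))
  tree <- read_labeled_tree(file.path(dir, "tree.nwk"))
  ann_path <- file.path(dir, "annotations.tsv")
  annotations <- if (file.exists(ann_path)) read_annotations(ann_path) else NULL

  tests <- list(); failures <- character(0)
  for (f in gene_files) {
    gene <- sub("\\.fasta$", "", basename(f))
    res <- tryCatch({
      aln <- read_codon_alignment(f)
      branch_rates_test(aln, tree, gene = gene, estimate_scale = estimate_scale,
                        n_restarts = n_restarts, seed = seed + length(tests))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(gene, ": ", conditionMessage(res)))
      next
    }
    if (verbose)
      message(sprintf("%s lnL0=%.3f lnL1=%.3f p=%.4g dir=%s",
                      gene, res$lnL_null, res$lnL_alt, res$p_raw, res$direction))
    tests[[gene]] <- res
  }
  if (!length(tests)) stop("all genes failed: ", paste(failures, collapse = "; "))

  tab <- collect_gene_tests(tests, alpha = alpha)
  relaxed_flag <- vapply(tests, function(t) isTRUE(t$relaxed_call), logical(1))
  tab$relaxed_candidate <- tab$significant & relaxed_flag[tab$gene]
  candidates <- tab$gene[tab$relaxed_candidate]
  sign_res <- direction_sign_test(tab$direction)
  enr <- if (!is.null(annotations))
    enrich_table(candidates, tab$gene, annotations, method = method)
  else NULL
  counts <- c(tested = nrow(tab), converged = sum(tab$converged),
              significant = sum(tab$significant),
              candidates = length(candidates), failed = length(failures))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(tab, file.path(out_dir, "gene_tests.tsv"))
    writeLines(candidates, file.path(out_dir, "candidates.txt"))
    if (!is.null(enr)) write_results_table(enr, file.path(out_dir, "enrichment.tsv"))
    log <- c(sprintf("genes tested: %d", counts["tested"]),
             sprintf("converged: %d", counts["converged"]),
             sprintf("BH-significant at alpha=%g: %d of %d genes",
                     alpha, counts["significant"], counts["tested"]),
             sprintf("relaxed-selection candidates: %d of %d genes",
                     counts["candidates"], counts["tested"]),
             sprintf("direction sign test: %d of %d toward %s, p = %.4g",
                     sign_res$k, sign_res$n, sign_res$direction, sign_res$p),
             if (length(failures)) paste("failed:", failures))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  structure(list(tests = tab, candidates = candidates, sign_test = sign_res,
                 enrichment = enr, counts = counts, failures = failures,
                 alpha = alpha),
            class = "flight_pipeline_result")
}

#' @export
print.flight_pipeline_result <- function(x, ...) {
  cat("flight pipeline run:\n")
  cat(sprintf("  %d of %d genes BH-significant (alpha = %g); %d relaxed-selection candidates\n",
              x$counts["significant"], x$counts["tested"], x$alpha,
              x$counts["candidates"]))
  cat(sprintf("  direction sign test: %d of %d toward %s (p = %.4g)\n",
              x$sign_test$k, x$sign_test$n, x$sign_test$direction, x$sign_test$p))
  if (!is.null(x$enrichment) && nrow(x$enrichment))
    cat("  top category:", x$enrichment$category[1],
        sprintf("(O=%d, E=%.2f, p=%.3g)\n", x$enrichment$O[1],
                x$enrichment$E[1], x$enrichment$p[1]))
  invisible(x)
}
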