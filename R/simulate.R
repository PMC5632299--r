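#' Simulate a codon alignment along a labeled tree
#'
#' Evolves codon sites down the tree by sampling from the same transition
#' probability matrices the likelihood uses (site-wise transition sampling,
#' not event simulation), so the generative process exactly matches the
#' inferential model. The root codon of each site is drawn from the
#' stationary frequencies. Under a branch-site model each site draws one of
#' the four site classes once and keeps it across the whole tree; the
#' elevated ratio `omega2` applies only on foreground (class > 0) branches.
#'
#' @param tree a `labeled_tree` (or `phylo`) with branch lengths in expected
#'   substitutions per codon.
#' @param model list describing the generating model:
#'   `type = "branch"` with `omega` (one dN/dS value per branch class), or
#'   `type = "branch_site"` with `omega0`, `omega2`, `p0`, `p1`;
#'   both with `kappa` and optional `freqs` (default equal) and `code`.
#' @param n_sites number of codon sites, >= 1.
#' @param seed integer seed; the draw is fully determined by it.
#' @return a `codon_alignment` over the tree's tip labels.
#' @export
simulate_codon_alignment <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  if (!inherits(tree, "labeled_tree")) tree <- labeled_tree(tree)
  code <- model$code %||% "standard"
  gc <- genetic_code(code)
  ns <- length(gc$codons)
  freqs <- model$freqs %||% rep(1 / ns, ns)
  freqs <- validate_freqs(freqs, ns)
  type <- model$type %||% "branch"
  kappa <- model$kappa %||% 2

  perm <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  edges <- tree$edge[rev(perm), , drop = FALSE]   # preorder: parent before child
  lens <- tree$edge.length[rev(perm)]
  ecls <- tree$edge.class[rev(perm)]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- edges[1, 1]

  with_seed(seed, {
    # per-site class and per-(site-class, branch-class) omega lookup
    if (type == "branch_site") {
      probs <- branch_site_probs(model$p0, model$p1)
      site_class <- sample.int(4L, n_sites, replace = TRUE, prob = probs)
      omega_for <- function(sc, fg) {
        if (!fg) c(model$omega0, 1, model$omega0, 1)[sc]
        else c(model$omega0, 1, model$omega2, model$omega2)[sc]
      }
    } else {
      site_class <- rep(1L, n_sites)
      omega_by_class <- rep_len(as.numeric(model$omega), max(ecls) + 1L)
      omega_for <- function(sc, fg_class) omega_by_class[fg_class + 1L]
    }
    if (type == "branch_site") {
      # all site classes share the conserved-class normalization, so neutral
      # and selected sites evolve proportionally faster (matching inference)
      uom <- unique(c(model$omega0, 1, model$omega2))
      rho <- codon_rate(kappa, model$omega0, freqs, code)
      eig <- lapply(uom, function(w)
        decompose_generator(build_rate_matrix(kappa, w, freqs, code = code,
                                              scale = FALSE) / rho, freqs))
    } else {
      uom <- unique(omega_by_class)
      eig <- lapply(uom, function(w)
        decompose_generator(build_rate_matrix(kappa, w, freqs, code = code), freqs))
    }

    states <- matrix(0L, nnode, n_sites)
    states[root, ] <- sample.int(ns, n_sites, replace = TRUE, prob = freqs)
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      # one P matrix per omega used on this edge
      om_site <- if (type == "branch_site")
        vapply(site_class, omega_for, numeric(1), fg = ecls[e] > 0L)
      else rep(omega_for(1L, ecls[e]), n_sites)
      child_state <- integer(n_sites)
      for (w in unique(om_site)) {
        sel <- which(om_site == w)
        P <- transition_probabilities(eig[[match(w, uom)]], lens[e])
        for (s in unique(states[parent, sel])) {
          idx <- sel[states[parent, sel] == s]
          child_state[idx] <- sample.int(ns, length(idx), replace = TRUE, prob = P[s, ])
        }
      }
      states[child, ] <- child_state
    }
    seqs <- vapply(seq_len(ntip), function(i)
      paste(gc$codons[states[i, ]], collapse = ""), character(1))
    names(seqs) <- tree$tip.label
    codon_alignment(seqs, code = code)
  })
}

#' Build a flight-loss style study scenario
#'
#' Generates the panel structure of a replicated flight-loss comparative
#' design: independent coalescent-shaped sub-trees, each containing one focal
#' branch labeled with the panel's flight state (class 1) against background
#' branches (class 0), mirroring sub-trees built from a lineage of interest,
#' its sister lineages and successive outgroups.
#'
#' @param n_flightless number of flightless panels (default 11, the design's
#'   flightless lineage count).
#' @param n_flying number of related flying panels (default 9).
#' @param taxa_per_subtree taxa per panel tree, in `[4, 30]`; default 14
#'   (the smallest panel of the emulated design). A vector is recycled over
#'   panels.
#' @param branch_length_range range the panel tree's branch lengths are
#'   rescaled into (expected substitutions per codon).
#' @param grades qualitative mapping-accuracy grades (`"good"`, `"fair"`,
#'   `"approximate"`) recycled over panels; metadata only, recording how
#'   confidently a trait loss maps onto the focal branch.
#' @param seed integer seed.
#' @return object of class `flight_scenario`: a list with `panels` (each a
#'   list with `id`, `state`, `grade`, `tree`, `focal_edge`) and the seed.
#' @export
make_flight_scenario <- function(n_flightless = 11L, n_flying = 9L,
                                 taxa_per_subtree = 14L,
                                 branch_length_range = c(0.02, 0.3),
                                 grades = "good",
                                 seed = NULL) {
  stopifnot(n_flightless >= 1L, n_flying >= 1L,
            all(taxa_per_subtree >= 4L), all(taxa_per_subtree <= 30L),
            all(grades %in% c("good", "fair", "approximate")))
  states <- c(rep("flightless", n_flightless), rep("flying", n_flying))
  sizes <- rep_len(taxa_per_subtree, length(states))
  grades <- rep_len(grades, length(states))
  with_seed(seed, {
    panels <- lapply(seq_along(states), function(i) {
      n <- sizes[i]
      tr <- ape::rcoal(n, tip.label = sprintf("p%02d_t%02d", i, seq_len(n)))
      # rescale depths into the target substitutions-per-codon range
      tr$edge.length <- stats::runif(nrow(tr$edge), branch_length_range[1],
                                     branch_length_range[2])
      # focal branch: a random internal (non-root-adjacent if possible) or
      # terminal edge; exactly one per panel
      focal <- sample.int(nrow(tr$edge), 1L)
      cls <- integer(nrow(tr$edge))
      cls[focal] <- 1L
      list(id = sprintf("panel%02d", i), state = states[i], grade = grades[i],
           tree = labeled_tree(tr, cls), focal_edge = focal)
    })
    structure(list(panels = panels, n_flightless = n_flightless,
                   n_flying = n_flying, seed = seed),
              class = "flight_scenario")
  })
}

#' @export
print.flight_scenario <- function(x, ...) {
  cat("flight_scenario:", x$n_flightless, "flightless +", x$n_flying,
      "flying panels;", length(x$panels[[1]]$tree$tip.label), "taxa in panel 1\n")
  invisible(x)
}

#' Simulate a gene-to-category annotation table with planted enrichment
#'
#' Assigns genes to categories of prescribed sizes. Non-planted categories
#' sample members uniformly from the background; planted categories
#' over-sample candidate genes so that the expected number of candidates in
#' the category is `enrichment_factor` times the chance expectation
#' `K n / N` (each member is a candidate with probability
#' `enrichment_factor * n / N`), planting a known over-representation signal
#' for the enrichment statistics to recover.
#'
#' @param background_genes character vector of gene ids (the universe).
#' @param category_sizes named integer vector: category id -> size.
#' @param planted character vector of planted category ids (subset of the
#'   names of `category_sizes`).
#' @param enrichment_factor fold over-representation (>= 1) of candidate
#'   genes inside planted categories; infeasible factors (per-member
#'   candidate probability above 1) are an error.
#' @param candidate_set character vector of candidate gene ids.
#' @param seed integer seed.
#' @return an `annotation_table` (named list gene -> categories) covering
#'   every background gene (possibly with no categories).
#' @export
simulate_annotations <- function(background_genes, category_sizes, planted = character(0),
                                 enrichment_factor = 1, candidate_set = character(0),
                                 seed = NULL) {
  stopifnot(all(planted %in% names(category_sizes)), enrichment_factor >= 1)
  if (any(category_sizes > length(background_genes)))
    stop("infeasible category size: exceeds background")
  N <- length(background_genes)
  n_cand <- length(intersect(candidate_set, background_genes))
  if (length(planted) && enrichment_factor * n_cand / N > 1)
    stop("infeasible factor: per-member candidate probability exceeds 1")
  with_seed(seed, {
    member <- lapply(names(category_sizes), function(cat) {
      sz <- category_sizes[[cat]]
      if (!(cat %in% planted) || n_cand == 0L)
        return(sample(background_genes, sz))
      cand <- intersect(background_genes, candidate_set)
      rest <- setdiff(background_genes, cand)
      o <- stats::rbinom(1, sz, enrichment_factor * n_cand / N)
      o <- min(o, length(cand), sz)
      o <- max(o, sz - length(rest))
      c(sample(cand, o), sample(rest, sz - o))
    })
    names(member) <- names(category_sizes)
    ann <- stats::setNames(vector("list", length(background_genes)), background_genes)
    for (g in background_genes) ann[[g]] <- character(0)
    for (cat in names(member)) for (g in member[[cat]])
      ann[[g]] <- c(ann[[g]], cat)
    structure(ann, class = "annotation_table")
  })
}
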