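#' Genes detected only on the focal branch
#'
#' Filters branch-test hits to those unique to the focal branch: genes
#' significant on the focal stem but on neither the upstream nor the
#' downstream control branch.
#'
#' @param sig_focal,sig_upstream,sig_downstream character vectors of
#'   BH-significant gene ids from the three tests.
#' @param universe optional common tested-gene universe; supplying it turns
#'   ids outside the universe into an error.
#' @return object of class `candidate_set`: list with `genes`, `provenance`
#'   (`"unique_focal"`), and the three input sizes.
#' @export
unique_focal_candidates <- function(sig_focal, sig_upstream = character(0),
                                    sig_downstream = character(0),
                                    universe = NULL) {
  if (!is.null(universe)) {
    out <- setdiff(c(sig_focal, sig_upstream, sig_downstream), universe)
    if (length(out)) stop("gene(s) outside universe: ", paste(out, collapse = ", "))
  }
  genes <- setdiff(sig_focal, union(sig_upstream, sig_downstream))
  structure(list(genes = sort(genes), provenance = "unique_focal",
                 n_focal = length(unique(sig_focal)),
                 n_upstream = length(unique(sig_upstream)),
                 n_downstream = length(unique(sig_downstream))),
            class = "candidate_set")
}

#' Replicated-lineage candidate tally with flying-lineage subtraction
#'
#' Counts, per gene, in how many flightless panels it was significant, then
#' subtracts its count over related flying panels (floored at zero), and
#' keeps genes whose net count reaches the threshold — replicated evidence of
#' selection associated with flight loss beyond what comparable flying
#' lineages show.
#'
#' @param flightless_panels list of character vectors: significant genes per
#'   flightless panel.
#' @param flying_panels list of character vectors for the flying panels.
#' @param threshold minimum net count (default 3 lineages).
#' @param panels_tested optional named integer vector (gene -> number of
#'   panels whose universe contained the gene), reported for transparency;
#'   genes absent from a panel simply contribute no count.
#' @return a `candidate_set` with `genes`, `counts` data.frame (gene,
#'   flightless_count, flying_count, net) and `provenance = "tally"`.
#' @export
tally_candidates <- function(flightless_panels, flying_panels = list(),
                             threshold = 3L, panels_tested = NULL) {
  stopifnot(threshold >= 1L)
  genes <- unique(c(unlist(flightless_panels), unlist(flying_panels)))
  fl <- table(factor(unlist(lapply(flightless_panels, unique)), levels = genes))
  fy <- table(factor(unlist(lapply(flying_panels, unique)), levels = genes))
  net <- pmax(as.integer(fl) - as.integer(fy), 0L)
  counts <- data.frame(gene = genes, flightless_count = as.integer(fl),
                       flying_count = as.integer(fy), net = net,
                       stringsAsFactors = FALSE)
  if (!is.null(panels_tested))
    counts$panels_tested <- as.integer(panels_tested[counts$gene])
  keep <- counts$gene[counts$net >= threshold]
  structure(list(genes = sort(keep), provenance = "tally",
                 threshold = as.integer(threshold), counts = counts),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set (", x$provenance, "): ", length(x$genes), " genes\n", sep = "")
  if (length(x$genes)) cat(" ", paste(utils::head(x$genes, 10), collapse = ", "),
                           if (length(x$genes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Two-sided exact binomial sign test on per-gene directions
#'
#' Tests whether per-gene direction-of-effect calls (e.g. which pooled branch
#' class has the higher dN/dS ratio) are split unevenly, using the exact
#' binomial at p = 1/2 with the two-sided p-value computed by doubling the
#' smaller tail (inclusive of the observed count) and capping at 1. Ties must
#' be excluded before calling.
#'
#' @param directions character (or factor) vector of per-gene directions with
#'   exactly two levels, or an integer count `k` when `n` is given.
#' @param n when `directions` is a count: total number of genes.
#' @return list with `k` (count in the more frequent — or stated — direction),
#'   `n`, `p`, and `direction` (the majority label, when labels were given).
#' @export
direction_sign_test <- function(directions, n = NULL) {
  if (is.null(n)) {
    d <- as.character(directions)
    d <- d[!is.na(d)]
    if (!length(d)) stop("zero usable genes")
    lv <- sort(unique(d))
    if (length(lv) > 2L) stop("more than two direction labels")
    k <- sum(d == lv[1])
    if (k < length(d) - k) { lv <- rev(lv); k <- length(d) - k }
    n <- length(d)
    major <- lv[1]
  } else {
    k <- as.integer(directions)
    n <- as.integer(n)
    if (n < 1L || k < 0L || k > n) stop("invalid counts")
    major <- NA_character_
  }
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  list(k = k, n = n, p = p, direction = major)
}
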