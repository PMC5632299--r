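#' Expected candidate count in a category
#'
#' The chance expectation used by over-representation tables: genes in the
#' category (`K`) divided by background size (`N`), times candidate-list size
#' (`n`). Full precision; display rounding happens only in output columns.
#'
#' @param K genes in the category among the background.
#' @param N background size.
#' @param n candidate-list size.
#' @return expected count `K * n / N` (vectorized).
#' @export
expected_count <- function(K, N, n) {
  if (any(N <= 0)) stop("background size N must be positive")
  if (any(K < 0 | K > N | n < 0 | n > N)) stop("require 0 <= K, n <= N")
  K * n / N
}

#' Fold enrichment of a category in a candidate list
#'
#' Observed count divided by the unrounded expected count. Using the rounded
#' expectation instead would distort small categories (3 observed over an
#' expectation of 0.36 is 8.4-fold, not 3/0.4 = 7.5), so rounding is applied
#' only to display columns.
#'
#' @param O observed candidates in the category.
#' @param K,N,n as in [expected_count()].
#' @return `O / (K n / N)`; `Inf` (with a warning) when the expectation is
#'   zero but something was observed, `NaN` when both are zero.
#' @export
fold_enrichment <- function(O, K, N, n) {
  E <- expected_count(K, N, n)
  if (any(O < 0 | O > pmin(K, n))) stop("require 0 <= O <= min(K, n)")
  out <- O / E
  if (any(E == 0 & O > 0)) warning("zero expectation with nonzero observation: infinite fold enrichment")
  out
}

#' One-tailed Fisher exact test for category representation
#'
#' Hypergeometric tail probability for the 2x2 table splitting the background
#' into candidates vs non-candidates and in-category vs out-of-category.
#' Over-representation is `P(X >= O)` and under-representation `P(X <= O)`,
#' both inclusive of the observed table.
#'
#' @param O observed candidates in the category.
#' @param K,N,n as in [expected_count()].
#' @param direction `"over"` (default) or `"under"`.
#' @return the one-tailed p-value.
#' @export
fisher_one_tailed <- function(O, K, N, n, direction = c("over", "under")) {
  direction <- match.arg(direction)
  check_table(O, K, N, n)
  if (direction == "over") stats::phyper(O - 1, K, N - K, n, lower.tail = FALSE)
  else stats::phyper(O, K, N - K, n)
}

check_table <- function(O, K, N, n) {
  if (any(N <= 0 | K < 0 | n < 0 | K > N | n > N)) stop("inconsistent margins")
  if (any(O < 0 | O > K | O > n | (n - O) > (N - K))) stop("inconsistent counts")
  invisible(TRUE)
}

#' Binomial over-representation test
#'
#' The binomial analogue of the over-representation test: the observed count
#' against `X ~ Binomial(n, K/N)`, `p = P(X >= O)`.
#'
#' @inheritParams fisher_one_tailed
#' @return the one-tailed p-value.
#' @export
binomial_overrep <- function(O, K, N, n) {
  check_table(O, K, N, n)
  stats::pbinom(O - 1, n, K / N, lower.tail = FALSE)
}

#' EASE-style conservative over-representation score
#'
#' Fisher over-representation tail computed after removing one observed
#' candidate from the category cell (`P(X >= O - 1)` under the same margins),
#' the penalization that makes singleton hits non-significant by
#' construction: one observed gene scores 1.
#'
#' @inheritParams fisher_one_tailed
#' @return the penalized one-tailed p-value; 1 when `O = 0` by convention.
#' @export
ease_score <- function(O, K, N, n) {
  check_table(O, K, N, n)
  ifelse(O == 0, 1, stats::phyper(O - 2, K, N - K, n, lower.tail = FALSE))
}

#' Over-representation table for a candidate gene list
#'
#' Builds one row per annotation category present in the background (K >= 1)
#' with observed/expected counts, fold enrichment, and a one-tailed
#' over-representation p-value by the chosen method. Raw p-values only: when
#' candidate lists already come out of an FDR-controlled selection stage, no
#' additional multiplicity correction is applied here.
#'
#' @param candidates character vector of candidate gene ids (must be a subset
#'   of `background`).
#' @param background character vector: the mapped background gene universe.
#' @param annotations `annotation_table` (named list gene -> categories);
#'   genes without entries count as unannotated.
#' @param method `"fisher"` (default), `"ease"`, or `"binomial"`.
#' @param direction `"over"` (default) or `"under"` (Fisher only).
#' @return data.frame of class `enrichment_table` with columns category, K,
#'   N, n, O, E, E_display, FE, FE_display, p, method — ordered by p.
#' @export
enrich_table <- function(candidates, background, annotations,
                         method = c("fisher", "ease", "binomial"),
                         direction = c("over", "under")) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  bad <- setdiff(candidates, background)
  if (length(bad)) stop("candidate(s) not in background: ", paste(bad, collapse = ", "))
  N <- length(unique(background))
  n <- length(unique(candidates))
  cats_bg <- unlist(annotations[intersect(names(annotations), background)], use.names = FALSE)
  if (!length(cats_bg))
    return(structure(empty_enrichment_df(), class = c("enrichment_table", "data.frame")))
  Ktab <- table(cats_bg)
  cats_cd <- unlist(annotations[intersect(names(annotations), candidates)], use.names = FALSE)
  Otab <- table(factor(cats_cd, levels = names(Ktab)))
  K <- as.integer(Ktab); O <- as.integer(Otab)
  E <- expected_count(K, N, n)
  FE <- ifelse(E > 0, O / E, ifelse(O > 0, Inf, NaN))
  p <- switch(method,
              fisher = fisher_one_tailed(O, K, N, n, direction),
              ease = ease_score(O, K, N, n),
              binomial = binomial_overrep(O, K, N, n))
  df <- data.frame(category = names(Ktab), K = K, N = N, n = n, O = O,
                   E = E, E_display = vapply(E, display_round, numeric(1)),
                   FE = FE, FE_display = vapply(FE, display_round, numeric(1)),
                   p = p, method = method, stringsAsFactors = FALSE)
  df <- df[order(df$p, -df$FE, df$category), ]
  rownames(df) <- NULL
  structure(df, class = c("enrichment_table", "data.frame"))
}

empty_enrichment_df <- function() {
  data.frame(category = character(0), K = integer(0), N = integer(0),
             n = integer(0), O = integer(0), E = numeric(0),
             E_display = numeric(0), FE = numeric(0), FE_display = numeric(0),
             p = numeric(0), method = character(0), stringsAsFactors = FALSE)
}

# numeric counterpart of format_display(): half-away-from-zero to 1 decimal,
# one significant digit below 0.1
display_round <- function(x) {
  if (!is.finite(x)) return(x)
  if (abs(x) >= 0.095) round_half_up(x, 1) else signif(x, 1)
}

#' Grouped-term over-representation test
#'
#' Tests a user-defined union of categories (e.g. all wing-development terms,
#' or all mitochondrion/ATP/respiratory-chain terms) as one gene set, by an
#' ordinary one-tailed Fisher test on membership of the union.
#'
#' @param group_categories character vector of category ids to pool.
#' @param candidates,background,annotations as in [enrich_table()].
#' @param direction `"over"` or `"under"`.
#' @return one-row data.frame with the pooled K, N, n, O and p.
#' @export
grouped_term_test <- function(group_categories, candidates, background,
                              annotations, direction = c("over", "under")) {
  direction <- match.arg(direction)
  in_group <- function(g) {
    cats <- annotations[[g]]
    !is.null(cats) && length(intersect(cats, group_categories)) > 0
  }
  member <- vapply(background, in_group, logical(1))
  N <- length(background); K <- sum(member)
  n <- length(candidates); O <- sum(vapply(candidates, in_group, logical(1)))
  data.frame(K = K, N = N, n = n, O = O,
             p = fisher_one_tailed(O, K, N, n, direction),
             direction = direction)
}
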