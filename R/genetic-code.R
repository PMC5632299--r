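#' Genetic code tables for codon models
#'
#' Builds the lookup structures a codon substitution model needs: the list of
#' sense (non-stop) codons of a genetic code, their amino-acid translations,
#' and the single-nucleotide-change structure between them.
#'
#' @param code `"standard"` (nuclear, 61 sense codons) or `"invmito"`
#'   (invertebrate mitochondrial, 62 sense codons).
#' @return A list with elements `codons` (character vector of sense codons),
#'   `aa` (amino acid per sense codon), `stops` (stop codons), and `code`
#'   (the name). Cached per code.
#' @export
genetic_code <- function(code = c("standard", "invmito")) {
  code <- match.arg(code)
  cached <- .codonsel_env$codes[[code]]
  if (!is.null(cached)) return(cached)
  numcode <- if (code == "standard") 1L else 5L
  nt <- c("T", "C", "A", "G")
  all64 <- as.vector(vapply(nt, function(a)
    vapply(nt, function(b) paste0(a, b, nt), character(4)), character(16)))
  aa <- vapply(all64, function(cdn)
    seqinr::translate(strsplit(cdn, "")[[1]], numcode = numcode), character(1))
  sense <- aa != "*"
  out <- list(codons = all64[sense], aa = aa[sense],
              stops = all64[!sense], code = code)
  out$change <- codon_change_table(out$codons)
  .codonsel_env$codes[[code]] <- out
  out
}

.codonsel_env <- new.env(parent = emptyenv())
.codonsel_env$codes <- list()

# For each ordered pair of sense codons differing at exactly one position,
# record whether the change is a transition (A<->G, C<->T) and whether it is
# synonymous under the code. Returned as an index matrix used by the rate
# matrix builder.
codon_change_table <- function(codons) {
  n <- length(codons)
  mat <- do.call(rbind, strsplit(codons, ""))
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) i != j), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  ndiff <- (mat[i, 1] != mat[j, 1]) + (mat[i, 2] != mat[j, 2]) + (mat[i, 3] != mat[j, 3])
  keep <- ndiff == 1L
  i <- i[keep]; j <- j[keep]
  pos <- ifelse(mat[i, 1] != mat[j, 1], 1L, ifelse(mat[i, 2] != mat[j, 2], 2L, 3L))
  from <- mat[cbind(i, pos)]
  to <- mat[cbind(j, pos)]
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transition <- purine[from] == purine[to]
  list(i = i, j = j, transition = unname(transition))
}

# Split a nucleotide string into codons; no validation here.
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

is_unambiguous_codon <- function(codons) {
  grepl("^[ACGT]{3}$", codons)
}
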