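# Shared small fixtures, built in code.

tiny_alignment <- function() {
  codon_alignment(c(A = "ATGGCTAAG", B = "ATGGCAAAG", C = "ATGGGAAAA"))
}

tiny_tree <- function() {
  read_labeled_tree(text = "((A:0.1,B:0.1):0.05,C:0.2);")
}

# small labeled comparison tree: classes 1 (flightless) and 2 (flying) on two
# terminal branches each, over a 8-taxon coalescent backbone
small_comparison_tree <- function(seed = 42) {
  codonsel:::with_seed(seed, {
    tr <- ape::rcoal(8, tip.label = paste0("t", 1:8))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.25)
    ntip <- 8L
    cls <- integer(nrow(tr$edge))
    term <- which(tr$edge[, 2] <= ntip)
    cls[term[1:2]] <- 1L
    cls[term[3:4]] <- 2L
    labeled_tree(tr, cls)
  })
}

# a small foreground-labeled panel tree for branch-site tests
small_panel_tree <- function(ntaxa = 6, seed = 11) {
  codonsel:::with_seed(seed, {
    tr <- ape::rcoal(ntaxa, tip.label = paste0("s", seq_len(ntaxa)))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.25)
    cls <- integer(nrow(tr$edge))
    cls[sample(nrow(tr$edge), 1)] <- 1L
    labeled_tree(tr, cls)
  })
}
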