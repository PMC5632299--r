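test_that("codon alignments validate in-frame invariants", {
  aln <- codon_alignment(c(A = "ATGGCTAAG", B = "ATGGCAAAG"))
  expect_s3_class(aln, "codon_alignment")
  expect_equal(aln$sites, 3L)
  expect_equal(aln$taxa, c("A", "B"))

  expect_error(codon_alignment(c(A = "ATGGCTAAGC", B = "ATGGCAAAGC")),
               "multiple of 3")
  expect_error(codon_alignment(c(A = "ATGGCT", B = "ATGGCATT")), "ragged")
  expect_error(codon_alignment(c(A = "ATGGCT", A = "ATGGCA")), "duplicate")
  expect_error(codon_alignment(c(A = "ATGTAAGCT")),
               "stop codon 'TAA' in taxon 'A' at codon site 2")
  expect_error(codon_alignment(c("a b" = "ATGGCT")), "whitespace")
})

test_that("genetic code selection changes which codons are stops", {
  # TGA is a stop under the standard code but tryptophan (sense) in the
  # invertebrate mitochondrial code; AGA switches from arginine to serine
  expect_error(codon_alignment(c(A = "ATGTGA")), "stop codon")
  aln <- codon_alignment(c(A = "ATGTGA"), code = "invmito")
  expect_equal(aln$sites, 2L)
  std <- genetic_code("standard"); mito <- genetic_code("invmito")
  expect_equal(unname(std$aa[std$codons == "AGA"]), "R")
  expect_equal(unname(mito$aa[mito$codons == "AGA"]), "S")
  expect_setequal(mito$stops, c("TAA", "TAG"))
  expect_equal(length(std$codons), 61L)
  expect_equal(length(mito$codons), 62L)
})

test_that("FASTA and relaxed PHYLIP readers agree and round-trip", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">A extra descriptors ignored", "ATGGCT", "AAG", ">B", "ATGGCAAAG"), fa)
  a1 <- read_codon_alignment(fa)
  expect_equal(a1$sites, 3L)
  expect_equal(paste(a1$codons$A, collapse = ""), "ATGGCTAAG")

  ph <- tempfile(fileext = ".phy")
  writeLines(c("2 9", "A ATGGCT AAG", "B", "ATGGCAAAG"), ph)
  a2 <- read_codon_alignment(ph)
  expect_equal(a2$codons, a1$codons)

  out <- tempfile(fileext = ".fasta")
  write_codon_alignment(a1, out)
  expect_equal(read_codon_alignment(out)$codons, a1$codons)
})

test_that("Newick branch-class labels parse, default, and round-trip", {
  tr <- read_labeled_tree(text = "((A#1:0.1,B#1:0.1):0.05,C:0.2);")
  expect_s3_class(tr, "labeled_tree")
  expect_setequal(unique(tr$edge.class), c(0L, 1L))
  tips1 <- tr$edge[tr$edge.class == 1L, 2]
  expect_setequal(tr$tip.label[tips1], c("A", "B"))

  tr0 <- read_labeled_tree(text = "((A:0.1,B:0.1):0.05,C:0.2);")
  expect_true(all(tr0$edge.class == 0L))

  # internal-node class labels and round-trip through write_labeled_tree
  tr2 <- read_labeled_tree(text = "((A:0.1,B:0.1)#2:0.05,(C:0.1,D:0.1)#1:0.2);")
  expect_setequal(unique(tr2$edge.class), 0:2)
  txt <- write_labeled_tree(tr2)
  tr3 <- read_labeled_tree(text = txt)
  expect_equal(sort(tr3$tip.label), sort(tr2$tip.label))
  key <- function(t) {
    ntip <- length(t$tip.label)
    cls <- t$edge.class[match(seq_len(ntip), t$edge[, 2])]
    sort(paste(t$tip.label, cls))
  }
  expect_equal(key(tr3), key(tr2))

  expect_error(read_labeled_tree(text = "((A:0.1,B:0.1"), "[Nn]ewick")
})

test_that("non-contiguous classes are renumbered from 0", {
  tr <- read_labeled_tree(text = "((A#3:0.1,B#3:0.1):0.05,C#7:0.2);")
  expect_setequal(unique(tr$edge.class), c(0L, 1L, 2L))
})

test_that("trait-to-class mapping follows the stem-inclusion policy", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.2);")
  traits <- data.frame(clade = "A,B", state = "flightless")
  with_stem <- assign_branch_classes(tr, traits, include_stem = TRUE)
  without <- assign_branch_classes(tr, traits, include_stem = FALSE)
  ntip <- 4L
  mrca <- ape::getMRCA(tr, c("A", "B"))
  # hand-enumerated expectation: terminal edges of A and B, plus the stem
  expect_setequal(with_stem$edge[with_stem$edge.class == 1L, 2],
                  c(match(c("A", "B"), tr$tip.label), mrca))
  expect_setequal(without$edge[without$edge.class == 1L, 2],
                  match(c("A", "B"), tr$tip.label))
  # deterministic: same inputs, same classes
  expect_equal(assign_branch_classes(tr, traits)$edge.class, with_stem$edge.class)
  expect_error(assign_branch_classes(tr, data.frame(clade = "A,X", state = "flightless")),
               "unknown leaves")
  expect_error(assign_branch_classes(tr, data.frame(clade = "A,C", state = "flightless")),
               "monophyletic")
})

test_that("annotation tables read, merge duplicates, and round-trip", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tcatA;catB", "g2\tcatA", "g3\t", "g1\tcatB;catC"), f)
  ann <- read_annotations(f)
  expect_setequal(ann$g1, c("catA", "catB", "catC"))
  expect_equal(ann$g2, "catA")
  expect_length(ann$g3, 0L)
  f2 <- tempfile(fileext = ".tsv")
  write_annotations(ann, f2)
  expect_equal(read_annotations(f2)$g1, ann$g1)
})

test_that("results tables print display columns the way published tables do", {
  rows <- data.frame(category = "Precatalytic spliceosome",
                     K = 34L, N = 914L, n = 38L, O = 7L,
                     E = expected_count(34, 914, 38),
                     E_display = 1.4,
                     FE = fold_enrichment(7, 34, 914, 38),
                     FE_display = 5.0,
                     p = fisher_one_tailed(7, 34, 914, 38))
  path <- tempfile(fileext = ".tsv")
  write_results_table(rows, path)
  txt <- readLines(path)
  fields <- strsplit(txt[2], "\t")[[1]]
  expect_equal(fields[match("E_display", strsplit(txt[1], "\t")[[1]])], "1.4")
  expect_equal(fields[match("FE_display", strsplit(txt[1], "\t")[[1]])], "5.0")
  # full-precision columns survive a read-back round trip to >= 6 significant digits
  back <- utils::read.delim(path)
  expect_equal(back$E, rows$E, tolerance = 1e-6)
  expect_equal(back$p, rows$p, tolerance = 1e-6)

  # header-only file for an empty row set
  empty <- codonsel:::empty_enrichment_df()
  p2 <- tempfile(fileext = ".tsv")
  write_results_table(empty, p2)
  expect_length(readLines(p2), 1L)
})
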