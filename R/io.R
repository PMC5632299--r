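#' In-frame codon alignments
#'
#' A `codon_alignment` holds one in-frame protein-coding nucleotide sequence
#' per taxon, indexed by codon site. Construction validates the in-frame
#' invariants: all sequences the same length, length a multiple of three,
#' unique non-empty taxon names without whitespace, and no unambiguous stop
#' codon of the active genetic code at any site (stops are disallowed
#' everywhere, including the final site, since these are coding alignments
#' trimmed to sense codons).
#'
#' @param sequences named character vector (or list) of nucleotide strings
#'   over `A,C,G,T`, gaps `-` and IUPAC ambiguity letters; names are taxa.
#' @param code genetic code: `"standard"` or `"invmito"`.
#' @return object of class `codon_alignment` with fields `taxa`, `sites`,
#'   `codons` (list of per-taxon codon vectors) and attribute `code`.
#' @export
codon_alignment <- function(sequences, code = "standard") {
  sequences <- toupper(unlist(sequences))
  taxa <- names(sequences)
  if (is.null(taxa) || any(!nzchar(taxa)) || anyNA(taxa))
    stop("all sequences must be named")
  if (any(grepl("[[:space:]]", taxa))) stop("taxon names must be whitespace-free")
  if (anyDuplicated(taxa)) stop("duplicate taxa: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (", paste(unique(lens), collapse = ", "), ")")
  if (lens[1] %% 3L != 0L)
    stop("length not multiple of 3 (", lens[1], " nt)")
  gc <- genetic_code(code)
  codons <- lapply(sequences, split_codons)
  for (tx in taxa) {
    hit <- which(codons[[tx]] %in% gc$stops)
    if (length(hit))
      stop("stop codon '", codons[[tx]][hit[1]], "' in taxon '", tx,
           "' at codon site ", hit[1])
  }
  structure(list(taxa = taxa, sites = lens[[1]] %/% 3L, codons = codons),
            code = code, class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x", x$sites, "codon sites (",
      attr(x, "code"), "code )\n")
  invisible(x)
}

#' Read an in-frame codon alignment
#'
#' Reads FASTA or relaxed sequential PHYLIP (detected from the first
#' non-blank character) and validates it via [codon_alignment()].
#'
#' @param path file path.
#' @param code genetic code: `"standard"` or `"invmito"`.
#' @param format `"auto"` (default), `"fasta"` or `"phylip"`.
#' @return a `codon_alignment`.
#' @export
read_codon_alignment <- function(path, code = "standard",
                                 format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) stop("empty alignment file: ", path)
  if (format == "auto")
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  seqs <- if (format == "fasta") parse_fasta(lines) else parse_relaxed_phylip(lines)
  codon_alignment(seqs, code = code)
}

parse_fasta <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found")
  nm <- sub("^>\\s*", "", lines[hdr])
  nm <- sub("\\s.*$", "", nm)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    body <- lines[seq.int(hdr[k] + 1L, ends[k])]
    gsub("[[:space:]]", "", paste(body, collapse = ""))
  }, character(1))
  stats::setNames(seqs, nm)
}

# Relaxed sequential PHYLIP: header "ntaxa nchar", then one name token followed
# by sequence (possibly wrapped over lines, whitespace anywhere in sequence).
parse_relaxed_phylip <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("bad PHYLIP header: ", lines[1])
  ntax <- as.integer(hdr[1]); nch <- as.integer(hdr[2])
  toks <- unlist(strsplit(trimws(lines[-1]), "[[:space:]]+"))
  seqs <- character(0)
  k <- 1L
  for (i in seq_len(ntax)) {
    nm <- toks[k]; k <- k + 1L
    s <- ""
    while (nchar(s) < nch) {
      if (k > length(toks)) stop("truncated PHYLIP: taxon '", nm, "'")
      s <- paste0(s, toks[k]); k <- k + 1L
    }
    if (nchar(s) != nch) stop("sequence for '", nm, "' has ", nchar(s),
                              " characters, expected ", nch)
    seqs[nm] <- s
  }
  seqs
}

#' Write a codon alignment as FASTA
#' @param alignment a `codon_alignment`.
#' @param path output file.
#' @param width line width for wrapping.
#' @export
write_codon_alignment <- function(alignment, path, width = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  for (tx in alignment$taxa) {
    s <- paste(alignment$codons[[tx]], collapse = "")
    writeLines(paste0(">", tx), con)
    writeLines(substring(s, seq(1L, nchar(s), width),
                         pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Phylogenies with branch classes
#'
#' A `labeled_tree` is an `ape::phylo` carrying one small-integer class per
#' edge (`$edge.class`): 0 is background, 1, 2, ... are focal classes such as
#' flightless / flying branch sets or the foreground of a branch-site test.
#'
#' @param tree an `ape::phylo`.
#' @param edge.class integer vector, one class per row of `tree$edge`;
#'   defaults to all background.
#' @return the tree with class `labeled_tree` prepended.
#' @export
labeled_tree <- function(tree, edge.class = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ne <- nrow(tree$edge)
  if (is.null(edge.class)) edge.class <- integer(ne)
  edge.class <- as.integer(edge.class)
  if (length(edge.class) != ne) stop("edge.class must have one entry per edge")
  if (any(edge.class < 0L)) stop("edge classes must be >= 0")
  cls <- sort(unique(edge.class))
  expect <- seq.int(0L, length(cls) - 1L)
  if (!identical(cls, expect)) {
    # renumber to contiguous 0..K-1 preserving order
    edge.class <- match(edge.class, cls) - 1L
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  tree$edge.class <- edge.class
  class(tree) <- unique(c("labeled_tree", class(tree)))
  tree
}

#' Read a Newick tree with branch-class labels
#'
#' Accepts PAML-style `#k` suffixes on tip or internal node labels; the class
#' applies to the branch subtending that node. Unlabeled branches default to
#' class 0 and classes are renumbered contiguously from 0. Internal labels
#' without `#` are kept as node names, not classes.
#'
#' @param path file path, or a Newick string via `text`.
#' @param text optional Newick string (overrides `path`).
#' @return a `labeled_tree`.
#' @export
read_labeled_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) stop("unparseable Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick")
  ntip <- length(tr$tip.label)
  node_class <- integer(ntip + tr$Nnode)   # per node, class of subtending edge
  grab <- function(labels) {
    cls <- integer(length(labels))
    m <- regmatches(labels, regexpr("#\\s*[0-9]+\\s*$", labels))
    has <- grepl("#\\s*[0-9]+\\s*$", labels)
    cls[has] <- as.integer(sub("#", "", trimws(m)))
    list(labels = trimws(sub("#\\s*[0-9]+\\s*$", "", labels)), cls = cls)
  }
  g <- grab(tr$tip.label)
  tr$tip.label <- g$labels
  node_class[seq_len(ntip)] <- g$cls
  if (!is.null(tr$node.label)) {
    g <- grab(tr$node.label)
    tr$node.label <- g$labels
    node_class[ntip + seq_len(tr$Nnode)] <- g$cls
  }
  labeled_tree(tr, node_class[tr$edge[, 2]])
}

#' Write a labeled tree as Newick with `#k` class suffixes
#' @param tree a `labeled_tree`.
#' @param path output path; if `NULL` the Newick string is returned.
#' @export
write_labeled_tree <- function(tree, path = NULL) {
  tr <- tree
  ntip <- length(tr$tip.label)
  cls <- integer(ntip + tr$Nnode)
  cls[tr$edge[, 2]] <- tr$edge.class
  tip_suffix <- ifelse(cls[seq_len(ntip)] > 0, paste0("#", cls[seq_len(ntip)]), "")
  tr$tip.label <- paste0(tr$tip.label, tip_suffix)
  nl <- if (is.null(tr$node.label)) rep("", tr$Nnode) else tr$node.label
  ncls <- cls[ntip + seq_len(tr$Nnode)]
  tr$node.label <- paste0(nl, ifelse(ncls > 0, paste0("#", ncls), ""))
  class(tr) <- "phylo"
  txt <- ape::write.tree(tr)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Map trait annotations onto branch classes
#'
#' Assigns branch classes from a trait table of leaves or clades, the way
#' flight-state codings (flightless vs flying vs background) are mapped onto
#' a tree before pooled-branch rate tests. Each clade entry names either a
#' single leaf or a comma/plus-separated set of leaves whose MRCA subtree
#' carries the trait; the subtree must be monophyletic for the listed leaves.
#'
#' @param tree `phylo` or `labeled_tree`.
#' @param traits data.frame with columns `clade` and `state`; states are
#'   mapped through `state_classes`.
#' @param state_classes named integer vector mapping states to classes;
#'   default `c(flightless = 1, female_flightless = 1, flying = 2)` with any
#'   other state (`background`, `apterygote`, ...) left at class 0.
#' @param include_stem include the stem branch of an annotated clade
#'   (default `TRUE`, matching tests of stem lineages such as the branch on
#'   which flight originated); set `FALSE` to label only branches within the
#'   crown group.
#' @return a `labeled_tree`.
#' @export
assign_branch_classes <- function(tree, traits,
                                  state_classes = c(flightless = 1L,
                                                    female_flightless = 1L,
                                                    flying = 2L),
                                  include_stem = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  ne <- nrow(tree$edge)
  cls <- if (!is.null(tree$edge.class)) tree$edge.class else integer(ne)
  ntip <- length(tree$tip.label)
  for (r in seq_len(nrow(traits))) {
    state <- as.character(traits$state[r])
    k <- if (state %in% names(state_classes)) state_classes[[state]] else 0L
    if (k == 0L) next
    leaves <- trimws(strsplit(as.character(traits$clade[r]), "[,+]")[[1]])
    bad <- setdiff(leaves, tree$tip.label)
    if (length(bad)) stop("trait clade names unknown leaves: ", paste(bad, collapse = ", "))
    tips <- match(leaves, tree$tip.label)
    if (length(tips) == 1L) {
      cls[tree$edge[, 2] == tips] <- k
      next
    }
    mrca <- ape::getMRCA(tree, tips)
    desc <- phangorn_free_descendants(tree, mrca)
    if (!setequal(desc[desc <= ntip], tips))
      stop("clade (", traits$clade[r], ") is not monophyletic in the tree")
    members <- desc[desc != mrca]
    cls[tree$edge[, 2] %in% members] <- k
    if (include_stem) cls[tree$edge[, 2] == mrca] <- k
  }
  labeled_tree(tree, cls)
}

# All descendant nodes of `node` (including itself), by edge traversal.
phangorn_free_descendants <- function(tree, node) {
  out <- node
  frontier <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Read a gene-to-category annotation table
#'
#' Two-column TSV `gene<TAB>category[;category...]`; genes listed with an
#' empty second field are recorded as unannotated. Duplicate (gene, category)
#' pairs collapse to one.
#'
#' @param path TSV path.
#' @return named list mapping gene id to a character vector of categories
#'   (possibly empty), with class `annotation_table`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[`, character(1), 1L)
  cats <- lapply(parts, function(p)
    if (length(p) < 2L || !nzchar(p[2])) character(0)
    else unique(trimws(strsplit(p[2], ";", fixed = TRUE)[[1]])))
  out <- stats::setNames(cats, genes)
  if (anyDuplicated(genes)) {
    out <- tapply(cats, genes, function(x) unique(unlist(x)), simplify = FALSE)
    out <- out[unique(genes)]
  }
  structure(out, class = "annotation_table")
}

#' Write an annotation table
#' @param annotations named list gene -> categories.
#' @param path output TSV.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(names(annotations), function(g)
    paste0(g, "\t", paste(annotations[[g]], collapse = ";")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write result rows as TSV
#'
#' Writes per-gene test results or enrichment rows with a fixed column order.
#' Numeric columns keep at least six significant digits; enrichment tables
#' additionally carry `E_display` / `FE_display` columns rounded the way
#' published over-representation tables print them (one decimal, or one
#' significant digit below 0.1).
#'
#' @param rows a data.frame (e.g. from [enrich_table()] or the test runners).
#' @param path output path.
#' @export
write_results_table <- function(rows, path) {
  df <- as.data.frame(rows)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  disp <- grepl("_display$", names(df))
  for (j in which(num & !disp)) out[[j]] <- signif_str(df[[j]])
  for (j in which(num & disp)) out[[j]] <- vapply(df[[j]], format_display, character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

signif_str <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 8, format = "g"))
}

# Display rounding used in over-representation tables: half away from zero to
# one decimal, falling back to one significant digit for values below 0.1
# (so an expected count of 0.0438 prints as 0.04, and 8.36 prints as 8.4).
format_display <- function(x) {
  if (is.na(x)) return("NA")
  if (abs(x) >= 0.095) sprintf("%.1f", round_half_up(x, 1)) else formatC(signif(x, 1), format = "fg")
}

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
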