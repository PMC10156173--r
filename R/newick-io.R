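#' Read a Newick tree
#'
#' Parses a Newick string (or file) into an [ape::phylo] object with the
#' conventions used throughout this package: square-bracket comments are
#' discarded, single-quoted labels are accepted, fully numeric internal
#' labels are interpreted as branch supports (normalized to `[0,1]`;
#' values above 1 are taken as percentages and divided by 100), and other
#' internal labels are kept as node names.
#'
#' @param text a Newick string, or `NULL` if `file` is given.
#' @param file path to a file containing one Newick tree.
#' @return an object of class `phylo`.  Parsed supports, if any, are
#'   stored in the numeric vector attribute `support` (one entry per
#'   internal node, `NA` where the label was absent or non-numeric).
#' @details Duplicate leaf labels, negative branch lengths and unbalanced
#'   parentheses are rejected with an error naming the offending token.
#' @examples
#' tr <- read_newick("((A:1,B:1)0.95:0.5,C:2);")
#' attr(tr, "support")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) concord_error("concord_parse_error", "no input given")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^][]*\\]", "", text)   # discard comments
  # protect quoted labels
  quoted <- character(0)
  while (grepl("'", text, fixed = TRUE)) {
    m <- regmatches(text, regexpr("'[^']*'", text))
    if (length(m) == 0L)
      concord_error("concord_parse_error", "unbalanced quote in Newick input")
    quoted <- c(quoted, substr(m, 2L, nchar(m) - 1L))
    text <- sub("'[^']*'", sprintf("concordQUOTED%d", length(quoted)), text)
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    concord_error("concord_parse_error", sprintf(
      "unbalanced parentheses: %d '(' vs %d ')'", n_open, n_close))
  if (!grepl(";\\s*$", text))
    concord_error("concord_parse_error", "Newick input must end with ';'")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    concord_error("concord_parse_error", "malformed Newick input")
  restore <- function(x) {
    for (i in seq_along(quoted))
      x[x == sprintf("concordQUOTED%d", i)] <- quoted[i]
    x
  }
  tr$tip.label <- restore(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- restore(tr$node.label)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    concord_error("concord_parse_error",
                  paste("duplicate leaf label:", dup[1L]))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    concord_error("concord_parse_error", sprintf(
      "negative branch length: %g", min(tr$edge.length)))
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    sup[is.na(sup)] <- NA_real_
    sup <- ifelse(!is.na(sup) & sup > 1, sup / 100, sup)
    if (any(!is.na(sup) & (sup < 0 | sup > 1)))
      concord_error("concord_parse_error", "support outside [0,1] after normalization")
    attr(tr, "support") <- sup
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param file optional output path; if `NULL` the Newick string is
#'   returned.
#' @param digits number of significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  sup <- attr(tree, "support")
  if (!is.null(sup))
    tree$node.label <- ifelse(is.na(sup), tree$node.label %||% "",
                              format(sup, trim = TRUE, digits = 6))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a taxon-to-clade assignment table
#'
#' The table is tab-separated with columns `taxon_id`, `assembly` and
#' `clade`; `clade` must be one of `GLOEO`, `THERMO`, `HIGHER`,
#' `OUTGROUP`, `AMBIGUOUS`.
#'
#' @param path TSV file path.
#' @return a data frame with the three columns above.
#' @export
read_clade_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "clade")
  if (!all(need %in% names(df)))
    concord_error("concord_io_error",
                  "clade table must have columns taxon_id and clade")
  if (!"assembly" %in% names(df)) df$assembly <- NA_character_
  as_clade_map(setNames(df$clade, df$taxon_id))  # validates
  df[, c("taxon_id", "assembly", "clade")]
}

#' Write a taxon-to-clade table
#' @param clades named character vector or data frame as returned by
#'   [read_clade_map()].
#' @param path output TSV path.
#' @export
write_clade_map <- function(clades, path) {
  if (!is.data.frame(clades)) {
    cm <- as_clade_map(clades)
    clades <- data.frame(taxon_id = names(cm), assembly = NA_character_,
                         clade = unname(cm), stringsAsFactors = FALSE)
  }
  utils::write.table(clades, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Coerce to a clade map
#'
#' A clade map is a named character vector: names are taxon ids, values
#' are lineage labels from the closed set
#' `GLOEO/THERMO/HIGHER/OUTGROUP/AMBIGUOUS`.
#'
#' @param x named character vector or the data frame form.
#' @return a validated named character vector.
#' @export
as_clade_map <- function(x) {
  if (is.data.frame(x)) x <- setNames(x$clade, x$taxon_id)
  if (is.null(names(x)) || any(names(x) == ""))
    concord_error("concord_io_error", "clade map must be named by taxon id")
  bad <- setdiff(unique(x), CLADE_LABELS)
  if (length(bad))
    concord_error("concord_io_error",
                  paste("unknown clade label:", bad[1L]))
  if (anyDuplicated(names(x)))
    concord_error("concord_io_error", "duplicate taxon id in clade map")
  x
}

#' Read an aligned FASTA file of amino-acid sequences
#'
#' @param path FASTA path.
#' @return a named character vector of equal-width gapped sequences
#'   (alphabet: the 20 standard residues, `-`, and `X`).
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  aln <- setNames(as.character(ss), names(ss))
  validate_alignment(aln)
  aln
}

#' Write an alignment to FASTA
#' @param aln named character vector (equal widths).
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  validate_alignment(aln)
  writeLines(paste0(">", names(aln), "\n", unname(aln)), path)
  invisible(path)
}

validate_alignment <- function(aln) {
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    concord_error("concord_io_error", "alignment rows must have unique names")
  w <- unique(nchar(aln))
  if (length(w) != 1L)
    concord_error("concord_io_error", "alignment rows differ in width")
  ok <- paste0(AA_ALPHABET, collapse = "")
  if (any(grepl(sprintf("[^%sX-]", ok), aln)))
    concord_error("concord_io_error", "alignment contains non-amino-acid characters")
  invisible(aln)
}

#' Read ungapped protein sequences into a record table
#'
#' @param path FASTA path.
#' @param assembly assembly name attached to every record.
#' @return data frame with columns `id`, `assembly`, `sequence`.
#' @export
read_fasta_proteins <- function(path, assembly = NA_character_) {
  ss <- Biostrings::readAAStringSet(path)
  data.frame(id = names(ss), assembly = assembly,
             sequence = gsub("-", "", as.character(ss)),
             stringsAsFactors = FALSE)
}
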